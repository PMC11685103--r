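# Gene-level meta-learning: per-interaction aggregation of MRE scores and a
# gradient-boosted meta-classifier over the two per-region maxima.

#' Aggregate scored sites to interaction-level features
#'
#' One row per (miRNA, gene): the maximum MRE score separately in the
#' 3' UTR and CDS. A region without sites contributes 0 (absence is
#' informative; the score floor is 0). Site counts per region are kept as
#' diagnostics. Permutation-invariant in the input order.
#'
#' @param scored_sites data.frame with columns `mirna_id`, `gene_id`,
#'   `region` ("UTR3"/"CDS") and `score` in \[0,1\].
#' @return data.frame with `mirna_id`, `gene_id`, `max_utr3_score`,
#'   `max_cds_score`, `n_utr3_sites`, `n_cds_sites`.
#' @export
aggregate_mre_scores <- function(scored_sites) {
  need <- c("mirna_id", "gene_id", "region", "score")
  miss <- setdiff(need, names(scored_sites))
  if (length(miss)) stop("scored_sites missing column(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      max_utr3_score = numeric(), max_cds_score = numeric(),
                      n_utr3_sites = integer(), n_cds_sites = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(scored_sites) == 0L) return(empty)
  if (any(scored_sites$score < 0 | scored_sites$score > 1))
    stop("MRE scores must lie in [0, 1]")
  key <- paste(scored_sites$mirna_id, scored_sites$gene_id, sep = "\r")
  split_idx <- split(seq_len(nrow(scored_sites)), key)
  rows <- lapply(split_idx, function(ix) {
    sub <- scored_sites[ix, , drop = FALSE]
    u <- sub$score[sub$region == "UTR3"]
    c0 <- sub$score[sub$region == "CDS"]
    data.frame(mirna_id = sub$mirna_id[1L], gene_id = sub$gene_id[1L],
               max_utr3_score = if (length(u)) max(u) else 0,
               max_cds_score = if (length(c0)) max(c0) else 0,
               n_utr3_sites = length(u), n_cds_sites = length(c0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain sites by score for meta-learner training
#'
#' Sites in positive interactions are kept only when their first-layer score
#' exceeds 0.5; sites in negative interactions only when below 0.5. Scores
#' exactly 0.5 are dropped from both sets (strict inequalities).
#' Interactions left without sites keep region maxima of 0 downstream.
#'
#' @param scored_sites data.frame as in [aggregate_mre_scores()].
#' @param labels data.frame with `mirna_id`, `gene_id`, `label` (0/1) at the
#'   interaction level.
#' @param threshold retention threshold (default 0.5).
#' @return filtered `scored_sites`.
#' @export
filter_training_sites <- function(scored_sites, labels, threshold = 0.5) {
  key <- paste(scored_sites$mirna_id, scored_sites$gene_id, sep = "\r")
  lkey <- paste(labels$mirna_id, labels$gene_id, sep = "\r")
  lab <- labels$label[match(key, lkey)]
  keep <- (lab == 1 & scored_sites$score > threshold) |
    (lab == 0 & scored_sites$score < threshold)
  keep[is.na(keep)] <- FALSE
  out <- scored_sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Train the gene-level meta-learner
#'
#' Fits a gradient-boosted classifier on the two per-region maximum MRE
#' scores, reports 5-fold stratified cross-validated AUC/accuracy, then
#' refits on all data for deployment.
#'
#' @param features data.frame from [aggregate_mre_scores()] (columns
#'   `max_utr3_score`, `max_cds_score`).
#' @param labels 0/1 vector, one per row of `features`.
#' @param seed RNG seed for fold assignment.
#' @param n_trees,depth,shrinkage gradient-boosting hyperparameters
#'   (defaults 200 trees, depth 3, shrinkage 0.1).
#' @param n_folds cross-validation folds (default 5).
#' @return object of class `meta_model` with elements `model`, `cv_report`
#'   (per-fold AUC and accuracy), `cv_auc`, and `threshold_default` (0.5).
#' @export
train_meta_learner <- function(features, labels, seed = 1L, n_trees = 200L,
                               depth = 3L, shrinkage = 0.1, n_folds = 5L) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (length(y) < 20L) stop("need at least 20 interactions, got ", length(y))
  Xm <- as.matrix(features[, c("max_utr3_score", "max_cds_score")])
  stopifnot(nrow(Xm) == length(y))
  fold <- stratified_folds(y, n_folds, seed)
  cv <- lapply(seq_len(n_folds), function(k) {
    tr <- fold != k; te <- fold == k
    fit <- gbm_fit(Xm[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                   depth = depth, shrinkage = shrinkage)
    p <- predict(fit, Xm[te, , drop = FALSE])
    data.frame(fold = k, n = sum(te), auc = rank_auc(p, y[te]),
               accuracy = mean((p >= 0.5) == (y[te] == 1)))
  })
  cv <- do.call(rbind, cv)
  fit <- gbm_fit(Xm, y, n_trees = n_trees, depth = depth, shrinkage = shrinkage)
  structure(list(model = fit, cv_report = cv, cv_auc = mean(cv$auc),
                 threshold_default = 0.5), class = "meta_model")
}

#' Score interactions with a trained meta-learner
#'
#' @param meta a `meta_model`.
#' @param features data.frame with `max_utr3_score`, `max_cds_score`.
#' @return probability per row, order preserved.
#' @export
score_interactions <- function(meta, features) {
  stopifnot(inherits(meta, "meta_model"))
  need <- c("max_utr3_score", "max_cds_score")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features missing column(s): ", paste(miss, collapse = ", "))
  predict(meta$model, as.matrix(features[, need]))
}

#' Serialize / load a meta-learner
#'
#' @param meta a `meta_model`.
#' @param dir output directory.
#' @return `dir` (write) or the `meta_model` (read).
#' @export
write_meta_model <- function(meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(meta, file.path(dir, "meta.rds"))
  invisible(dir)
}

#' @rdname write_meta_model
#' @export
read_meta_model <- function(dir) readRDS(file.path(dir, "meta.rds"))
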