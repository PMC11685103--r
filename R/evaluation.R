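# Metrics, threshold selection, and functional-efficacy statistics.

#' Rank-based AUC (ties averaged)
#'
#' Equals the Mann-Whitney probability P(score_pos > score_neg) +
#' 0.5 P(equal).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector.
#' @return AUC in \[0,1\].
#' @export
rank_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation (average precision): precision accumulated at each
#' positive along the score-ranked list, ties processed as a block with the
#' block's interpolated precision.
#'
#' @inheritParams rank_auc
#' @return AUPRC in \[0,1\].
#' @export
auprc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("both classes required for AUPRC")
  npos <- sum(y == 1)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  ap <- 0; tp <- 0; n_seen <- 0
  i <- 1L
  while (i <= length(ys)) {
    j <- i
    while (j < length(ys) && ss[j + 1L] == ss[i]) j <- j + 1L
    block_pos <- sum(ys[i:j]); block_n <- j - i + 1L
    prec <- (tp + block_pos) / (n_seen + block_n)
    ap <- ap + prec * block_pos
    tp <- tp + block_pos; n_seen <- n_seen + block_n
    i <- j + 1L
  }
  ap / npos
}

#' Confusion and ranking metrics for binary predictions
#'
#' @param scores numeric predictions in \[0,1\].
#' @param labels 0/1 vector (both classes required).
#' @param threshold decision threshold; predictions `>= threshold` are
#'   called positive (default 0.5).
#' @param ci_reps bootstrap replicates for an AUC confidence interval
#'   (0 = skip; 2000 is the conventional choice).
#' @param ci_seed seed for the bootstrap.
#' @return list of class `metric_report`: `auc`, `auprc`, `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, `precision`, `recall`, `threshold_used`,
#'   and optionally `ci_auc = c(lo, hi)`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5, ci_reps = 0L,
                           ci_seed = 1L) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("both classes required")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  out <- list(auc = rank_auc(scores, y), auprc = auprc(scores, y),
              accuracy = (tp + tn) / length(y), f1 = f1,
              sensitivity = sens, specificity = spec,
              precision = prec, recall = sens, threshold_used = threshold)
  if (ci_reps > 0L) {
    set.seed(ci_seed)
    n <- length(y)
    reps <- replicate(ci_reps, {
      ix <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[ix])) < 2L) NA_real_ else rank_auc(scores[ix], y[ix])
    })
    out$ci_auc <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.3f  AUPRC %.3f  acc %.3f  F1 %.3f  sens %.3f  spec %.3f (thr %.3f)\n",
              x$auc, x$auprc, x$accuracy, x$f1, x$sensitivity, x$specificity,
              x$threshold_used))
  invisible(x)
}

#' Youden-index optimal threshold
#'
#' Exhaustive search over the observed score values for the threshold
#' maximizing J = sensitivity + specificity - 1 (predictions called at
#' `score >= threshold`); ties resolve to the smallest such score. Warns
#' when the best J is not positive (anti-predictive or degenerate scores).
#'
#' @inheritParams rank_auc
#' @return the optimal threshold (an observed score value).
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("both classes required")
  cand <- sort(unique(scores))
  J <- vapply(cand, function(thr) {
    pred <- scores >= thr
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1L))
  best <- max(J)
  if (best <= 0) warning("maximum Youden index is not positive (J = ",
                         signif(best, 3L), ")")
  cand[which(J == best)[1L]]
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Uses the exact permutation null distribution when both groups have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction (no continuity correction).
#'
#' @param x,y numeric samples.
#' @param exact_max exact-enumeration size bound per group (default 8).
#' @return list with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample")
  all_v <- c(x, y)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  ties <- any(duplicated(all_v))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    ranks <- seq_len(n1 + n2)
    combs <- combn(n1 + n2, n1)
    sums <- colSums(matrix(ranks[combs], nrow = n1))
    p <- 2 * min(mean(sums <= W), mean(sums >= W))
    return(list(statistic = W, p_value = min(1, p), exact = TRUE))
  }
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = W, p_value = 1, exact = FALSE))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, p_value = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether `x` is stochastically smaller than `y` (D+ on the ECDF
#' difference F_x - F_y), with the asymptotic one-sided tail
#' exp(-2 m n D^2 / (m + n)).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (D+) and `p_value`.
#' @export
ks_one_sided <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample")
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), numeric(1L))
  Fy <- vapply(v, function(t) mean(y <= t), numeric(1L))
  D <- max(Fx - Fy)
  p <- exp(-2 * n1 * n2 * max(D, 0)^2 / (n1 + n2))
  list(statistic = D, p_value = min(1, p))
}

#' Functional-efficacy comparison of predicted target groups
#'
#' Compares the perturbation response (log2 fold change) of each predicted
#' target group against genes with no predicted site, with a two-tailed
#' Wilcoxon rank-sum test per group. Optionally ranks within groups and
#' keeps only the `top_n` genes per group (callers pass score-ordered
#' sets). An optional one-sided KS variant supports model-vs-model
#' comparisons.
#'
#' @param perturb data.frame with `gene_id` and `log2_fc`.
#' @param groups named list of gene-id character vectors; must include
#'   `no_site` and at least one target group; groups must be disjoint.
#' @param top_n optional cap per non-reference group (first `top_n` ids
#'   taken in the order given; default `Inf`).
#' @param test `"wilcoxon"` (default) or `"ks"`.
#' @return data.frame: `group`, `n`, `n_ref`, `median_lfc`,
#'   `median_lfc_ref`, `statistic`, `p_value`.
#' @export
functional_efficacy <- function(perturb, groups, top_n = Inf,
                                test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  if (!"no_site" %in% names(groups)) stop("groups must include 'no_site'")
  if (length(groups$no_site) == 0L) stop("group 'no_site' is empty")
  empties <- names(groups)[vapply(groups, length, integer(1L)) == 0L]
  if (length(empties)) stop("empty group(s): ", paste(empties, collapse = ", "))
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) stop("groups must be disjoint")
  target_groups <- setdiff(names(groups), "no_site")
  ref <- perturb$log2_fc[perturb$gene_id %in% groups$no_site]
  if (!length(ref)) stop("no perturbation data for 'no_site' genes")
  rows <- lapply(target_groups, function(g) {
    sel <- groups[[g]]
    if (is.finite(top_n)) sel <- head(sel, top_n)
    v <- perturb$log2_fc[perturb$gene_id %in% sel]
    if (!length(v)) stop("no perturbation data for group '", g, "'")
    res <- if (test == "wilcoxon") wilcoxon_ranksum(v, ref) else ks_one_sided(v, ref)
    data.frame(group = g, n = length(v), n_ref = length(ref),
               median_lfc = median(v), median_lfc_ref = median(ref),
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
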