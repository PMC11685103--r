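# Independent oracles: deliberately naive re-derivations of the quantities
# the package computes, sharing no code with the implementation paths they
# check.

oracle_comp <- c(A = "U", C = "G", G = "C", U = "A", N = "#")

# Naive all-windows scanner: for every anchor, test each category definition
# directly, apply precedence, then dedup identical match starts.
oracle_scan_region <- function(mirna_seq, transcript, region) {
  iv <- if (region == "UTR3") transcript$utr3 else transcript$cds
  cs <- strsplit(substr(transcript$seq, iv[1] + 1, iv[2]), "")[[1]]
  m <- strsplit(mirna_seq, "")[[1]]
  L <- length(cs)
  comp17 <- unname(oracle_comp[m[1:17]])
  res <- list()
  for (a_local in seq_len(L + 1)) {        # anchor: local index opposite position 1
    tpos <- a_local - (0:16)               # target index opposite positions 1..17
    valid <- tpos >= 1 & tpos <= L
    tch <- rep("#", 17)
    tch[valid] <- cs[tpos[valid]]
    wc <- comp17 == tch
    a1A <- tch[1] == "A"
    cat <- NULL
    if (all(wc[2:10])) cat <- "9mer"
    else if (all(wc[2:8]) && a1A) cat <- "8mer"
    else if (all(wc[2:8])) cat <- "7mer-m8"
    else if (all(wc[2:7]) && a1A) cat <- "7mer-A1"
    else if (all(wc[2:7])) cat <- "6mer"
    else if (all(wc[4:14])) cat <- "centered"
    else if (sum(wc[2:7]) == 5 &&
             (all(wc[13:16]) || all(wc[14:17]))) cat <- "compensatory"
    if (is.null(cat)) next
    anchor <- iv[1] + a_local - 1
    span <- switch(cat,
                   "6mer" = c(anchor - 6, anchor),
                   "7mer-A1" = c(anchor - 6, anchor + 1),
                   "7mer-m8" = c(anchor - 7, anchor),
                   "8mer" = c(anchor - 7, anchor + 1),
                   "9mer" = c(anchor - 9, anchor),
                   "centered" = c(anchor - 13, anchor - 2),
                   "compensatory" = c(anchor - 6, anchor))
    if (span[1] < iv[1] || span[2] > iv[2]) next
    res[[length(res) + 1]] <- data.frame(start = as.integer(span[1]),
                                         end = as.integer(span[2]),
                                         anchor = as.integer(anchor),
                                         category = cat,
                                         stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(), anchor = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  prec <- match(out$category, c("9mer", "8mer", "7mer-m8", "7mer-A1", "6mer",
                                "centered", "compensatory"))
  out <- out[order(out$start, prec), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force AUC: pairwise comparison counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden search over observed scores (>= threshold convention).
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  J <- sapply(cand, function(thr) {
    sens <- mean(scores[labels == 1] >= thr)
    spec <- mean(scores[labels == 0] < thr)
    sens + spec - 1
  })
  cand[which(J == max(J))[1]]
}

# Exact Wilcoxon rank-sum null by enumeration of all label assignments.
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  combs <- combn(n1 + n2, n1)
  sums <- apply(combs, 2, function(ix) sum(seq_len(n1 + n2)[ix]))
  p <- 2 * min(mean(sums <= W), mean(sums >= W))
  list(statistic = W, p_value = min(1, p))
}

random_transcript <- function(len, id = "t1", gc = 0.5) {
  seq <- paste(sample(c("A", "C", "G", "U"), len, TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  split <- floor(0.6 * len)
  transcript_model(id, paste0("g_", id), seq, cds = c(0, split),
                   utr3 = c(split, len))
}

random_mirna_seq <- function(len = 22) {
  paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
}

constant_track <- function(transcripts, value) {
  sc <- lapply(transcripts, function(tr) rep(value, nchar(tr$seq)))
  names(sc) <- vapply(transcripts, `[[`, character(1), "transcript_id")
  conservation_track_vectors(sc)
}
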