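# Enumerative miRNA binding-site scanner.
#
# Site categories follow the standard seed taxonomy, with a centered class
# and a 3' compensatory class for non-canonical pairing. A site is anchored
# at the target position opposite miRNA position 1 ("anchor", 0-based
# transcript coordinate); miRNA position i pairs the target position
# anchor - (i - 1), i.e. the seed match lies immediately 5' of the anchor on
# the target.
#
# Category definitions (miRNA positions are 1-based from the 5' end):
#   6mer        Watson-Crick (WC) pairing of positions 2-7
#   7mer-A1     6mer plus an A in the target opposite position 1
#   7mer-m8     WC pairing of positions 2-8
#   8mer        7mer-m8 plus target A opposite position 1
#   9mer        WC pairing of positions 2-10
#   centered    WC pairing of positions 4-14 (>= 11 contiguous pairs) with
#               no 6mer seed match at the locus
#   compensatory  exactly one non-WC position (mismatch or G:U wobble) in the
#               2-7 seed, rescued by >= 4 contiguous WC pairs within
#               positions 13-17; only where no canonical or centered
#               category applies
#
# Precedence at a locus: 9mer > 8mer > 7mer-m8 > 7mer-A1 > 6mer > centered >
# compensatory; exactly one site is emitted per locus.

SITE_CATEGORIES <- c("9mer", "8mer", "7mer-m8", "7mer-A1", "6mer",
                     "centered", "compensatory")

category_rank <- function(category) match(category, SITE_CATEGORIES)

rna_complement <- function(x) chartr("ACGU", "UGCA", x)

#' Reverse complement of an RNA string
#' @param x RNA string.
#' @return reverse complement string.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(rna_complement(s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

wobble_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Report antiparallel pairing between a miRNA and a target substring
#'
#' The miRNA substring is read 5'->3' and paired against the target
#' substring read 3'->5' (so `mirna_sub[1]` pairs `target_sub[n]`).
#'
#' @param mirna_sub,target_sub equal-length RNA strings (both written
#'   5'->3').
#' @param allow_wobble flag G:U pairs as "wobble" instead of "mismatch".
#' @return character vector (one per miRNA position) over
#'   \{"WC", "wobble", "mismatch"\}.
#' @export
revcomp_match <- function(mirna_sub, target_sub, allow_wobble = FALSE) {
  m <- strsplit(mirna_sub, "")[[1L]]
  t <- rev(strsplit(target_sub, "")[[1L]])
  if (length(m) != length(t)) stop("mirna_sub and target_sub must have equal length")
  out <- rep("mismatch", length(m))
  out[wc_pair(m, t)] <- "WC"
  if (allow_wobble) out[wobble_pair(m, t)] <- "wobble"
  out
}

# Pairing matrices over all anchors of a region-local char vector.
# Row i = miRNA position i; column a = anchor (1-based index into cs of the
# target position opposite miRNA position 1). Entries outside the region are
# FALSE.
pairing_matrices <- function(mchars, cs, max_pos = 17L) {
  L <- length(cs)
  nA <- L + 1L                       # anchor may sit one past the region end
  comp <- rna_complement(paste(cs, collapse = ""))
  compc <- strsplit(comp, "")[[1L]]
  WC <- matrix(FALSE, nrow = max_pos, ncol = nA)
  WB <- matrix(FALSE, nrow = max_pos, ncol = nA)
  for (i in seq_len(max_pos)) {
    a <- seq_len(nA)
    tpos <- a - (i - 1L) - 1L        # 0-based region-local target position
    ok <- tpos >= 0L & tpos < L
    ti <- tpos[ok] + 1L
    WC[i, ok] <- mchars[i] == compc[ti]
    WB[i, ok] <- wobble_pair(rep(mchars[i], length(ti)), cs[ti])
  }
  list(WC = WC, WB = WB)
}

classify_anchors <- function(mchars, cs) {
  pm <- pairing_matrices(mchars, cs)
  WC <- pm$WC; WB <- pm$WB
  nA <- ncol(WC)
  L <- length(cs)
  a1_is_A <- c(cs, "#")[seq_len(nA)] == "A"   # target base at the anchor
  seed6 <- colSums(WC[2:7, , drop = FALSE]) == 6L
  seed7 <- seed6 & WC[8L, ]
  seed9 <- seed7 & WC[9L, ] & WC[10L, ]
  centered <- colSums(WC[4:14, , drop = FALSE]) == 11L
  seed_wc_n <- colSums(WC[2:7, , drop = FALSE])
  comp_seed <- seed_wc_n == 5L
  run3p <- (WC[13L, ] & WC[14L, ] & WC[15L, ] & WC[16L, ]) |
    (WC[14L, ] & WC[15L, ] & WC[16L, ] & WC[17L, ])
  cat <- rep(NA_character_, nA)
  cat[comp_seed & run3p] <- "compensatory"
  cat[centered & !seed6] <- "centered"
  cat[seed6] <- "6mer"
  cat[seed6 & a1_is_A] <- "7mer-A1"
  cat[seed7] <- "7mer-m8"
  cat[seed7 & a1_is_A] <- "8mer"
  cat[seed9] <- "9mer"
  list(category = cat, WC = WC, WB = WB)
}

site_span <- function(category, anchor) {
  # transcript interval of the seed-side pairing (0-based, half-open)
  switch(category,
         "6mer"        = c(anchor - 6L, anchor),
         "7mer-A1"     = c(anchor - 6L, anchor + 1L),
         "7mer-m8"     = c(anchor - 7L, anchor),
         "8mer"        = c(anchor - 7L, anchor + 1L),
         "9mer"        = c(anchor - 9L, anchor),
         "centered"    = c(anchor - 13L, anchor - 2L),
         "compensatory" = c(anchor - 6L, anchor))
}

empty_sites <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             gene_id = character(), region = character(),
             start = integer(), end = integer(), anchor = integer(),
             category = character(), paired_positions = character(),
             wobble_positions = character(), wobble_count = integer(),
             stringsAsFactors = FALSE)
}

#' Scan one transcript region for candidate miRNA binding sites
#'
#' Enumerates every locus of the region matching any supported site
#' category, keeping the strongest category per locus. Output rows are
#' sorted by `start`, then category precedence. Coordinates are 0-based,
#' half-open, in transcript space; sites never extend beyond the region.
#'
#' @param mirna named single-element character vector, or a plain RNA string
#'   with `mirna_id` supplied; length >= 17 nt required.
#' @param transcript a [transcript_model()].
#' @param region `"UTR3"` or `"CDS"`.
#' @param mirna_id identifier (defaults to `names(mirna)`).
#' @return data.frame of candidate sites (possibly zero rows) with columns
#'   `mirna_id`, `transcript_id`, `gene_id`, `region`, `start`, `end`,
#'   `anchor`, `category`, `paired_positions`, `wobble_positions`,
#'   `wobble_count`.
#' @export
scan_region <- function(mirna, transcript, region, mirna_id = names(mirna)) {
  region <- match.arg(region, c("UTR3", "CDS"))
  mseq <- normalize_rna(unname(mirna[1L]))
  if (is.null(mirna_id)) mirna_id <- "miRNA"
  if (nchar(mseq) < 17L) stop("miRNA shorter than 17 nt: ", mirna_id)
  iv <- region_interval(transcript, region)
  L <- iv[2L] - iv[1L]
  if (L <= 0L) return(empty_sites())
  cs <- strsplit(substr(transcript$seq, iv[1L] + 1L, iv[2L]), "")[[1L]]
  mchars <- strsplit(mseq, "")[[1L]][1:17]
  cl <- classify_anchors(mchars, cs)
  hit <- which(!is.na(cl$category))
  if (length(hit) == 0L) return(empty_sites())
  rows <- lapply(hit, function(a) {
    categ <- cl$category[a]
    anchor <- iv[1L] + a - 1L                # 0-based transcript coordinate
    span <- site_span(categ, anchor)
    if (span[1L] < iv[1L] || span[2L] > iv[2L]) return(NULL)
    paired <- switch(categ,
                     "6mer" = 2:7, "7mer-A1" = 2:7, "7mer-m8" = 2:8,
                     "8mer" = 2:8, "9mer" = 2:10, "centered" = 4:14,
                     "compensatory" = {
                       seedwc <- which(cl$WC[2:7, a]) + 1L
                       run <- if (cl$WC[13L, a] && cl$WC[14L, a] &&
                                  cl$WC[15L, a] && cl$WC[16L, a]) 13:16 else 14:17
                       c(seedwc, run)
                     })
    wob <- integer(0)
    if (categ == "compensatory") {
      bad <- setdiff(2:7, which(cl$WC[2:7, a]) + 1L)
      wob <- bad[cl$WB[bad, a]]
    }
    data.frame(mirna_id = mirna_id, transcript_id = transcript$transcript_id,
               gene_id = transcript$gene_id, region = region,
               start = span[1L], end = span[2L], anchor = anchor,
               category = categ,
               paired_positions = paste(paired, collapse = ","),
               wobble_positions = paste(wob, collapse = ","),
               wobble_count = length(wob), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_sites())
  # precedence dedup on match_start: keep the strongest category per start
  out <- out[order(out$start, category_rank(out$category)), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan both annotated regions of a transcript
#'
#' Union of [scan_region()] over the 3' UTR and CDS; windows are clipped
#' per region, so sites never span the CDS/3' UTR boundary.
#'
#' @inheritParams scan_region
#' @return data.frame of candidate sites.
#' @export
scan_transcript <- function(mirna, transcript, mirna_id = names(mirna)) {
  res <- list()
  if (diff(transcript$utr3) > 0L)
    res$utr3 <- scan_region(mirna, transcript, "UTR3", mirna_id = mirna_id)
  if (diff(transcript$cds) > 0L)
    res$cds <- scan_region(mirna, transcript, "CDS", mirna_id = mirna_id)
  if (length(res) == 0L)
    stop("transcript ", transcript$transcript_id, " has no annotated region")
  out <- do.call(rbind, unname(res))
  rownames(out) <- NULL
  out
}

#' Scan many miRNAs against many transcripts
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts list of transcript models.
#' @return combined candidate-site data.frame.
#' @export
scan_all <- function(mirnas, transcripts) {
  res <- list()
  for (m in names(mirnas)) {
    for (tr in transcripts) {
      if (diff(tr$utr3) <= 0L && diff(tr$cds) <= 0L) next
      res[[length(res) + 1L]] <- scan_transcript(mirnas[m], tr, mirna_id = m)
    }
  }
  if (length(res) == 0L) return(empty_sites())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
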