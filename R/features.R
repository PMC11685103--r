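# Five-channel feature encoding for candidate MREs.
#
# Every site is framed in a 30-nt window with 60-nt flanks on each side
# (150 nt total). The window is anchored so that the target base opposite
# miRNA position 1 sits at window offset 22 (0-based): 22 nt upstream leave
# room for the full 3'-supplementary pairing span of a 23-nt miRNA, 7 nt
# remain downstream. Windows and flanks are clipped at the annotated region
# boundary and N-padded; the two region models never see sequence from the
# other region.

MRE_WINDOW_LEN <- 30L
FLANK_LEN <- 60L
EXTENDED_LEN <- 150L
CHIMERA_MIRNA_LEN <- 23L
DUPLEX_LEN <- 60L

DOTBRACKET_DUPLEX_ALPHABET <- c("(", ")", ".", "&")
DOTBRACKET_FOLD_ALPHABET <- c("(", ")", ".")
PAD_CHAR <- "-"

#' Frame a candidate site in its 30/60/60 window
#'
#' @param site one row of a candidate-site data.frame (needs `anchor`).
#' @param region integer `c(start, end)`: the annotated region interval the
#'   site lives in (0-based, half-open transcript coordinates).
#' @return list with `window`, `upflank`, `downflank` intervals (transcript
#'   coordinates, possibly extending outside `region`; out-of-region
#'   positions are N-padded downstream).
#' @export
anchor_window <- function(site, region) {
  anchor <- as.integer(site$anchor)
  win <- c(anchor - 22L, anchor + 8L)
  list(window = win,
       upflank = c(win[1L] - FLANK_LEN, win[1L]),
       downflank = c(win[2L], win[2L] + FLANK_LEN),
       region = as.integer(region))
}

# Extract the sequence of a transcript interval clipped to a region;
# positions outside the region (or transcript) become N.
region_subseq <- function(transcript, interval, region) {
  n <- interval[2L] - interval[1L]
  out <- rep("N", n)
  pos <- seq.int(interval[1L], interval[2L] - 1L)
  ok <- pos >= region[1L] & pos < region[2L]
  if (any(ok)) {
    chars <- strsplit(substr(transcript$seq, min(pos[ok]) + 1L, max(pos[ok]) + 1L), "")[[1L]]
    out[ok] <- chars
  }
  paste(out, collapse = "")
}

#' Build the 150-symbol extended MRE sequence
#'
#' upflank (60) + window (30) + downflank (60), N-padded where the frame
#' leaves the annotated region.
#'
#' @param window result of [anchor_window()].
#' @param transcript a [transcript_model()].
#' @return 150-character string over \{A,C,G,U,N\}.
#' @export
build_extended_mre <- function(window, transcript) {
  paste0(region_subseq(transcript, window$upflank, window$region),
         region_subseq(transcript, window$window, window$region),
         region_subseq(transcript, window$downflank, window$region))
}

#' Build the 53-symbol miRNA-MRE chimera
#'
#' The miRNA (<= 23 nt, right-padded with N to 23) concatenated with the
#' 30-nt site window.
#'
#' @param mirna miRNA sequence (17-23 nt).
#' @param window_seq the 30-nt window sequence.
#' @return 53-character string.
#' @export
build_chimera <- function(mirna, window_seq) {
  mseq <- normalize_rna(unname(mirna[1L]))
  if (nchar(mseq) > CHIMERA_MIRNA_LEN)
    stop("miRNA longer than ", CHIMERA_MIRNA_LEN,
         " nt; refusing to truncate (", nchar(mseq), " nt)")
  if (nchar(window_seq) != MRE_WINDOW_LEN)
    stop("window sequence must be ", MRE_WINDOW_LEN, " nt")
  pad <- strrep("N", CHIMERA_MIRNA_LEN - nchar(mseq))
  paste0(mseq, pad, window_seq)
}

fold_input <- function(x) gsub("N", "A", x)  # folding engine rejects N

#' Co-fold a miRNA with a site window
#'
#' Thermodynamic duplex (intermolecular-only) folding of the miRNA against
#' the 30-nt window. The structure is serialized as
#' `structure(miRNA) & structure(window)` in dot-bracket notation, '(' on
#' the miRNA strand, ')' on the target, right-padded with '-' to exactly 60
#' symbols. When no duplex with negative free energy exists, all positions
#' are dots and the MFE is 0.
#'
#' @param mirna miRNA sequence.
#' @param window_seq 30-nt window sequence.
#' @return list with `structure` (60 chars) and `mfe` (kcal/mol, <= 0).
#' @export
fold_duplex <- function(mirna, window_seq) {
  mseq <- normalize_rna(unname(mirna[1L]))
  if (nchar(window_seq) != MRE_WINDOW_LEN)
    stop("window sequence must be ", MRE_WINDOW_LEN, " nt")
  res <- duplex_fold_cpp(fold_input(mseq), fold_input(normalize_rna(window_seq)))
  body <- paste0(res$structure1, "&", res$structure2)
  if (nchar(body) > DUPLEX_LEN)
    stop("duplex serialization exceeds ", DUPLEX_LEN, " symbols")
  structure_str <- paste0(body, strrep(PAD_CHAR, DUPLEX_LEN - nchar(body)))
  list(structure = structure_str, mfe = res$mfe, n_pairs = res$n_pairs)
}

#' Fold the 150-nt extended MRE context
#'
#' Single-sequence minimum-free-energy structure of the extended MRE
#' (N folds as A; the encoded sequence keeps its Ns).
#'
#' @param extended 150-character extended MRE string.
#' @return 150-character dot-bracket string.
#' @export
fold_context <- function(extended) {
  if (nchar(extended) != EXTENDED_LEN)
    stop("extended MRE must be ", EXTENDED_LEN, " symbols, got ", nchar(extended))
  mfe_fold_cpp(fold_input(normalize_rna(extended)))$structure
}

#' Per-base conservation profile of the extended MRE
#'
#' @param window result of [anchor_window()].
#' @param transcript a [transcript_model()].
#' @param track a `conservation_track`.
#' @return numeric vector of length 150 in \[0,1\]; positions outside the
#'   annotated region are 0.
#' @export
conservation_profile <- function(window, transcript, track) {
  full <- c(window$upflank[1L], window$downflank[2L])
  vals <- read_conservation(track, transcript, full)
  pos <- seq.int(full[1L], full[2L] - 1L)
  vals[pos < window$region[1L] | pos >= window$region[2L]] <- 0
  vals
}

#' One-hot encode a symbol string
#'
#' Row i carries a single 1 at the alphabet index of symbol i; symbols
#' outside the alphabet (N, padding) give an all-zero row.
#'
#' @param s symbol string.
#' @param alphabet ordered character vector of channel symbols.
#' @return numeric matrix `nchar(s) x length(alphabet)`.
#' @export
one_hot_encode <- function(s, alphabet) {
  if (length(alphabet) == 0L) stop("empty alphabet")
  chars <- strsplit(s, "")[[1L]]
  m <- matrix(0, nrow = length(chars), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  idx <- match(chars, alphabet)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a string
#'
#' All-zero rows decode to `unknown`.
#'
#' @param m one-hot matrix with alphabet column names.
#' @param unknown symbol for all-zero rows.
#' @return decoded string.
#' @export
one_hot_decode <- function(m, unknown = "N") {
  idx <- apply(m, 1L, function(r) { w <- which(r == 1); if (length(w)) w[1L] else NA })
  chars <- ifelse(is.na(idx), unknown, colnames(m)[idx])
  paste(chars, collapse = "")
}

#' Build the full five-channel feature bundle for one site
#'
#' Composes the window framing, sequence extraction, chimera construction,
#' duplex and context folding, conservation lookup and one-hot encoding.
#' Deterministic for fixed inputs.
#'
#' @param site one candidate-site row (from [scan_region()] or the
#'   synthetic generator).
#' @param mirna miRNA sequence (named or plain).
#' @param transcript a [transcript_model()].
#' @param track a `conservation_track`.
#' @return object of class `feature_bundle`: list with matrices
#'   `extended_mre` (150x4), `chimera` (53x4), `duplex` (60x4), `fold`
#'   (150x3), `conservation` (150x1) and scalar `duplex_mfe`.
#' @export
build_bundle <- function(site, mirna, transcript, track) {
  region <- region_interval(transcript, site$region)
  w <- anchor_window(site, region)
  extended <- build_extended_mre(w, transcript)
  window_seq <- substr(extended, FLANK_LEN + 1L, FLANK_LEN + MRE_WINDOW_LEN)
  chim <- build_chimera(mirna, window_seq)
  dup <- fold_duplex(mirna, window_seq)
  ctx <- fold_context(extended)
  cons <- conservation_profile(w, transcript, track)
  structure(list(
    extended_mre = one_hot_encode(extended, RNA_ALPHABET),
    chimera = one_hot_encode(chim, RNA_ALPHABET),
    duplex = one_hot_encode(dup$structure, DOTBRACKET_DUPLEX_ALPHABET),
    fold = one_hot_encode(ctx, DOTBRACKET_FOLD_ALPHABET),
    conservation = matrix(cons, ncol = 1L),
    duplex_mfe = dup$mfe
  ), class = "feature_bundle")
}

#' Stack feature bundles into per-branch arrays
#'
#' @param bundles list of `feature_bundle` objects.
#' @return list of arrays, one per branch, each `n x length x channels`
#'   (conservation has one channel).
#' @export
stack_bundles <- function(bundles) {
  n <- length(bundles)
  stack1 <- function(field) {
    d <- dim(bundles[[1L]][[field]])
    arr <- array(0, dim = c(n, d[1L], d[2L]))
    for (i in seq_len(n)) arr[i, , ] <- bundles[[i]][[field]]
    arr
  }
  list(mre = stack1("extended_mre"), chimera = stack1("chimera"),
       duplex = stack1("duplex"), fold = stack1("fold"),
       conservation = stack1("conservation"))
}
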