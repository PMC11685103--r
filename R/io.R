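# Sequence, region-annotation and conservation input handling.
#
# All coordinates are 0-based, half-open, in transcript space (BED
# convention). Sequences are normalized to the RNA alphabet {A,C,G,U,N} on
# ingest: lower case is raised, T becomes U, anything else becomes N.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U, and replaces any symbol outside
#' \{A,C,G,U\} with N.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  gsub("[^ACGUN]", "N", x)
}

#' Read a FASTA file of (mi)RNA or transcript sequences
#'
#' Sequences are normalized with [normalize_rna()]. Record order is
#' preserved; duplicate identifiers are an error. The identifier is the
#' header token up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first, ": expected '>' header, got '",
         substr(lines[first], 1L, 40L), "'")
  }
  hdr <- which(startsWith(lines, ">"))
  for (h in hdr) {
    id <- strsplit(trimws(sub("^>", "", lines[h])), "\\s+")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) stop("malformed FASTA at line ", h, ": empty record id")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_rna(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a transcript model
#'
#' A transcript model couples a transcript sequence with its CDS and 3' UTR
#' intervals in transcript coordinates (0-based, half-open). Either region
#' may be empty (zero-width). The 3' UTR must start at or after the CDS end
#' and both intervals must be disjoint and within the sequence.
#'
#' @param transcript_id,gene_id identifiers.
#' @param seq transcript sequence (normalized on construction).
#' @param cds,utr3 integer length-2 vectors `c(start, end)`, 0-based
#'   half-open; use `c(0, 0)` for an absent region.
#' @param appris optional APPRIS label (e.g. "PRINCIPAL:1").
#' @param chrom_map optional data.frame mapping transcript blocks to genomic
#'   blocks (columns `t_start`, `t_end`, `chrom`, `g_start`, `strand`) for
#'   bigWig conservation lookup.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seq, cds, utr3,
                             appris = NA_character_, chrom_map = NULL) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  cds <- as.integer(cds); utr3 <- as.integer(utr3)
  chk <- function(iv, nm) {
    if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 0L || iv[2L] > n)
      stop(nm, " interval out of bounds for transcript ", transcript_id)
  }
  chk(cds, "cds"); chk(utr3, "utr3")
  if (utr3[2L] > utr3[1L] && cds[2L] > cds[1L]) {
    if (utr3[1L] < cds[2L]) stop("utr3 must start at or after cds end: ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id, seq = seq,
                 cds = cds, utr3 = utr3, appris = appris,
                 chrom_map = chrom_map),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s): %d nt, CDS [%d,%d), 3'UTR [%d,%d)>\n",
              x$transcript_id, x$gene_id, nchar(x$seq),
              x$cds[1L], x$cds[2L], x$utr3[1L], x$utr3[2L]))
  invisible(x)
}

region_interval <- function(transcript, region) {
  region <- match.arg(region, c("UTR3", "CDS"))
  if (region == "UTR3") transcript$utr3 else transcript$cds
}

#' Read a region-annotation table and assemble transcript models
#'
#' The TSV must carry columns `transcript_id`, `gene_id`, `cds_start`,
#' `cds_end`, `utr3_start`, `utr3_end` and optionally `appris`.
#'
#' @param seqs named character vector of transcript sequences (from
#'   [read_fasta()]).
#' @param path path to the region TSV.
#' @return named list of [transcript_model()] objects.
#' @export
read_region_table <- function(seqs, path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end",
            "utr3_start", "utr3_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region table missing column(s): ", paste(miss, collapse = ", "))
  if (!"appris" %in% names(df)) df$appris <- NA_character_
  absent <- setdiff(df$transcript_id, names(seqs))
  if (length(absent)) stop("region table references transcripts absent from FASTA: ",
                           paste(head(absent, 5L), collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(df$transcript_id[i], df$gene_id[i], seqs[[df$transcript_id[i]]],
                     cds = c(df$cds_start[i], df$cds_end[i]),
                     utr3 = c(df$utr3_start[i], df$utr3_end[i]),
                     appris = df$appris[i])
  })
  names(out) <- df$transcript_id
  out
}

appris_rank <- function(label) {
  # PRINCIPAL:1 best, then PRINCIPAL:2..., then ALTERNATIVE:1..., unlabeled last
  ifelse(is.na(label) | !nzchar(label), 1e6,
         ifelse(grepl("^PRINCIPAL:", label), as.numeric(sub("^PRINCIPAL:", "", label)),
                ifelse(grepl("^ALTERNATIVE:", label),
                       100 + as.numeric(sub("^ALTERNATIVE:", "", label)), 1e6)))
}

#' Select the principal transcript of a gene
#'
#' Picks the transcript with the best APPRIS label; ties are broken by the
#' longest 3' UTR, then by lexicographic transcript id. Deterministic and
#' order-independent.
#'
#' @param candidates list of [transcript_model()] objects, all one gene.
#' @return the selected transcript model.
#' @export
select_principal_transcript <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate transcripts")
  genes <- unique(vapply(candidates, `[[`, character(1L), "gene_id"))
  if (length(genes) != 1L) stop("mixed gene_ids: ", paste(genes, collapse = ", "))
  rank <- vapply(candidates, function(t) appris_rank(t$appris), numeric(1L))
  ulen <- vapply(candidates, function(t) diff(t$utr3), integer(1L))
  tid <- vapply(candidates, `[[`, character(1L), "transcript_id")
  ord <- order(rank, -ulen, tid)
  candidates[[ord[1L]]]
}

# ---- Conservation tracks ---------------------------------------------------

#' Conservation track from per-transcript score vectors
#'
#' The fixture-friendly conservation source: a named list of numeric vectors,
#' one per transcript, each the per-base phastCons-style score in \[0,1\].
#'
#' @param scores named list of numeric vectors (names = transcript ids).
#' @param missing_value value returned outside the transcript or for
#'   transcripts without data (default 0, i.e. unconserved).
#' @return object of class `conservation_track`.
#' @export
conservation_track_vectors <- function(scores, missing_value = 0) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  structure(list(type = "vector", scores = scores, missing_value = missing_value),
            class = "conservation_track")
}

#' Conservation track backed by a bigWig file
#'
#' Genome-anchored conservation. Each transcript queried against this track
#' must carry a `chrom_map` translating transcript blocks to genomic blocks.
#' Requires the rtracklayer package.
#'
#' @param path path to a bigWig file of per-base scores in \[0,1\].
#' @param missing_value value for positions without data (default 0).
#' @return object of class `conservation_track`.
#' @export
conservation_track_bigwig <- function(path, missing_value = 0) {
  if (!file.exists(path)) stop("bigWig file not found: ", path)
  structure(list(type = "bigwig", path = path, missing_value = missing_value),
            class = "conservation_track")
}

#' Read per-transcript conservation scores from a TSV
#'
#' Two columns: `transcript_id` and `scores` (comma-separated per-base
#' values).
#'
#' @param path TSV path.
#' @return a `conservation_track`.
#' @export
read_conservation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "scores") %in% names(df)))
    stop("conservation TSV needs columns transcript_id, scores")
  sc <- lapply(strsplit(df$scores, ","), as.numeric)
  names(sc) <- df$transcript_id
  conservation_track_vectors(sc)
}

#' Per-base conservation over a transcript interval
#'
#' Returns one score per position of `interval` (0-based, half-open in
#' transcript coordinates). The interval may extend beyond the transcript;
#' out-of-bounds positions, and positions without track data, take the
#' track's `missing_value`. Scores are clipped to \[0,1\].
#'
#' @param track a `conservation_track`.
#' @param transcript a `transcript_model`.
#' @param interval integer `c(start, end)`, 0-based half-open; may extend
#'   past the transcript ends.
#' @return numeric vector of length `end - start`.
#' @export
read_conservation <- function(track, transcript, interval) {
  stopifnot(inherits(track, "conservation_track"))
  start <- as.integer(interval[1L]); end <- as.integer(interval[2L])
  if (end < start) stop("invalid interval")
  n <- end - start
  out <- rep(track$missing_value, n)
  if (n == 0L) return(out)
  tlen <- nchar(transcript$seq)
  pos <- seq.int(start, end - 1L)           # transcript coords, 0-based
  inside <- pos >= 0L & pos < tlen
  if (!any(inside)) return(pmin(pmax(out, 0), 1))
  if (track$type == "vector") {
    v <- track$scores[[transcript$transcript_id]]
    if (!is.null(v)) {
      idx <- pos[inside] + 1L
      vals <- ifelse(idx <= length(v), v[idx], track$missing_value)
      vals[is.na(vals)] <- track$missing_value
      out[inside] <- vals
    }
  } else if (track$type == "bigwig") {
    if (is.null(transcript$chrom_map))
      stop("transcript ", transcript$transcript_id,
           " lacks a chrom_map; required for bigWig conservation")
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("package 'rtracklayer' is required for bigWig conservation tracks")
    cm <- transcript$chrom_map
    for (b in seq_len(nrow(cm))) {
      hit <- inside & pos >= cm$t_start[b] & pos < cm$t_end[b]
      if (!any(hit)) next
      off <- pos[hit] - cm$t_start[b]
      gpos <- if (identical(cm$strand[b], "-"))
        cm$g_start[b] + (cm$t_end[b] - cm$t_start[b] - 1L) - off
      else cm$g_start[b] + off
      gr <- GenomicRanges::GRanges(cm$chrom[b],
                                   IRanges::IRanges(start = min(gpos) + 1L,
                                                    end = max(gpos) + 1L))
      cov <- rtracklayer::import(rtracklayer::BigWigFile(track$path),
                                 which = gr, as = "NumericList")[[1L]]
      vals <- cov[gpos - min(gpos) + 1L]
      vals[is.na(vals)] <- track$missing_value
      out[hit] <- vals
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Write a per-transcript conservation track to TSV
#'
#' @param track a vector-backed `conservation_track`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(track, path) {
  stopifnot(track$type == "vector")
  df <- data.frame(transcript_id = names(track$scores),
                   scores = vapply(track$scores,
                                   function(v) paste(signif(v, 4L), collapse = ","),
                                   character(1L)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
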