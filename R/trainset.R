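# Training-set construction from high-throughput evidence: AGO-CLIP peak
# filtering, CLASH chimera filtering, and tissue-matched labeling of
# candidate sites against perturbation expression tables.

#' Filter AGO-CLIP peaks by peak-caller score
#'
#' Strict threshold: only peaks with `score > min_score` are retained.
#'
#' @param peaks data.frame with at least a `score` column.
#' @param min_score retention threshold (default 0.5).
#' @return filtered data.frame.
#' @export
filter_peaks <- function(peaks, min_score = 0.5) {
  out <- peaks[peaks$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter CLASH/CLEAR-CLIP chimera records
#'
#' Keeps chimeras with a favorable hybrid (MFE strictly below 0 kcal/mol)
#' supported by more than one chimeric read. Idempotent.
#'
#' @param records data.frame with columns `mfe` and `chimeric_reads`.
#' @return filtered data.frame.
#' @export
filter_chimeras <- function(records) {
  out <- records[records$mfe < 0 & records$chimeric_reads > 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlaps_any <- function(start, end, p_start, p_end) {
  # 0-based half-open interval overlap of one site against a peak set
  any(start < p_end & end > p_start)
}

#' Label candidate sites from CLIP peaks and perturbation responses
#'
#' A site is POSITIVE when it overlaps a retained AGO peak from a
#' tissue-matched library and its gene responds in the expected direction
#' with |fold change| >= 1.5 (|log2FC| >= log2(1.5)), at FDR < 0.05 where an
#' FDR is available. A site is NEGATIVE when it lies in a non-AGO background
#' peak, or when its gene is non-responsive (|log2FC| < `null_band`) in the
#' matched perturbation and the site overlaps no retained AGO peak. Other
#' sites are left unlabeled and excluded. Finally, interaction-level
#' exclusivity is enforced: a (miRNA, gene) pair with any positive site
#' never contributes negative sites, and vice versa.
#'
#' @param sites candidate-site data.frame (columns `mirna_id`,
#'   `transcript_id`, `gene_id`, `start`, `end`).
#' @param peaks retained AGO peaks: `transcript_id`, `start`, `end`,
#'   `score`, `library_id` (already passed through [filter_peaks()]).
#' @param background_peaks non-AGO background peaks, same layout (may have
#'   zero rows).
#' @param perturb perturbation records: `gene_id`, `log2_fc`, `fdr` (NA when
#'   not applicable), `direction_expected` ("down_on_transfection" or
#'   "up_on_knockdown"), `experiment_id`.
#' @param tissue_map data.frame linking `library_id` to `experiment_id`
#'   (tissue-matched pairs).
#' @param fc_threshold fold-change threshold on the linear scale
#'   (default 1.5).
#' @param null_band |log2FC| bound below which a gene counts as
#'   non-responsive (default 0.1).
#' @return `sites` with an added integer `label` column (1/0), unlabeled
#'   rows dropped.
#' @export
label_sites <- function(sites, peaks, background_peaks, perturb, tissue_map,
                        fc_threshold = 1.5, null_band = 0.1) {
  miss <- setdiff(peaks$library_id, tissue_map$library_id)
  if (length(miss))
    stop("no tissue mapping for peak library(ies): ",
         paste(unique(miss), collapse = ", "))
  lfc_min <- log2(fc_threshold)
  responds <- function(gene, exps) {
    rows <- perturb[perturb$gene_id == gene & perturb$experiment_id %in% exps, , drop = FALSE]
    if (!nrow(rows)) return(FALSE)
    dir_ok <- ifelse(rows$direction_expected == "down_on_transfection",
                     rows$log2_fc <= -lfc_min, rows$log2_fc >= lfc_min)
    fdr_ok <- is.na(rows$fdr) | rows$fdr < 0.05
    any(dir_ok & fdr_ok)
  }
  unresponsive <- function(gene, exps) {
    rows <- perturb[perturb$gene_id == gene & perturb$experiment_id %in% exps, , drop = FALSE]
    nrow(rows) > 0L && all(abs(rows$log2_fc) < null_band)
  }
  n <- nrow(sites)
  label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- sites[i, ]
    pk <- peaks[peaks$transcript_id == s$transcript_id, , drop = FALSE]
    hit <- pk[s$start < pk$end & s$end > pk$start, , drop = FALSE]
    matched_exps <- tissue_map$experiment_id[tissue_map$library_id %in% hit$library_id]
    in_background <- {
      bg <- background_peaks[background_peaks$transcript_id == s$transcript_id, , drop = FALSE]
      nrow(bg) > 0L && overlaps_any(s$start, s$end, bg$start, bg$end)
    }
    if (nrow(hit) > 0L && responds(s$gene_id, matched_exps)) {
      label[i] <- 1L
    } else if (in_background) {
      label[i] <- 0L
    } else if (nrow(hit) == 0L &&
               unresponsive(s$gene_id, tissue_map$experiment_id)) {
      label[i] <- 0L
    }
  }
  out <- sites
  out$label <- label
  out <- out[!is.na(out$label), , drop = FALSE]
  # interaction-level exclusivity: positives win, their pairs leave the negatives
  key <- paste(out$mirna_id, out$gene_id, sep = "\r")
  pos_pairs <- unique(key[out$label == 1L])
  out <- out[!(out$label == 0L & key %in% pos_pairs), , drop = FALSE]
  rownames(out) <- NULL
  out
}
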