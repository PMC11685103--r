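# Self-contained synthetic data with the statistical structure the model
# assumes: planted binding sites of known category carry the sequence
# signal, and class-shifted conservation carries the evolutionary signal.
# Duplex and folding channels are computed (not simulated) from the planted
# sequences, so multi-branch learning is exercised for real.

#' Configuration for the synthetic generator
#'
#' Defaults describe the desk-scale training world: 1200 transcripts of
#' 300-1500 nt at GC 0.5 (CDS = first 60% of the transcript, 3' UTR the
#' remainder), 10 random 22-nt miRNAs, 2000 planted positive MREs and 2000
#' scanner-verified negative loci in the 3' UTR, planted categories
#' dominated by canonical seeds, and per-base conservation at mean 0.7
#' (positives) versus 0.3 (negatives) with noise SD 0.15.
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_length_range integer `c(min, max)` lengths.
#' @param gc_content GC fraction in (0,1).
#' @param n_mirnas number of random 22-nt miRNAs.
#' @param n_pos,n_neg class sizes.
#' @param planted_categories named numeric vector of category proportions
#'   (must sum to 1).
#' @param conservation_signal list with `mean_pos`, `mean_neg`, `noise_sd`.
#' @param region region planted and scanned (`"UTR3"` or `"CDS"`).
#' @param seed RNG seed; the full dataset is a pure function of the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 1200L,
                       transcript_length_range = c(300L, 1500L),
                       gc_content = 0.5, n_mirnas = 10L,
                       n_pos = 2000L, n_neg = 2000L,
                       planted_categories = c("8mer" = 0.30, "7mer-m8" = 0.25,
                                              "7mer-A1" = 0.15, "6mer" = 0.10,
                                              "9mer" = 0.05, "centered" = 0.075,
                                              "compensatory" = 0.075),
                       conservation_signal = list(mean_pos = 0.7,
                                                  mean_neg = 0.3,
                                                  noise_sd = 0.15),
                       region = "UTR3", seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1,
            abs(sum(planted_categories) - 1) < 1e-8,
            all(names(planted_categories) %in% SITE_CATEGORIES),
            conservation_signal$mean_pos >= 0, conservation_signal$mean_pos <= 1,
            conservation_signal$mean_neg >= 0, conservation_signal$mean_neg <= 1)
  if (transcript_length_range[1L] < 150L)
    stop("transcripts shorter than 150 nt cannot host an extended MRE frame")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 transcript_length_range = as.integer(transcript_length_range),
                 gc_content = gc_content, n_mirnas = as.integer(n_mirnas),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 planted_categories = planted_categories,
                 conservation_signal = conservation_signal,
                 region = match.arg(region, c("UTR3", "CDS")),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_rna <- function(n, gc) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random transcriptome
#'
#' i.i.d. sequences at the configured GC content; each transcript's CDS is
#' the first 60% and the 3' UTR the remainder. Reproducible from the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return named list of [transcript_model()]s.
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  r <- cfg$transcript_length_range
  if (r[2L] < r[1L]) stop("degenerate transcript length range")
  set.seed(cfg$seed)
  out <- lapply(seq_len(cfg$n_transcripts), function(i) {
    L <- sample(r[1L]:r[2L], 1L)
    split <- as.integer(floor(0.6 * L))
    transcript_model(sprintf("TX%04d", i), sprintf("G%04d", i),
                     random_rna(L, cfg$gc_content),
                     cds = c(0L, split), utr3 = c(split, L))
  })
  names(out) <- vapply(out, `[[`, character(1L), "transcript_id")
  out
}

generate_mirnas <- function(cfg) {
  set.seed(cfg$seed + 7919L)
  out <- vapply(seq_len(cfg$n_mirnas), function(i) random_rna(22L, cfg$gc_content),
                character(1L))
  names(out) <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  out
}

# write complement of miRNA position i at target anchor a (0-based coords)
set_chars <- function(chars, pos0, values) {
  chars[pos0 + 1L] <- values
  chars
}

not_base <- function(avoid) sample(setdiff(RNA_ALPHABET, avoid), 1L)

#' Plant one binding site of a given category
#'
#' Writes the exact target subsequence the category requires (reverse
#' complement of the relevant miRNA positions, an A opposite position 1
#' where required) at the requested anchor, plus blocker bases that prevent
#' the locus from being classified as a stronger category. The modified
#' transcript is re-scanned and the planted category must be recovered at
#' the planted anchor, otherwise an error is thrown (callers retry at a new
#' position).
#'
#' @param transcript a [transcript_model()].
#' @param mirna named miRNA sequence.
#' @param category site category name.
#' @param region `"UTR3"` or `"CDS"`.
#' @param position anchor: 0-based transcript coordinate of the target base
#'   opposite miRNA position 1.
#' @param verify re-scan and confirm recovery (default TRUE).
#' @return list with `transcript` (modified) and `site` (truth row).
#' @export
plant_site <- function(transcript, mirna, category, region, position,
                       verify = TRUE) {
  category <- match.arg(category, SITE_CATEGORIES)
  region <- match.arg(region, c("UTR3", "CDS"))
  iv <- region_interval(transcript, region)
  a <- as.integer(position)
  if (a - 22L < iv[1L] || a + 8L > iv[2L])
    stop("anchor ", a, " leaves no room for the 30-nt window in ", region)
  occupied <- attr(transcript, "planted")
  if (!is.null(occupied) &&
      any(a - 22L < occupied$end & a + 8L > occupied$start))
    stop("planted site would overlap an existing planted site")
  m <- strsplit(normalize_rna(unname(mirna[1L])), "")[[1L]]
  comp <- function(i) rna_complement(m[i])
  chars <- strsplit(transcript$seq, "")[[1L]]
  wpos <- function(i) a - (i - 1L)       # target position opposite miRNA i
  write_wc <- function(chars, idx) {
    for (i in idx) chars <- set_chars(chars, wpos(i), comp(i))
    chars
  }
  block <- function(chars, i) set_chars(chars, wpos(i), not_base(comp(i)))
  if (category %in% c("6mer", "7mer-A1")) {
    chars <- write_wc(chars, 2:7)
    chars <- block(chars, 8L)
    chars <- set_chars(chars, a, if (category == "7mer-A1") "A" else not_base("A"))
  } else if (category %in% c("7mer-m8", "8mer")) {
    chars <- write_wc(chars, 2:8)
    chars <- block(chars, 9L)
    chars <- set_chars(chars, a, if (category == "8mer") "A" else not_base("A"))
  } else if (category == "9mer") {
    chars <- write_wc(chars, 2:10)
  } else if (category == "centered") {
    chars <- write_wc(chars, 4:14)
    chars <- block(chars, 2L)
  } else { # compensatory
    chars <- write_wc(chars, 2:7)
    q <- sample(2:7, 1L)
    wobble_ok <- m[q] %in% c("G", "U")
    if (wobble_ok && runif(1L) < 0.5) {
      chars <- set_chars(chars, wpos(q), if (m[q] == "G") "U" else "G")
    } else {
      avoid <- c(comp(q), if (m[q] == "G") "U", if (m[q] == "U") "G")
      chars <- set_chars(chars, wpos(q), not_base(avoid))
    }
    chars <- write_wc(chars, 13:16)
    chars <- block(chars, 10L)        # keep the locus out of the centered class
    chars <- set_chars(chars, a, not_base("A"))
  }
  out <- transcript
  out$seq <- paste(chars, collapse = "")
  mirna_id <- if (!is.null(names(mirna))) names(mirna)[1L] else "miRNA"
  span <- site_span(category, a)
  site <- data.frame(mirna_id = mirna_id, transcript_id = out$transcript_id,
                     gene_id = out$gene_id, region = region,
                     start = span[1L], end = span[2L], anchor = a,
                     category = category, stringsAsFactors = FALSE)
  if (verify) {
    found <- scan_region(mirna, out, region, mirna_id = mirna_id)
    hit <- found[found$anchor == a, , drop = FALSE]
    if (nrow(hit) != 1L || hit$category != category)
      stop("planted ", category, " not recovered at anchor ", a,
           " (context interference)")
  }
  attr(out, "planted") <- rbind(occupied,
                                data.frame(start = a - 22L, end = a + 8L))
  list(transcript = out, site = site)
}

#' Generate the labeled MRE feature dataset
#'
#' Plants `n_pos` sites (categories per the configured proportions) at
#' non-overlapping loci, overwrites their 150-nt conservation with the
#' positive-class distribution, then draws `n_neg` scanner-verified
#' site-free loci as negatives on the background conservation. All five
#' feature channels are built with the real feature pipeline.
#'
#' @param cfg a [sim_config()].
#' @param max_tries placement retries per site before giving up.
#' @return list with `bundles` (feature bundles), `labels` (0/1), `truth`
#'   (per-example data.frame), `transcripts`, `mirnas`, `track`.
#' @export
generate_mre_dataset <- function(cfg, max_tries = 60L) {
  stopifnot(inherits(cfg, "sim_config"))
  transcripts <- generate_transcriptome(cfg)
  mirnas <- generate_mirnas(cfg)
  cs <- cfg$conservation_signal
  set.seed(cfg$seed + 104729L)
  cons <- lapply(transcripts, function(tr)
    pmin(pmax(rnorm(nchar(tr$seq), cs$mean_neg, cs$noise_sd), 0), 1))
  names(cons) <- names(transcripts)
  truth <- list(); n_placed <- 0L
  cats <- sample(names(cfg$planted_categories), cfg$n_pos, replace = TRUE,
                 prob = cfg$planted_categories)
  for (j in seq_len(cfg$n_pos)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ti <- sample(length(transcripts), 1L)
      tr <- transcripts[[ti]]
      iv <- region_interval(tr, cfg$region)
      lo <- iv[1L] + 22L; hi <- iv[2L] - 8L
      if (hi <= lo) next
      a <- sample(lo:(hi - 1L), 1L)
      res <- tryCatch(plant_site(tr, mirnas[sample(length(mirnas), 1L)],
                                 cats[j], cfg$region, a),
                      error = function(e) NULL)
      if (is.null(res)) next
      transcripts[[ti]] <- res$transcript
      win <- c(max(iv[1L], a - 82L), min(iv[2L], a + 68L))
      idx <- (win[1L] + 1L):win[2L]
      cons[[tr$transcript_id]][idx] <-
        pmin(pmax(rnorm(length(idx), cs$mean_pos, cs$noise_sd), 0), 1)
      truth[[length(truth) + 1L]] <- cbind(res$site, label = 1L)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place positive site ", j, " after ",
                      max_tries, " tries; enlarge the transcriptome")
  }
  # negatives: site-free windows under the background conservation
  scan_cache <- new.env(parent = emptyenv())
  get_sites <- function(mid, tr) {
    key <- paste(mid, tr$transcript_id)
    if (is.null(scan_cache[[key]]))
      scan_cache[[key]] <- scan_region(mirnas[mid], tr, cfg$region, mirna_id = mid)
    scan_cache[[key]]
  }
  planted_iv <- lapply(transcripts, function(tr) attr(tr, "planted"))
  for (j in seq_len(cfg$n_neg)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ti <- sample(length(transcripts), 1L)
      tr <- transcripts[[ti]]
      iv <- region_interval(tr, cfg$region)
      lo <- iv[1L] + 22L; hi <- iv[2L] - 8L
      if (hi <= lo) next
      a <- sample(lo:(hi - 1L), 1L)
      win <- c(a - 22L, a + 8L)
      occ <- planted_iv[[tr$transcript_id]]
      if (!is.null(occ) && any(win[1L] < occ$end + 53L & win[2L] > occ$start - 53L))
        next  # keep clear of planted windows and their conservation halo
      mid <- names(mirnas)[sample(length(mirnas), 1L)]
      sites <- get_sites(mid, tr)
      if (nrow(sites) && any(win[1L] < sites$end & win[2L] > sites$start)) next
      truth[[length(truth) + 1L]] <- data.frame(
        mirna_id = mid, transcript_id = tr$transcript_id, gene_id = tr$gene_id,
        region = cfg$region, start = a - 6L, end = a, anchor = a,
        category = "none", label = 0L, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place negative locus ", j)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  track <- conservation_track_vectors(cons)
  bundles <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    build_bundle(row, mirnas[row$mirna_id], transcripts[[row$transcript_id]],
                 track)
  })
  list(bundles = bundles, labels = truth$label, truth = truth,
       transcripts = transcripts, mirnas = mirnas, track = track)
}

#' Generate interaction-level features for the meta-learner
#'
#' Per-region maxima drawn from Beta(5,2) for positives and Beta(2,5) for
#' negatives (configurable), emulating the separation the first layer
#' produces between functional and non-functional interactions.
#'
#' @param n_pos,n_neg class sizes.
#' @param shape_pos,shape_neg Beta shape pairs.
#' @param seed RNG seed.
#' @return list with `features` (data.frame) and `labels`.
#' @export
generate_interaction_dataset <- function(n_pos = 1000L, n_neg = 1000L,
                                         shape_pos = c(5, 2),
                                         shape_neg = c(2, 5), seed = 1L) {
  set.seed(seed)
  n <- n_pos + n_neg
  lab <- c(rep(1L, n_pos), rep(0L, n_neg))
  draw <- function(k, sh) rbeta(k, sh[1L], sh[2L])
  features <- data.frame(
    mirna_id = sprintf("mir-%04d", seq_len(n)),
    gene_id = sprintf("G%04d", seq_len(n)),
    max_utr3_score = c(draw(n_pos, shape_pos), draw(n_neg, shape_neg)),
    max_cds_score = c(draw(n_pos, shape_pos), draw(n_neg, shape_neg)),
    stringsAsFactors = FALSE)
  list(features = features, labels = lab)
}

#' Generate a perturbation-response fixture
#'
#' Target genes respond with log2 fold changes N(-effect, 0.5) under
#' transfection (or N(+effect, 0.5) under knockdown); non-targets draw from
#' N(0, 0.5).
#'
#' @param targets,nontargets gene-id character vectors.
#' @param effect mean |log2FC| shift of true targets (>= 0).
#' @param seed RNG seed.
#' @param direction `"down_on_transfection"` or `"up_on_knockdown"`.
#' @param experiment_id experiment label.
#' @return perturbation data.frame (`gene_id`, `log2_fc`, `fdr`,
#'   `direction_expected`, `experiment_id`).
#' @export
generate_perturbation_fixture <- function(targets, nontargets, effect,
                                          seed = 1L,
                                          direction = c("down_on_transfection",
                                                        "up_on_knockdown"),
                                          experiment_id = "sim_exp") {
  direction <- match.arg(direction)
  stopifnot(effect >= 0)
  set.seed(seed)
  mu <- if (direction == "down_on_transfection") -effect else effect
  data.frame(
    gene_id = c(targets, nontargets),
    log2_fc = c(rnorm(length(targets), mu, 0.5),
                rnorm(length(nontargets), 0, 0.5)),
    fdr = NA_real_,
    direction_expected = direction,
    experiment_id = experiment_id,
    stringsAsFactors = FALSE)
}
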