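test_that("generate_transcriptome is seed-reproducible with stated lengths and GC", {
  cfg <- sim_config(n_transcripts = 100, transcript_length_range = c(300, 1500),
                    gc_content = 0.5, seed = 1)
  t1 <- generate_transcriptome(cfg)
  t2 <- generate_transcriptome(cfg)
  expect_identical(lapply(t1, `[[`, "seq"), lapply(t2, `[[`, "seq"))
  lens <- vapply(t1, function(tr) nchar(tr$seq), integer(1))
  expect_true(all(lens >= 300 & lens <= 1500))
  gc <- mean(unlist(lapply(t1, function(tr) {
    ch <- strsplit(tr$seq, "")[[1]]
    mean(ch %in% c("G", "C"))
  })))
  expect_lt(abs(gc - 0.5), 0.03)
  expect_error(generate_transcriptome(
    sim_config(transcript_length_range = c(500, 400))), "degenerate")
})

test_that("plant_site writes recoverable sites and region tags", {
  set.seed(12)
  let7 <- c("let-7a-5p" = "UGAGGUAGUAGGUUGUAUAGUU")
  tr <- random_transcript(800, id = "p1")
  res <- plant_site(tr, let7, "8mer", "UTR3", tr$utr3[1] + 60)
  s <- scan_region(let7, res$transcript, "UTR3")
  hit <- s[s$anchor == res$site$anchor, ]
  expect_identical(hit$category, "8mer")
  expect_identical(res$site$region, "UTR3")
  # centered plants are recovered as centered, not canonical
  res2 <- plant_site(res$transcript, let7, "centered", "UTR3",
                     tr$utr3[1] + 150)
  s2 <- scan_region(let7, res2$transcript, "UTR3")
  expect_identical(s2$category[s2$anchor == res2$site$anchor], "centered")
  # overlap with an existing planted window is rejected
  expect_error(plant_site(res2$transcript, let7, "6mer", "UTR3",
                          tr$utr3[1] + 155), "overlap")
  # CDS plants carry the CDS tag
  res3 <- plant_site(tr, let7, "7mer-m8", "CDS", 120)
  expect_identical(res3$site$region, "CDS")
  expect_identical(scan_region(let7, res3$transcript, "CDS")$category, "7mer-m8")
})

test_that("generate_mre_dataset delivers exact counts, recoverable truth, seed control", {
  cfg <- sim_config(n_transcripts = 80, n_pos = 60, n_neg = 60, n_mirnas = 4,
                    seed = 7)
  ds <- generate_mre_dataset(cfg)
  expect_length(ds$bundles, 120)
  expect_equal(sum(ds$labels == 1), 60)
  expect_equal(sum(ds$labels == 0), 60)
  pos <- ds$truth[ds$truth$label == 1, ]
  rec <- vapply(seq_len(nrow(pos)), function(i) {
    s <- scan_region(ds$mirnas[pos$mirna_id[i]],
                     ds$transcripts[[pos$transcript_id[i]]],
                     pos$region[i], mirna_id = pos$mirna_id[i])
    any(s$anchor == pos$anchor[i] & s$category == pos$category[i])
  }, logical(1))
  expect_true(all(rec))
  # negatives: no scanned site overlaps the negative window
  neg <- ds$truth[ds$truth$label == 0, ]
  clean <- vapply(seq_len(nrow(neg)), function(i) {
    s <- scan_region(ds$mirnas[neg$mirna_id[i]],
                     ds$transcripts[[neg$transcript_id[i]]],
                     neg$region[i], mirna_id = neg$mirna_id[i])
    !any(neg$anchor[i] - 22 < s$end & neg$anchor[i] + 8 > s$start)
  }, logical(1))
  expect_true(all(clean))
  # different seeds give different data, same seed identical
  ds_b <- generate_mre_dataset(cfg)
  expect_identical(ds$truth, ds_b$truth)
  cfg2 <- sim_config(n_transcripts = 80, n_pos = 60, n_neg = 60, n_mirnas = 4,
                     seed = 8)
  ds2 <- generate_mre_dataset(cfg2)
  expect_false(identical(ds$truth, ds2$truth))
})

test_that("class-conditional conservation separation matches the config", {
  cfg <- sim_config(n_transcripts = 60, n_pos = 40, n_neg = 40, n_mirnas = 3,
                    seed = 3)
  ds <- generate_mre_dataset(cfg)
  mid <- function(b) mean(b$conservation[61:90])  # the 30-nt window itself
  mpos <- mean(vapply(ds$bundles[ds$labels == 1], mid, numeric(1)))
  mneg <- mean(vapply(ds$bundles[ds$labels == 0], mid, numeric(1)))
  expect_lt(abs(mpos - 0.7), 0.05)
  expect_lt(abs(mneg - 0.3), 0.05)
})

test_that("interaction dataset matches the Beta mixture and is seed-stable", {
  ds <- generate_interaction_dataset(n_pos = 1000, n_neg = 1000, seed = 11)
  expect_equal(sum(ds$labels), 1000)
  mpos <- mean(ds$features$max_utr3_score[ds$labels == 1])
  mneg <- mean(ds$features$max_utr3_score[ds$labels == 0])
  expect_lt(abs(mpos - 5 / 7), 0.03)
  expect_lt(abs(mneg - 2 / 7), 0.03)
  ds2 <- generate_interaction_dataset(n_pos = 1000, n_neg = 1000, seed = 11)
  expect_identical(ds$features, ds2$features)
})

test_that("perturbation fixtures shift targets in the requested direction", {
  fx <- generate_perturbation_fixture(paste0("t", 1:200), paste0("n", 1:2000),
                                      effect = 1, seed = 5)
  expect_lt(mean(fx$log2_fc[startsWith(fx$gene_id, "t")]), -0.8)
  expect_lt(abs(mean(fx$log2_fc[startsWith(fx$gene_id, "n")])), 0.05)
  fx2 <- generate_perturbation_fixture("a", "b", effect = 2, seed = 5,
                                       direction = "up_on_knockdown")
  expect_identical(fx2$direction_expected[1], "up_on_knockdown")
  expect_error(generate_perturbation_fixture("a", "b", effect = -1), "effect")
})
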