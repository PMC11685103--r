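let7 <- c("let-7a-5p" = "UGAGGUAGUAGGUUGUAUAGUU")

test_that("anchor_window places the A1-opposite base at window offset 22", {
  site <- data.frame(anchor = 100L)
  w <- anchor_window(site, region = c(0L, 400L))
  expect_equal(w$window, c(78L, 108L))
  expect_equal(w$upflank, c(18L, 78L))
  expect_equal(w$downflank, c(108L, 168L))
})

test_that("build_extended_mre pads with N outside the region", {
  tr <- transcript_model("t1", "g1", strrep("G", 400), cds = c(0, 0), utr3 = c(0, 400))
  # ample context: no N
  full <- build_extended_mre(anchor_window(data.frame(anchor = 200L), c(0L, 400L)), tr)
  expect_equal(nchar(full), 150)
  expect_false(grepl("N", full))
  # window starts at 3: upflank covers [-57, 3) -> 57 leading Ns
  w <- anchor_window(data.frame(anchor = 25L), c(0L, 400L))
  s <- build_extended_mre(w, tr)
  expect_equal(substr(s, 1, 57), strrep("N", 57))
  expect_identical(substr(s, 58, 58), "G")
  # window ends at 403, region at 400: 3 + 60 trailing Ns
  w2 <- anchor_window(data.frame(anchor = 395L), c(0L, 400L))
  s2 <- build_extended_mre(w2, tr)
  expect_equal(substr(s2, 88, 150), strrep("N", 63))
  expect_identical(substr(s2, 87, 87), "G")
})

test_that("region boundaries clip windows independently per region", {
  seq <- paste0(strrep("A", 60), strrep("C", 60))
  tr <- transcript_model("t1", "g1", seq, cds = c(0, 60), utr3 = c(60, 120))
  s_cds <- build_extended_mre(anchor_window(data.frame(anchor = 50L), c(0L, 60L)), tr)
  s_utr <- build_extended_mre(anchor_window(data.frame(anchor = 110L), c(60L, 120L)), tr)
  expect_false(grepl("C", s_cds))  # CDS frame never reads UTR sequence
  expect_false(grepl("A", s_utr))
})

test_that("build_chimera pads the miRNA slot to 23 and rejects longer input", {
  w30 <- strrep("G", 30)
  chim <- build_chimera(let7, w30)
  expect_equal(nchar(chim), 53)
  expect_identical(substr(chim, 23, 23), "N")   # 22-nt miRNA, one pad slot
  chim23 <- build_chimera(c(m = strrep("U", 23)), w30)
  expect_false(grepl("N", chim23))
  expect_error(build_chimera(c(m = strrep("U", 24)), w30), "truncate")
  expect_error(build_chimera(let7, strrep("G", 29)), "30")
})

test_that("one-hot encoding follows the alphabet and decodes back", {
  expect_equal(one_hot_encode("ACGU", c("A", "C", "G", "U")), diag(4),
               ignore_attr = TRUE)
  expect_equal(unname(one_hot_encode("N", c("A", "C", "G", "U"))),
               matrix(0, 1, 4))
  m <- one_hot_encode("(.)", c("(", ")", ".", "&"))
  expect_equal(unname(m), rbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 1, 0, 0)))
  expect_error(one_hot_encode("A", character()), "alphabet")
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "U"), 40, TRUE), collapse = "")
  expect_identical(one_hot_decode(one_hot_encode(s, c("A", "C", "G", "U"))), s)
})

test_that("conservation_profile zeroes padding and clips to [0,1]", {
  tr <- transcript_model("t1", "g1", strrep("A", 300), cds = c(0, 0), utr3 = c(0, 300))
  track <- conservation_track_vectors(list(t1 = rep(0.8, 300)))
  w <- anchor_window(data.frame(anchor = 150L), c(0L, 300L))
  expect_equal(conservation_profile(w, tr, track), rep(0.8, 150))
  # clipped left flank: frame starts before the region
  w2 <- anchor_window(data.frame(anchor = 72L), c(0L, 300L))  # upflank from -10
  v2 <- conservation_profile(w2, tr, track)
  expect_equal(v2[1:10], rep(0, 10))
  expect_equal(v2[11:150], rep(0.8, 140))
  track3 <- conservation_track_vectors(list(t1 = rep(1.5, 300)))
  expect_equal(conservation_profile(w, tr, track3), rep(1, 150))
})

test_that("build_bundle yields the contracted shapes, deterministically", {
  set.seed(31)
  tr <- random_transcript(500, id = "t1")
  res <- plant_site(tr, let7, "8mer", "UTR3", tr$utr3[1] + 60)
  track <- constant_track(list(res$transcript), 0.6)
  b <- build_bundle(res$site, let7, res$transcript, track)
  expect_s3_class(b, "feature_bundle")
  expect_equal(dim(b$extended_mre), c(150L, 4L))
  expect_equal(dim(b$chimera), c(53L, 4L))
  expect_equal(dim(b$duplex), c(60L, 4L))
  expect_equal(dim(b$fold), c(150L, 3L))
  expect_equal(dim(b$conservation), c(150L, 1L))
  for (f in c("extended_mre", "chimera", "duplex", "fold")) {
    expect_true(all(rowSums(b[[f]]) %in% c(0, 1)), label = f)
  }
  expect_true(all(b$conservation >= 0 & b$conservation <= 1))
  b2 <- build_bundle(res$site, let7, res$transcript, track)
  expect_identical(b, b2)
})

test_that("edge sites produce all-zero one-hot rows and zero conservation", {
  tr <- transcript_model("t1", "g1", strrep("G", 200), cds = c(0, 0), utr3 = c(0, 200))
  track <- constant_track(list(tr), 0.9)
  site <- data.frame(mirna_id = "m", transcript_id = "t1", gene_id = "g1",
                     region = "UTR3", anchor = 25L, category = "6mer",
                     start = 19L, end = 25L)
  b <- build_bundle(site, let7, tr, track)
  # upflank starts at 25-22-60 = -57: those rows are all-zero, conservation 0
  expect_true(all(b$extended_mre[1:57, ] == 0))
  expect_true(all(b$conservation[1:57] == 0))
  expect_true(all(b$conservation[58:150] == 0.9))
})

test_that("stack_bundles produces n x length x channel arrays", {
  tr <- transcript_model("t1", "g1", strrep("G", 200), cds = c(0, 0), utr3 = c(0, 200))
  track <- constant_track(list(tr), 0.5)
  site <- data.frame(region = "UTR3", anchor = 100L)
  bundles <- list(build_bundle(site, let7, tr, track),
                  build_bundle(site, let7, tr, track))
  X <- stack_bundles(bundles)
  expect_equal(dim(X$mre), c(2L, 150L, 4L))
  expect_equal(dim(X$conservation), c(2L, 150L, 1L))
  expect_equal(X$mre[1, , ], bundles[[1]]$extended_mre, ignore_attr = TRUE)
})
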