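test_that("read_fasta normalizes to the RNA alphabet and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m1", "ACGT", ">a", "acgu", ">b", "GGxG"), fa)
  seqs <- read_fasta(fa)
  expect_identical(names(seqs), c("m1", "a", "b"))
  expect_identical(unname(seqs), c("ACGU", "ACGU", "GGNG"))
})

test_that("read_fasta rejects duplicates, empty and malformed input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU", ">a", "GG"), fa)
  expect_error(read_fasta(fa), "duplicate")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), "empty")
  writeLines(c("ACGT", ">a", "ACGU"), fa)
  expect_error(read_fasta(fa), "line 1")
})

test_that("FASTA round-trip reproduces ids and sequences exactly", {
  set.seed(11)
  seqs <- vapply(1:5, function(i) random_mirna_seq(30), character(1))
  names(seqs) <- paste0("s", 1:5)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})

test_that("transcript_model validates intervals", {
  expect_error(transcript_model("t", "g", "ACGUACGU", cds = c(0, 10), utr3 = c(0, 0)),
               "out of bounds")
  expect_error(transcript_model("t", "g", "ACGUACGUAC", cds = c(2, 8), utr3 = c(4, 10)),
               "at or after")
  tr <- transcript_model("t", "g", "acgtACGT", cds = c(0, 4), utr3 = c(4, 8))
  expect_identical(tr$seq, "ACGUACGU")
})

test_that("read_conservation pads, clips and honors interval length", {
  tr <- transcript_model("t1", "g1", strrep("A", 200), cds = c(0, 120), utr3 = c(120, 200))
  track <- conservation_track_vectors(list(t1 = rep(0.5, 200)))
  expect_equal(read_conservation(track, tr, c(0, 150)), rep(0.5, 150))
  v <- read_conservation(track, tr, c(-10, 20))
  expect_length(v, 30)
  expect_equal(v[1:10], rep(0, 10))
  expect_equal(v[11:30], rep(0.5, 20))
  track2 <- conservation_track_vectors(list(t1 = c(0.1, 0.9)))
  expect_equal(read_conservation(track2, tr, c(0, 2)), c(0.1, 0.9))
  # values outside [0,1] are clipped
  track3 <- conservation_track_vectors(list(t1 = rep(1.7, 200)))
  expect_equal(read_conservation(track3, tr, c(0, 5)), rep(1, 5))
  # length contract holds for arbitrary clipping
  for (iv in list(c(-50, 10), c(190, 260), c(-5, 250))) {
    expect_length(read_conservation(track, tr, iv), iv[2] - iv[1])
  }
})

test_that("bigWig track without a chrom_map is a configuration error", {
  fake <- withr::local_tempfile(fileext = ".bw")
  writeLines("x", fake)
  track <- conservation_track_bigwig(fake)
  tr <- transcript_model("t1", "g1", strrep("A", 50), cds = c(0, 30), utr3 = c(30, 50))
  expect_error(read_conservation(track, tr, c(0, 10)), "chrom_map")
})

test_that("conservation TSV round-trips through the vector track", {
  track <- conservation_track_vectors(list(t1 = c(0.25, 0.5, 1), t2 = rep(0.1, 4)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_conservation_tsv(track, tsv)
  back <- read_conservation_tsv(tsv)
  expect_equal(back$scores$t1, c(0.25, 0.5, 1))
  expect_equal(back$scores$t2, rep(0.1, 4))
})

test_that("select_principal_transcript applies APPRIS, 3'UTR length, then id", {
  mk <- function(id, appris, ulen) {
    transcript_model(id, "g1", strrep("A", 1000), cds = c(0, 400),
                     utr3 = c(400, 400 + ulen), appris = appris)
  }
  t1 <- mk("t1", "PRINCIPAL:1", 100); t2 <- mk("t2", "PRINCIPAL:2", 500)
  expect_identical(select_principal_transcript(list(t1, t2))$transcript_id, "t1")
  t2b <- mk("t2", "PRINCIPAL:1", 500)
  expect_identical(select_principal_transcript(list(t1, t2b))$transcript_id, "t2")
  u1 <- mk("t1", NA, 100); u2 <- mk("t2", NA, 100)
  expect_identical(select_principal_transcript(list(u1, u2))$transcript_id, "t1")
  expect_error(select_principal_transcript(list()), "no candidate")
  bad <- mk("t3", NA, 10); bad$gene_id <- "g2"
  expect_error(select_principal_transcript(list(t1, bad)), "mixed")
})

test_that("select_principal_transcript is order-independent", {
  set.seed(3)
  cand <- lapply(1:6, function(i) {
    transcript_model(paste0("t", i), "g1", strrep("A", 1000), cds = c(0, 300),
                     utr3 = c(300, 300 + sample(50:600, 1)),
                     appris = sample(c("PRINCIPAL:1", "PRINCIPAL:3",
                                       "ALTERNATIVE:1", NA), 1))
  })
  ref <- select_principal_transcript(cand)$transcript_id
  for (k in 1:10) {
    expect_identical(select_principal_transcript(sample(cand))$transcript_id, ref)
  }
})
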