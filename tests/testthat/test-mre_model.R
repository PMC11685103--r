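# Architecture contracts and small-scale training behavior.

make_tiny_data <- function(n = 40, seed = 5) {
  # fabricated branch tensors with a simple separable signal in every branch
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  mk <- function(L, C) {
    arr <- array(runif(n * L * C) * 0.5, c(n, L, C))
    arr[y == 1, seq_len(min(10, L)), 1] <- arr[y == 1, seq_len(min(10, L)), 1] + 0.5
    arr
  }
  list(X = list(mre = mk(150, 4), chimera = mk(53, 4), duplex = mk(60, 4),
                fold = mk(150, 3), conservation = mk(150, 1)),
       y = y)
}

test_that("the default model exposes the reference architecture", {
  model <- build_model(model_spec("UTR3", seed = 1))
  s <- model_summary(model)
  expect_setequal(unique(s$branch), c("mre", "chimera", "duplex", "fold",
                                      "conservation", "head"))
  expect_equal(attr(s, "dense_nodes"), c(90L, 55L, 35L))
  expect_true(all(attr(s, "gru_units") == 24L))
  expect_equal(attr(s, "pool_size"), 2L)
  expect_equal(attr(s, "dropout"), 0.1)
  dense <- s[s$type == "dense", "out_channels"]
  expect_equal(dense, c(90L, 55L, 35L))
  expect_equal(s[s$type == "sigmoid", "out_channels"], 1L)
  # reference filter counts and strides per branch
  conv <- s[s$type == "conv", ]
  expect_equal(conv$out_channels[conv$branch == "mre"], c(35L, 50L))
  expect_equal(conv$stride[conv$branch == "chimera"], c(2L, 3L, 4L))
  expect_equal(conv$out_channels[conv$branch == "conservation"], c(20L, 40L, 60L))
})

test_that("every layer length matches the closed-form conv/pool arithmetic", {
  model <- build_model(model_spec("UTR3", seed = 1))
  s <- model_summary(model)
  for (br in unique(s$branch)) {
    rows <- s[s$branch == br & s$type %in% c("input", "conv", "maxpool"), ]
    if (!nrow(rows)) next
    L <- rows$out_length[rows$type == "input"]
    for (i in which(rows$type != "input")) {
      r <- rows[i, ]
      if (r$type == "conv") L <- (L - r$kernel) %/% r$stride + 1
      if (r$type == "maxpool") L <- L %/% 2
      expect_equal(r$out_length, L, label = paste(br, r$layer))
      expect_gte(L, 1)
    }
  }
})

test_that("impossible conv arithmetic is rejected with the offending layer", {
  bad <- branch_spec("chimera", c(16, 32, 62), c(6, 6, 6), c(2, 3, 4))
  expect_error(build_model(model_spec("UTR3", branches = list(bad), seed = 1)),
               "conv layer 3")
})

test_that("ablation_variants yields 8 buildable uniquely-named variants", {
  variants <- ablation_variants(model_spec("UTR3", seed = 1))
  expect_length(variants, 8)
  expect_false(anyDuplicated(names(variants)) > 0)
  expect_setequal(names(variants),
                  c("mre_only", "chimera_only", "duplex_only", "fold_only",
                    "conservation_only", "chimera+conservation",
                    "chimera+duplex", "no_fold"))
  for (nm in names(variants)) {
    m <- build_model(variants[[nm]])
    expect_s3_class(m, "mre_model")
  }
  single <- build_model(variants$chimera_only)
  s <- model_summary(single)
  expect_equal(setdiff(unique(s$branch), "head"), "chimera")
  expect_equal(attr(s, "dense_nodes"), c(90L, 55L, 35L))
})

test_that("training rejects single-class labels and reports history", {
  td <- make_tiny_data()
  spec <- model_spec("UTR3", dense_nodes = c(12, 8, 5), seed = 2)
  model <- build_model(spec)
  expect_error(train_mre_model(model, td$X, rep(1, length(td$y))), "single class")
  fit <- train_mre_model(model, td$X, td$y, epochs = 2)
  expect_s3_class(fit$history, "data.frame")
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("same seed reproduces the epoch-1 training loss exactly", {
  td <- make_tiny_data()
  spec <- model_spec("UTR3", dense_nodes = c(12, 8, 5), seed = 7)
  f1 <- train_mre_model(build_model(spec), td$X, td$y, epochs = 1)
  f2 <- train_mre_model(build_model(spec), td$X, td$y, epochs = 1)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
})

test_that("scores lie in [0,1], preserve order, and are batch-size invariant", {
  td <- make_tiny_data(n = 30)
  spec <- model_spec("UTR3", dense_nodes = c(12, 8, 5), seed = 3)
  fit <- train_mre_model(build_model(spec), td$X, td$y, epochs = 2)
  p1 <- score_mres(fit, td$X, batch_size = 30)
  p2 <- score_mres(fit, td$X, batch_size = 7)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_lt(max(abs(p1 - p2)), 1e-5)
})

test_that("shape mismatches are rejected naming the branch", {
  spec <- model_spec("UTR3", branches = "chimera", seed = 1)
  model <- build_model(spec)
  expect_error(score_mres(model, list(chimera = array(0, c(2, 50, 4)))),
               "chimera")
  expect_error(score_mres(model, list(mre = array(0, c(2, 150, 4)))),
               "missing input")
})

test_that("models round-trip through the serialized directory layout", {
  td <- make_tiny_data(n = 24)
  spec <- model_spec("UTR3", branches = c("chimera", "conservation"),
                     dense_nodes = c(10, 6, 4), seed = 11)
  fit <- train_mre_model(build_model(spec), td$X, td$y, epochs = 2)
  dir <- withr::local_tempdir()
  write_mre_model(fit, dir)
  back <- read_mre_model(dir)
  Xs <- list(chimera = td$X$chimera, conservation = td$X$conservation)
  expect_equal(score_mres(back, Xs), score_mres(fit, Xs), tolerance = 1e-12)
})
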