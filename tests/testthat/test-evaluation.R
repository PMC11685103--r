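test_that("binary_metrics on the worked four-point example", {
  m <- binary_metrics(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), threshold = 0.5)
  expect_equal(m$auc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_identical(m$recall, m$sensitivity)
  expect_error(binary_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC equals brute-force pairwise counting, including ties", {
  set.seed(14)
  for (rep in 1:15) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)   # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(rank_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("label-independent scores give AUC near 0.5", {
  set.seed(50)
  scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(rank_auc(scores, labels) - 0.5), 0.03)
})

test_that("bootstrap CI brackets the point AUC and is seeded", {
  set.seed(15)
  scores <- c(rnorm(100, 1), rnorm(100))
  labels <- rep(c(1, 0), each = 100)
  m1 <- binary_metrics(scores, labels, ci_reps = 200, ci_seed = 9)
  m2 <- binary_metrics(scores, labels, ci_reps = 200, ci_seed = 9)
  expect_identical(m1$ci_auc, m2$ci_auc)
  expect_true(m1$ci_auc[1] <= m1$auc && m1$auc <= m1$ci_auc[2])
})

test_that("youden_threshold equals exhaustive search, with documented ties", {
  expect_equal(youden_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1)), 0.6)
  expect_warning(j <- youden_threshold(rep(0.3, 6), rep(c(0, 1), 3)), "not positive")
  expect_equal(j, 0.3)
  expect_warning(youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)),
                 "not positive")
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(8:50, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(youden_threshold(scores, labels), oracle_youden(scores, labels))
  }
})

test_that("wilcoxon matches the exact enumeration oracle for n <= 8", {
  set.seed(31)
  for (rep in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties
    got <- wilcoxon_ranksum(x, y)
    want <- oracle_wilcoxon(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value)
    expect_true(got$exact)
  }
})

test_that("wilcoxon normal approximation behaves for larger samples", {
  set.seed(32)
  x <- rnorm(60, 1); y <- rnorm(60)
  got <- wilcoxon_ranksum(x, y)
  expect_false(got$exact)
  expect_lt(got$p_value, 1e-4)
  # agrees with the base-R normal-approximation implementation
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-10)
})

test_that("one-sided KS detects a downward shift and not its absence", {
  set.seed(33)
  x <- rnorm(200, -1); y <- rnorm(200)
  expect_lt(ks_one_sided(x, y)$p_value, 1e-6)
  expect_gt(ks_one_sided(y, x)$p_value, 0.5)
})

test_that("functional_efficacy flags shifted target groups against no_site", {
  set.seed(34)
  fx <- generate_perturbation_fixture(paste0("t", 1:100), paste0("n", 1:1000),
                                      effect = 1, seed = 34)
  groups <- list(canonical = paste0("t", 1:60),
                 non_canonical = paste0("t", 61:100),
                 no_site = paste0("n", 1:1000))
  res <- functional_efficacy(fx, groups)
  expect_setequal(res$group, c("canonical", "non_canonical"))
  expect_true(all(res$p_value < 1e-6))
  expect_true(all(res$median_lfc < res$median_lfc_ref))
  # input validation
  expect_error(functional_efficacy(fx, list(canonical = "t1")), "no_site")
  expect_error(functional_efficacy(fx, list(canonical = character(0),
                                            no_site = "n1")), "empty group")
  expect_error(functional_efficacy(fx, list(canonical = c("t1", "t2"),
                                            no_site = c("t2", "n1"))),
               "disjoint")
  res_ks <- functional_efficacy(fx, groups, test = "ks")
  expect_true(all(res_ks$p_value < 1e-4))
})

test_that("top_n caps the evaluated group in the order given", {
  fx <- generate_perturbation_fixture(paste0("t", 1:50), paste0("n", 1:200),
                                      effect = 1, seed = 35)
  groups <- list(targets = paste0("t", 1:50), no_site = paste0("n", 1:200))
  res <- functional_efficacy(fx, groups, top_n = 10)
  expect_equal(res$n, 10)
})
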