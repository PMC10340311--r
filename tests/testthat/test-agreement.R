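test_that("compute_ahi divides events by total sleep time", {
  hyp <- hypnogram(rep(c("W", "N2"), c(4, 720)))    # 6 h sleep
  expect_equal(compute_ahi(event_list(), hyp), 0)
  expect_equal(compute_ahi(40, hyp), 40 / 6, tolerance = 1e-9)
  hyp8 <- hypnogram(rep("N2", 960))                 # 8 h sleep
  expect_equal(compute_ahi(144, hyp8), 18)
  # linear in event count at fixed sleep time
  expect_equal(compute_ahi(80, hyp), 2 * compute_ahi(40, hyp))
})

test_that("bland_altman returns bias and 1.96-SD limits", {
  ba <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(unname(ba$loa), c(-1.96, 1.96))
  # est = ref: zero-width limits
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)
  # translation shifts bias, not width
  ba1 <- bland_altman(c(3, 7, 11), c(1, 2, 3))
  ba2 <- bland_altman(c(3, 7, 11) + 5, c(1, 2, 3))
  expect_equal(ba2$bias, ba1$bias + 5)
  expect_equal(ba2$loa_half_width, ba1$loa_half_width)
})

test_that("spearman_r matches the rank-formula oracle and handles ties", {
  expect_equal(spearman_r(1:6, c(2, 4, 9, 11, 30, 31))$r, 1)
  expect_equal(spearman_r(1:6, rev(1:6))$r, -1)
  expect_equal(spearman_r(1:6, c(2, 4, 9, 11, 30, 31))$p, 0)
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 6)
  expect_equal(spearman_r(x, y)$r, oracle_spearman(x, y), tolerance = 1e-12)
  expect_true(is.na(spearman_r(rep(1, 5), 1:5)$r))
  # the AHI < 30 subgroup filter drops large-reference pairs
  sp <- spearman_r(c(1, 2, 3, 50), c(2, 3, 4, 60), max_ref = 30)
  expect_equal(sp$n, 3)
})

test_that("icc_two_way reproduces the variance-components oracle", {
  expect_equal(icc_two_way(1:6, 1:6)$icc, 1)
  ref <- c(9, 6, 8, 7, 10, 6)
  est <- c(2, 1, 4, 1, 5, 2)
  icc <- icc_two_way(est, ref)
  expect_equal(icc$icc, oracle_icc21(est, ref), tolerance = 1e-10)
  expect_true(icc$ci[1] <= icc$icc && icc$icc <= icc$ci[2])
  # independent est and ref: ICC near 0
  set.seed(123)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(icc_two_way(a, b)$icc), 0.15)
})

test_that("severity_class uses 5/15/30 thresholds with NBL twins", {
  expect_equal(severity_class(0)$class, "normal")
  expect_equal(severity_class(18)$class, "moderate")
  expect_equal(severity_class(4.9)$class, "normal")
  expect_equal(severity_class(45)$class, "severe")
  # boundary values go to the upper class
  expect_equal(severity_class(5)$class, "mild")
  expect_equal(severity_class(30)$class, "severe")
  # AHI 5.1 inside the zone around 5 doubles as normal + mild
  sc <- severity_class(5.1, zones = NBL_ZONES_DEFAULT)
  expect_equal(sc$class, "mild")
  expect_equal(sc$twin, "normal")
  sc2 <- severity_class(4.7, zones = NBL_ZONES_DEFAULT)
  expect_equal(sort(c(sc2$class, sc2$twin)), c("mild", "normal"))
  expect_true(is.na(severity_class(10, zones = NBL_ZONES_DEFAULT)$twin))
  expect_error(severity_class(10, zones = c("5" = 1)), "boundaries")
})

test_that("cohen_kappa matches the closed form", {
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  expect_equal(cohen_kappa(diag(c(5, 5, 5, 5))), 1)
})

test_that("severity_report computes confusion, accuracy and kappa with NBL", {
  ref <- c(2, 10, 20, 40, 3, 12)
  est <- c(2, 11, 22, 45, 4, 13)
  sr <- severity_report(est, ref)
  expect_equal(sr$accuracy, 1)
  expect_equal(sr$kappa, 1)
  expect_equal(sr$accuracy_nbl, 1)
  # NBL forgives a near-boundary disagreement
  sr2 <- severity_report(est_ahi = c(4.5, 10), ref_ahi = c(5.1, 10))
  expect_equal(sr2$accuracy, 0.5)
  expect_equal(sr2$accuracy_nbl, 1)
})

test_that("NBL accuracy dominates plain accuracy on random cohorts", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(6:30, 1)
    ref <- runif(n, 0, 50)
    est <- pmax(ref + rnorm(n, 0, 6), 0)
    sr <- severity_report(est, ref)
    expect_gte(sr$accuracy_nbl, sr$accuracy)
  }
})

test_that("kappa of permutation-symmetric random tables is near zero", {
  set.seed(11)
  ks <- replicate(400, {
    tab <- matrix(stats::rmultinom(1, 400, rep(1 / 16, 16)), 4, 4)
    cohen_kappa(tab)
  })
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("covariate_error_correlation links AHI error to covariates", {
  ref <- c(10, 20, 30, 40, 50, 60)
  age <- c(30, 35, 40, 45, 50, 55)
  est <- ref + age / 10                      # error exactly proportional to age
  cc <- covariate_error_correlation(est, ref, data.frame(age = age))
  expect_equal(cc$r[cc$covariate == "age"], 1)
  # est = ref: error all zero, correlation undefined
  cc0 <- covariate_error_correlation(ref, ref, data.frame(age = age))
  expect_true(is.na(cc0$r[1]))
  # simulated null: |R| small
  set.seed(5)
  refn <- runif(200, 0, 50)
  estn <- refn + rnorm(200, 0, 5)
  ccn <- covariate_error_correlation(estn, refn,
                                     data.frame(bmi = runif(200, 20, 40)))
  expect_lt(abs(ccn$r[1]), 0.2)
})

test_that("agreement_report assembles all statistics", {
  set.seed(2)
  ref <- runif(12, 0, 45)
  est <- pmax(ref + rnorm(12, 0, 3), 0)
  ar <- agreement_report(est, ref, covariates = data.frame(age = runif(12, 20, 80)))
  expect_s3_class(ar, "agreement_report")
  expect_true(is.finite(ar$icc$icc))
  expect_true(is.finite(ar$spearman$r))
  expect_equal(dim(ar$severity$confusion), c(4L, 4L))
})
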