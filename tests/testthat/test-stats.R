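test_that("a perfect monotone linear relation gives all four coefficients = 1", {
  x <- c(1, 2, 3, 4, 5)
  rep <- correlation_report(x, 2 * x + 1)
  expect_equal(rep$r, 1)
  expect_equal(rep$R, 1)
  expect_equal(rep$tau, 1)
  expect_equal(rep$gamma, 1)
  neg <- correlation_report(x, -2 * x + 1)
  expect_equal(c(neg$r, neg$R, neg$tau, neg$gamma), rep(-1, 4))
})

test_that("the 4-point discordance example is counted exactly", {
  # all 6 pairs enumerated by hand: 5 concordant, 1 discordant
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  orc <- oracle_pairs(x, y)
  expect_equal(orc$C, 5L)
  expect_equal(orc$D, 1L)
  rep <- correlation_report(x, y)
  expect_equal(rep$gamma, 4 / 6)
  expect_equal(rep$tau, 4 / 6)
})

test_that("tau and gamma match the O(n^2) pair oracle, with and without ties", {
  set.seed(51)
  for (rep_i in 1:40) {
    n <- sample(5:25, 1)
    x <- stats::rnorm(n)
    y <- 0.4 * x + stats::rnorm(n)
    if (rep_i %% 2 == 0) {  # induce ties
      x <- round(x); y <- round(y, 1)
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    rep <- correlation_report(x, y)
    expect_equal(rep$gamma, oracle_gamma(x, y))
    expect_equal(rep$tau, oracle_tau_b(x, y))
    # tau-b also cross-checked against the independent base implementation
    expect_equal(rep$tau, stats::cor(x, y, method = "kendall"))
    if (!any(duplicated(x)) && !any(duplicated(y))) {
      expect_equal(rep$tau, rep$gamma)
    } else {
      expect_lte(abs(rep$tau), abs(rep$gamma) + 1e-12)
    }
  }
})

test_that("small-sample tau p-values agree with the exact distribution", {
  set.seed(52)
  for (rep_i in 1:5) {
    x <- stats::rnorm(7); y <- stats::rnorm(7)
    rep <- correlation_report(x, y)
    ct <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(rep$p_tau, ct$p.value, tolerance = 1e-10)
    # no ties: gamma equals tau, so the permutation p-values coincide
    expect_equal(rep$p_gamma, rep$p_tau, tolerance = 1e-10)
  }
})

test_that("rank statistics are invariant under strictly increasing transforms", {
  set.seed(53)
  x <- stats::rnorm(15); y <- 0.6 * x + stats::rnorm(15)
  a <- correlation_report(x, y)
  b <- correlation_report(exp(x), y^3 + 5 * y)
  expect_equal(a$R, b$R)
  expect_equal(a$tau, b$tau)
  expect_equal(a$gamma, b$gamma)
  # Pearson r is invariant under positive affine maps only
  c_ <- correlation_report(3 * x + 2, 0.5 * y - 1)
  expect_equal(a$r, c_$r)
})

test_that("negating y negates all four coefficients", {
  set.seed(54)
  x <- stats::rnorm(12); y <- 0.8 * x + stats::rnorm(12)
  a <- correlation_report(x, y)
  b <- correlation_report(x, -y)
  expect_equal(c(b$r, b$R, b$tau, b$gamma),
               -c(a$r, a$R, a$tau, a$gamma))
})

test_that("zero variance is reported as undefined, not silently zero", {
  rep <- correlation_report(c(1, 1, 1, 1, 1), c(1, 2, 3, 4, 5))
  expect_true(is.na(rep$r) && is.na(rep$tau) && is.na(rep$gamma))
  expect_match(rep$note, "zero variance")
})

test_that("regression recovers a noise-free line with a zero-width band", {
  x <- seq(-2, 4, length.out = 10)
  f <- fit_with_ci(x, 7.0 + 0.6 * x)
  expect_equal(f$intercept, 7.0, tolerance = 1e-10)
  expect_equal(f$slope, 0.6, tolerance = 1e-10)
  band <- f$band(c(-1, 0, 2))
  expect_equal(band$lwr, band$fit, tolerance = 1e-8)
  expect_equal(band$upr, band$fit, tolerance = 1e-8)
})

test_that("the confidence band contains the fitted line everywhere", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4.7)
  f <- fit_with_ci(x, y)
  grid <- seq(0, 5, by = 0.25)
  band <- f$band(grid)
  line <- f$intercept + f$slope * grid
  expect_true(all(band$lwr <= line + 1e-12))
  expect_true(all(band$upr >= line - 1e-12))
})

test_that("the 95% band at the mean x covers the true mean at nominal rate", {
  set.seed(55)
  n <- 15
  x <- seq(0, 1, length.out = n)
  truth <- 7.0 + 0.6 * mean(x)
  hits <- vapply(1:500, function(i) {
    y <- 7.0 + 0.6 * x + stats::rnorm(n, sd = 0.5)
    b <- fit_with_ci(x, y)$band(mean(x))
    b$lwr <= truth && truth <= b$upr
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("verify_dataset refuses families of fewer than five variants", {
  m <- affinity_model()
  recs <- data.frame(
    variant_label = paste0("v", 1:4), is_wildtype = c(TRUE, rep(FALSE, 3)),
    seq = vapply(1:4, function(i) consensus_promoter(), character(1)),
    expression = c(1, 2, 3, 4), species_tag = "ntTBP",
    exp_condition = "toy", predicted_minus_ln_kd = NA_real_,
    reference = "toy", stringsAsFactors = FALSE)
  d <- tata_dataset(1L, "toy", "toy", "toy", "ntTBP", "II", recs)
  expect_error(verify_dataset(d, m), "at least five variants")
})

test_that("p-values always lie in (0, 1]", {
  set.seed(56)
  for (i in 1:10) {
    n <- sample(c(5, 9, 20), 1)
    rep <- correlation_report(stats::rnorm(n), stats::rnorm(n))
    ps <- c(rep$p_r, rep$p_R, rep$p_tau, rep$p_gamma)
    expect_true(all(ps > 0 & ps <= 1))
  }
})
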