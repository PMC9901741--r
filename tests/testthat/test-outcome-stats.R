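test_that("Cox fit matches a direct partial-likelihood oracle (no ties)", {
  set.seed(41)
  n <- 30
  x <- rnorm(n)
  time <- rexp(n, rate = exp(0.8 * x))
  event <- rep(1, n)
  dat <- tibble::tibble(os_time = time, os_event = event, x = x)
  fit <- fit_cox(dat, "os", "x")
  b_oracle <- oracle_cox1(time, event, x)
  expect_equal(fit$result$estimate, b_oracle, tolerance = 1e-6)
})

test_that("Cox recovers a true two-group hazard ratio of 0.5", {
  set.seed(42)
  hrs <- replicate(5, {
    g <- rbinom(1000, 1, 0.5)
    time <- rexp(1000, rate = 0.01 * 0.5^g)
    dat <- tibble::tibble(os_time = time, os_event = 1, g = g)
    fit_cox(dat, "os", "g")$result$hr
  })
  expect_true(all(hrs > 0.4 & hrs < 0.6))
})

test_that("Cox CI covers 1 for a null covariate in most replicates", {
  set.seed(43)
  cover <- replicate(20, {
    x <- rnorm(500)
    time <- rexp(500, rate = 0.01)
    dat <- tibble::tibble(os_time = time, os_event = 1, x = x)
    r <- fit_cox(dat, "os", "x")$result
    r$conf_low <= 1 && 1 <= r$conf_high
  })
  expect_gte(mean(cover), 0.9)
})

test_that("Cox rejects constant covariates and too few events", {
  dat <- tibble::tibble(os_time = 1:10, os_event = 1, x = 5)
  expect_error(fit_cox(dat, "os", "x"), "constant covariate.*x")
  dat2 <- tibble::tibble(os_time = 1:10, os_event = c(1, rep(0, 9)),
                         x = rnorm(10))
  expect_error(fit_cox(dat2, "os", "x"), ">= 2 events")
})

test_that("separation is flagged, not an error", {
  dat <- tibble::tibble(os_time = c(1, 2, 3, 10, 11, 12),
                        os_event = 1, x = c(1, 1, 1, 0, 0, 0))
  fit <- fit_cox(dat, "os", "x")
  expect_false(fit$converged)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("log-rank: duplicated stratum gives p = 1; degenerate curves shape", {
  dat <- tibble::tibble(os_time = rep(c(1, 2, 3, 4), 2),
                        os_event = rep(c(1, 0, 1, 1), 2))
  km <- km_logrank(dat, rep(c("a", "b"), each = 4), "os")
  expect_equal(km$p_value, 1)
  # one stratum all events at t=1, other all censored at t=2
  dat2 <- tibble::tibble(os_time = c(1, 1, 1, 2, 2, 2),
                         os_event = c(1, 1, 1, 0, 0, 0))
  expect_warning(km2 <- km_logrank(dat2, rep(c("a", "b"), each = 3), "os"),
                 "zero events")
  ca <- km2$curves[km2$curves$stratum == "a", ]
  cb <- km2$curves[km2$curves$stratum == "b", ]
  expect_equal(ca$surv[ca$time == 1], 0)
  expect_true(all(cb$surv == 1))
})

test_that("horizon truncation censors beyond the horizon", {
  dat <- tibble::tibble(os_time = c(100, 400, 6000, 7000),
                        os_event = c(1, 1, 1, 1))
  km <- suppressWarnings(
    km_logrank(dat, c("a", "a", "b", "b"), "os", horizon_years = 10))
  expect_lte(max(km$curves$time), 10 * 365.25)
})

test_that("meta-analysis closed forms: identical and log-symmetric strata", {
  m <- meta_fixed_effect(tibble::tibble(
    stratum = c("s1", "s2"), estimate = log(0.5), se = 0.1))
  expect_equal(m$hr, 0.5, tolerance = 1e-12)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)
  m2 <- meta_fixed_effect(tibble::tibble(
    stratum = c("s1", "s2"), estimate = log(c(0.5, 2)), se = 0.2))
  expect_equal(m2$hr, 1, tolerance = 1e-12)
})

test_that("inverse-variance combination matches hand arithmetic and metafor", {
  loghr <- log(c(0.6, 0.85, 1.3))
  se <- c(0.15, 0.3, 0.22)
  m <- meta_fixed_effect(tibble::tibble(stratum = paste0("s", 1:3),
                                        estimate = loghr, se = se))
  orc <- oracle_meta(loghr, se)
  expect_equal(m$estimate, orc$est, tolerance = 1e-10)
  expect_equal(m$se, orc$se, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  mf <- metafor::rma(yi = loghr, sei = se, method = "FE")
  expect_equal(m$estimate, as.numeric(mf$beta), tolerance = 1e-8)
  expect_equal(m$se, mf$se, tolerance = 1e-8)
})

test_that("meta combined SE shrinks as 1/sqrt(K) for identical strata", {
  for (k in c(2, 4, 8)) {
    m <- meta_fixed_effect(tibble::tibble(
      stratum = paste0("s", 1:k), estimate = log(0.7), se = 0.2))
    expect_equal(m$se, 0.2 / sqrt(k), tolerance = 1e-12)
    expect_equal(m$hr, 0.7, tolerance = 1e-12)
  }
})

test_that("meta excludes unusable strata with a warning", {
  expect_warning(m <- meta_fixed_effect(tibble::tibble(
    stratum = c("a", "b", "c"), estimate = c(log(0.5), Inf, log(0.5)),
    se = c(0.1, 0.1, 0.1))), "excluding")
  expect_equal(m$k, 2)
})

test_that("nested LRT: identical models give statistic 0 and p 1", {
  set.seed(51)
  dat <- tibble::tibble(os_time = rexp(50, 0.01), os_event = 1, x = rnorm(50))
  f <- fit_cox(dat, "os", "x")
  res <- nested_lrt(f, f)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("nested LRT detects a real added covariate and rejects non-nesting", {
  set.seed(52)
  n <- 1000
  x <- rnorm(n); z <- rnorm(n)
  time <- rexp(n, rate = 0.01 * exp(0.4 * x + 0.4 * z))
  dat <- tibble::tibble(os_time = time, os_event = 1, x = x, z = z)
  small <- fit_cox(dat, "os", "x")
  large <- fit_cox(dat, "os", c("x", "z"))
  expect_lt(nested_lrt(small, large)$p_value, 0.05)
  other <- fit_cox(dat, "os", "z")
  expect_error(nested_lrt(other, fit_cox(dat, "os", "x")), "not nested")
  expect_error(nested_lrt(fit_cox(dat[1:500, ], "os", "x"), large),
               "same samples")
})

test_that("exact Wilcoxon enumeration: {1,2,3} vs {4,5,6} gives p = 0.1", {
  res <- group_wilcoxon(c(1, 2, 3, 4, 5, 6),
                        rep(c("a", "b"), each = 3))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))
})

test_that("Wilcoxon matches the permutation oracle on random small instances", {
  set.seed(61)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- sample(1000, n1 + n2)  # distinct -> exact path
    grp <- rep(c("a", "b"), c(n1, n2))
    res <- group_wilcoxon(vals, grp)
    expect_equal(res$p_value,
                 oracle_wilcoxon_exact(vals[grp == "a"], vals[grp == "b"]),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon with identical groups gives p = 1 and ties use the normal path", {
  res <- group_wilcoxon(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_false(res$exact)
  expect_equal(res$p_value, 1, tolerance = 0.05)
  expect_error(group_wilcoxon(1:3, c("a", "a", "a")), "exactly 2 groups")
})

test_that("Fisher quadrant test matches hypergeometric enumeration", {
  quad <- rep(c("high/high", "low/low"), each = 3)
  resp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- fisher_quadrant(quad, resp)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_fisher(3, 0, 0, 3))
  flat <- fisher_quadrant(rep(c("high/high", "low/low"), 2),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(flat$p_value, 1)
  expect_error(fisher_quadrant(character(0), logical(0)), "empty")
})

test_that("below-diagonal fraction counts strict I > A and missing ratios", {
  prof <- tibble::tibble(A = c(0.2, 0.45, 0.8, 0.3, 0.5),
                         I = c(0.4, 0.5, 0.4, 0.3, 0),
                         ai_ratio = c(0.5, 0.9, 2, 1, NA))
  res <- below_diagonal_fraction(prof)
  expect_equal(res$fraction, 2 / 4)   # A = I tie not counted; NA excluded
  expect_equal(res$n_missing, 1)
  res2 <- below_diagonal_fraction(prof, group = c("x", "x", "x", "y", "y"))
  expect_equal(res2$fraction[res2$group == "x"], 2 / 3)
  empty <- tibble::tibble(A = 1, I = 1, ai_ratio = NA_real_)
  expect_warning(res3 <- below_diagonal_fraction(empty), "undefined")
  expect_true(is.na(res3$fraction))
})
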