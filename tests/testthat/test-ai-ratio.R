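test_that("reverse_log inverts log2(x + 1)", {
  expect_equal(reverse_log(0), 0)
  expect_equal(reverse_log(3), 7)
  x <- c(0, 0.3, 2, 11.7)
  expect_equal(reverse_log(log2(x + 1)), x, tolerance = 1e-12)
})

test_that("min-max scaling hits 0 and 1 at the extremes", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 7))
  s <- minmax_scale(m)
  expect_equal(s[, "a"], c(0, 0.5, 1))
  expect_equal(s[, "b"], c(0, 1 / 3, 1))
})

test_that("degenerate constant cell type scales to zero with a warning", {
  m <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_warning(s <- minmax_scale(m), "degenerate")
  expect_equal(s[, "a"], c(0, 0, 0))
})

test_that("scoped scaling uses per-group extremes and rejects tiny groups", {
  m <- cbind(a = c(0, 10, 5, 15))
  s <- minmax_scale(m, scope = c("g1", "g1", "g2", "g2"))
  expect_equal(unname(s[, 1]), c(0, 1, 0, 1))
  expect_error(minmax_scale(m, scope = c("g1", "g1", "g1", "g2")), "< 2 samples")
})

test_that("compartment scores are means over assigned types only", {
  scaled <- cbind(Ta = c(0.5), Tb = c(0.7), Na = c(0.2), Nb = c(0.4))
  cs <- compartment_scores(scaled, tiny_panel())
  expect_equal(cs$A, 0.6)
  expect_equal(cs$I, 0.3)
  # excluded type changes neither compartment
  scaled2 <- cbind(scaled, Ex = 0.9)
  cs2 <- compartment_scores(scaled2, tiny_panel(excluded = TRUE))
  expect_equal(cs2, cs)
  # all values equal -> A = I
  same <- matrix(0.42, 1, 4, dimnames = list(NULL, c("Ta", "Tb", "Na", "Nb")))
  cs3 <- compartment_scores(same, tiny_panel())
  expect_equal(cs3$A, cs3$I)
})

test_that("ai_ratio divides, keeps zero numerator, and flags I = 0 as missing", {
  expect_equal(ai_ratio(0.6, 0.3), 2)
  expect_equal(ai_ratio(0, 0.5), 0)
  expect_message(r <- ai_ratio(c(0.4, 0.2), c(0, 0.5)), "innate score 0")
  expect_true(is.na(r[1]))
  expect_equal(r[2], 0.4)
  expect_equal(ai_ratio(0.4, 0, epsilon = 0.1), 4)
})

test_that("full profile matches the brute-force scaling oracle to 1e-12", {
  panel <- ratio_panel()
  m <- random_score_matrix(10, panel, seed = 101)
  prof <- immune_profile(scores_tibble(m), panel = panel)
  orc <- oracle_profile(m, panel)
  expect_equal(prof$A, orc$A, tolerance = 1e-12)
  expect_equal(prof$I, orc$I, tolerance = 1e-12)
  expect_equal(prof$ai_ratio, orc$ratio, tolerance = 1e-12)
  scaled <- as.matrix(prof[, paste("scaled", colnames(m))])
  expect_equal(unname(scaled), unname(orc$scaled), tolerance = 1e-12)
  expect_true(all(scaled >= 0 & scaled <= 1))
  # each non-degenerate cell type attains both extremes
  expect_true(all(apply(scaled, 2, min) == 0))
  expect_true(all(apply(scaled, 2, max) == 1))
})

test_that("the statistic is cohort-relative: a new extreme sample rescales others", {
  panel <- tiny_panel()
  m <- rbind(s1 = c(Ta = 1, Tb = 2, Na = 1, Nb = 2),
             s2 = c(Ta = 3, Tb = 4, Na = 3, Nb = 4))
  p1 <- immune_profile(scores_tibble(m), panel = panel)
  # permutation of samples permutes profiles identically
  p1r <- immune_profile(scores_tibble(m[2:1, ]), panel = panel)
  expect_equal(p1r[match(p1$sample_id, p1r$sample_id), -1], p1[, -1])
  # adding a sample above the previous max drags scaled values down
  m3 <- rbind(m, s3 = c(Ta = 6, Tb = 6, Na = 6, Nb = 6))
  p3 <- immune_profile(scores_tibble(m3), panel = panel)
  expect_lt(p3$A[p3$sample_id == "s2"], p1$A[p1$sample_id == "s2"])
  expect_equal(p3$A[p3$sample_id == "s3"], 1)
})

test_that("raising one adaptive type within cohort range never lowers A or the ratio", {
  panel <- ratio_panel()
  set.seed(202)
  for (rep in 1:20) {
    m <- random_score_matrix(8, panel, seed = 300 + rep)
    adaptive <- compartment_cell_types(panel, "adaptive")
    ty <- sample(adaptive, 1)
    i <- sample(which(m[, ty] < max(m[, ty])), 1)
    m2 <- m
    # move strictly towards (not past) the cohort max on the linear scale
    m2[i, ty] <- m[i, ty] + 0.5 * (max(m[, ty]) - m[i, ty])
    p1 <- immune_profile(scores_tibble(m), panel = panel)
    p2 <- immune_profile(scores_tibble(m2), panel = panel)
    expect_gte(p2$A[i], p1$A[i])
    expect_gte(p2$ai_ratio[i], p1$ai_ratio[i])
  }
})

test_that("an all-constant innate compartment yields missing ratios, not a crash", {
  panel <- tiny_panel()
  m <- rbind(s1 = c(Ta = 1, Tb = 2, Na = 3, Nb = 4),
             s2 = c(Ta = 2, Tb = 3, Na = 3, Nb = 4),
             s3 = c(Ta = 3, Tb = 4, Na = 3, Nb = 4))
  expect_warning(expect_message(
    prof <- immune_profile(scores_tibble(m), panel = panel), "innate score 0"),
    "degenerate")
  expect_true(all(prof$I == 0))
  expect_true(all(is.na(prof$ai_ratio)))
})

test_that("median split labels strictly-above-median as high, ties low", {
  expect_equal(as.character(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # per-scope medians
  lab <- median_split(c(1, 3, 10, 30), scope = c("a", "a", "b", "b"))
  expect_equal(as.character(lab), c("low", "high", "low", "high"))
  meds <- attr(lab, "medians")
  expect_equal(meds$median, c(2, 20))
  # missing values are excluded and labelled NA
  lab2 <- median_split(c(1, NA, 3))
  expect_true(is.na(lab2[2]))
})

test_that("female-median reference labels males against the female median", {
  vals <- c(1, 3, 2.5, 2)
  gender <- c("female", "female", "male", "male")
  lab <- female_median_reference(vals, gender)
  expect_equal(as.character(lab), c("low", "high", "high", "low"))  # median 2
  # male exactly at female median -> low (tie rule)
  expect_equal(as.character(lab)[4], "low")
  # stratum without females -> NA labels + warning
  expect_warning(
    lab2 <- female_median_reference(c(1, 2), c("male", "male"),
                                    scope = c("ct1", "ct1")),
    "no female")
  expect_true(all(is.na(lab2)))
})

test_that("add_strata builds the quadrant as the product of the two splits", {
  prof <- tibble::tibble(sample_id = paste0("s", 1:4),
                         ai_ratio = c(1, 2, 3, 4),
                         til_score = c(4, 3, 2, 1),
                         A = 1, I = 1)
  out <- add_strata(prof)
  expect_equal(out$quadrant,
               paste(out$ai_group, out$til_group, sep = "/"))
  expect_equal(out$quadrant[4], "high/low")
})
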