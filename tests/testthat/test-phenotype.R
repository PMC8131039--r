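test_that("retainability scoring follows the threshold-crossing rule", {
  # acceptability lost already at harvest
  s0 <- storage_series("a", "firmness", 0:6, c(6.5, 6, 5, 4, 3, 2, 1))
  r0 <- compute_retainability(s0)
  expect_identical(r0$retainability, 0L)
  expect_false(r0$censored)

  # never crosses: censored at last measured month
  s6 <- storage_series("b", "firmness", 0:6, rep(7.5, 7))
  r6 <- compute_retainability(s6)
  expect_identical(r6$retainability, 6L)
  expect_true(r6$censored)

  # first sub-threshold month is 3 -> retainability 2
  s2 <- storage_series("c", "firmness", 0:4, c(8.1, 7.6, 7.2, 6.8, 6.1))
  expect_identical(compute_retainability(s2, 7.0)$retainability, 2L)

  # a dip followed by recovery still terminates at the first crossing
  sdip <- storage_series("d", "firmness", 0:3, c(8, 6.9, 7.5, 7.4))
  expect_identical(compute_retainability(sdip)$retainability, 0L)

  expect_error(storage_series("e", "firmness", integer(), numeric()), "empty")
})

test_that("softening types I/II/III follow retainability and first-month drop", {
  s1 <- storage_series("a", "firmness", 0:6, c(6.5, 6, 5, 4, 3, 2, 1))
  expect_identical(classify_type(compute_retainability(s1), s1), "I")

  # retainability 6 with all monthly drops <= 0.3 -> III
  s3 <- storage_series("b", "firmness", 0:6, 8.8 - 0.3 * (0:6))
  expect_identical(classify_type(compute_retainability(s3), s3,
                                 rapid_drop = 1.0), "III")

  # month 0 -> 1 drop of 1.8 -> II
  s2 <- storage_series("c", "firmness", 0:6,
                       c(9.5, 7.7, 7.6, 7.5, 7.4, 7.3, 7.2))
  expect_identical(classify_type(compute_retainability(s2), s2,
                                 rapid_drop = 1.0), "II")

  # intermediate retainability stays unclassified
  s4 <- storage_series("d", "firmness", 0:6, c(9, 8, 7.5, 7.1, 6.5, 6, 5))
  expect_identical(classify_type(compute_retainability(s4), s4), "unclassified")

  # month-1 point absent for a month-6 retainer
  s5 <- storage_series("e", "firmness", c(0L, 2L, 4L, 6L), c(9, 8.5, 8, 7.5))
  expect_warning(ty <- classify_type(compute_retainability(s5), s5),
                 "month-1")
  expect_identical(ty, "unclassified")
})

test_that("raising the threshold never increases retainability", {
  for (seed in 1:40) {
    s <- random_series(seed)
    thresholds <- sort(runif(4, 1, 10))
    rets <- vapply(thresholds,
                   function(t) compute_retainability(s, t)$retainability,
                   integer(1))
    expect_true(all(diff(rets) <= 0L),
                info = paste("seed", seed))
  }
})

test_that("broad-sense heritability matches one-way ANOVA expectations", {
  # MS_error = 0 -> h2 = 1
  ph <- data.frame(hybrid_id = rep(c("a", "b", "c"), each = 2),
                   trait = "firmness_retainability",
                   opv = rep(c(1, 3, 5), each = 2),
                   year = rep(2016:2017, 3))
  expect_equal(estimate_h2(ph)$h2, 1)

  # all values equal -> var_g clamped at 0 -> h2 = 0
  ph0 <- transform(ph, opv = 2)
  expect_equal(estimate_h2(ph0)$h2, 0)

  # oracle: variance components recovered from stats::aov mean squares
  set.seed(11)
  g <- rnorm(40, 0, 2)
  ph2 <- data.frame(hybrid_id = rep(sprintf("h%02d", 1:40), each = 2),
                    trait = "firmness_retainability",
                    opv = pmax(rep(g, each = 2) + rnorm(80) + 3, 0),
                    year = rep(2016:2017, 40))
  fit <- stats::aov(opv ~ hybrid_id, data = ph2)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  var_g <- max(0, (ms[1] - ms[2]) / 2)
  est <- estimate_h2(ph2)
  expect_equal(est$var_g, var_g, tolerance = 1e-10)
  expect_equal(est$h2, var_g / (var_g + ms[2]), tolerance = 1e-10)

  expect_error(estimate_h2(ph[ph$year == 2016, ]), "2 years")
})

test_that("simulated variance components give h2 near truth; estimate is scale-free", {
  set.seed(21)
  n <- 500
  g <- rnorm(n, 0, 2)            # var_g = 4
  y <- vapply(1:2, function(yr) g + rnorm(n, 0, 1), numeric(n))  # var_e = 1
  ph <- data.frame(hybrid_id = rep(sprintf("h%03d", 1:n), 2),
                   trait = "t", opv = pmax(as.vector(y) + 5, 0),
                   year = rep(2016:2017, each = n))
  est <- estimate_h2(ph)
  expect_true(abs(est$h2 - 0.8) < 0.05)

  shifted <- transform(ph, opv = opv + 1.7)
  scaled <- transform(ph, opv = opv * 3.1)
  expect_equal(estimate_h2(shifted)$h2, est$h2, tolerance = 1e-10)
  expect_equal(estimate_h2(scaled)$h2, est$h2, tolerance = 1e-10)
})

test_that("trait correlation uses complete pairs and flags degeneracy", {
  expect_equal(correlate(1:5, 1:5)$r, 1.0)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")

  # brute-force covariance formula as the oracle
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$r, r_brute, tolerance = 1e-12)

  with_na <- correlate(c(x, NA), c(y, 1))
  expect_equal(with_na$n, 4L)
})
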