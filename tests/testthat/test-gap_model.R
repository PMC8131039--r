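test_that("fitting stores hand-computed effects and is deterministic", {
  model <- gap_fit(toy_geno(), toy_pheno(), min_class_n = 1L)
  expect_equal(model$overall_mean, 4)
  m1 <- model$effects$m1$classes
  expect_equal(m1$effect, c(-2, 2))
  m2 <- model$effects$m2$classes
  expect_equal(m2$effect, c(-1, 1))
  expect_equal(gap_fit(toy_geno(), toy_pheno(), min_class_n = 1L),
               model)

  # zero markers: degenerate mean-only model still predicts
  empty <- genotype_table(matrix(character(0), 4, 0,
                                 dimnames = list(paste0("h", 1:4), NULL)))
  m0 <- gap_fit(empty, toy_pheno())
  expect_length(m0$effects, 0)
  expect_equal(predict(m0, empty)$gpv, rep(4, 4))
})

test_that("GPV pyramids class effects onto the overall mean", {
  model <- gap_fit(toy_geno(), toy_pheno(), min_class_n = 1L)
  pred <- predict(model, toy_geno())
  # h2 carries A:A at m1 (-2) and C:T at m2 (+1): gpv = 4 - 2 + 1 = 3
  expect_equal(pred$gpv[pred$hybrid_id == "h2"], 3)
  expect_equal(pred$gpv[pred$hybrid_id == "h4"], 7)

  # hybrids with a missing call get no GPV
  calls <- toy_geno()$calls
  calls["h1", "m2"] <- NA
  pred2 <- predict(model, genotype_table(calls))
  expect_true(is.na(pred2$gpv[pred2$hybrid_id == "h1"]))
  expect_false(pred2$complete[pred2$hybrid_id == "h1"])
  expect_equal(pred2$gpv[pred2$hybrid_id == "h2"], 3)

  # model marker absent from the table is an error naming the marker
  expect_error(predict(model, genotype_table(calls[, "m1", drop = FALSE])),
               "m2")

  # unseen genotype class contributes zero with a warning
  calls3 <- toy_geno()$calls
  calls3["h1", "m2"] <- "T:T"
  expect_warning(pred3 <- predict(model, genotype_table(calls3)), "unseen")
  expect_equal(pred3$gpv[pred3$hybrid_id == "h1"], 4 - 2 + 0)
})

test_that("prediction is linear in the effects", {
  sim <- random_fixture(100, 6, seed = 13)
  model <- gap_fit(sim$genotypes, sim$phenotypes)
  doubled <- model
  for (m in names(doubled$effects)) {
    doubled$effects[[m]]$classes$effect <-
      2 * doubled$effects[[m]]$classes$effect
  }
  p1 <- predict(model, sim$genotypes, warn_unseen = FALSE)
  p2 <- predict(doubled, sim$genotypes, warn_unseen = FALSE)
  expect_equal(p2$gpv - model$overall_mean,
               2 * (p1$gpv - model$overall_mean), tolerance = 1e-12)
})

test_that("model GPV equals the naive per-hybrid oracle loop", {
  sim <- random_fixture(80, 10, seed = 29, missing_rate = 0.05)
  model <- gap_fit(sim$genotypes, sim$phenotypes)
  pred <- predict(model, sim$genotypes, warn_unseen = FALSE)
  expect_equal(pred$gpv, unname(oracle_gpv(model, sim$genotypes)),
               tolerance = 1e-9)
})

test_that("Pearson accuracy matches the brute-force formula", {
  p <- data.frame(gpv = c(1, 2, 3, 4, 5), opv = c(1.2, 1.9, 3.4, 3.9, 4.8))
  r_brute <- with(p, sum((gpv - mean(gpv)) * (opv - mean(opv))) /
                    sqrt(sum((gpv - mean(gpv))^2) * sum((opv - mean(opv))^2)))
  expect_equal(gap_accuracy(p), r_brute, tolerance = 1e-12)
  expect_equal(gap_accuracy(data.frame(gpv = 1:5, opv = 1:5)), 1)
  expect_equal(gap_accuracy(data.frame(gpv = 1:5, opv = -(1:5))), -1)
  expect_error(gap_accuracy(data.frame(gpv = rep(1, 5), opv = 1:5)),
               "zero variance")
})

test_that("cross-validation recovers a deterministic one-marker phenotype", {
  # phenotype fully determined by one 3-class marker
  mk <- marker_spec("q", "A:G", "A:G", a = 2, d = 1)
  sim <- simulate_f1_population(sim_config(
    n_hybrids = 300, markers = list(mk), target_h2 = 0.999, seed = 31))
  cv <- gap_cross_validate(sim$genotypes, sim$phenotypes, seed = 31)
  expect_gte(cv$mean_accuracy, 0.95)
})

test_that("cross-validated accuracy is near zero for unlinked phenotypes", {
  sim <- random_fixture(300, 8, seed = 37)
  shuffled <- sim$phenotypes
  set.seed(1)
  perm <- sample(unique(shuffled$hybrid_id))
  names(perm) <- unique(shuffled$hybrid_id)
  shuffled$hybrid_id <- unname(perm[shuffled$hybrid_id])
  cv <- gap_cross_validate(sim$genotypes, shuffled, seed = 41)
  expect_lt(abs(cv$mean_accuracy), 0.15)
})

test_that("cross-validation checks fold feasibility and is seeded", {
  sim <- random_fixture(10, 3, seed = 43)
  expect_error(gap_cross_validate(sim$genotypes, sim$phenotypes,
                                  k = 7, seed = 1), "2k")
  sim2 <- random_fixture(60, 4, seed = 47)
  a <- gap_cross_validate(sim2$genotypes, sim2$phenotypes, k = 3, runs = 2,
                          seed = 5)
  b <- gap_cross_validate(sim2$genotypes, sim2$phenotypes, k = 3, runs = 2,
                          seed = 5)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
})
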