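test_that("non-segregating marker specs are rejected", {
  expect_error(marker_spec("m", "A:A", "A:A", a = 1, d = 0), "non-segregating")
  expect_error(marker_spec("m", "A:A", "G:G", a = 1, d = 0), "non-segregating")
  expect_silent(marker_spec("m", "A:G", "G:G", a = 1, d = 0))
  expect_error(marker_spec("m", "A:T", "A:G", a = 1, d = 0), "outside")
})

test_that("config validation demands a seed and a valid h2", {
  expect_error(sim_config(n_hybrids = 10), "seed")
  expect_error(sim_config(n_hybrids = 10, target_h2 = 0, seed = 1))
  expect_error(sim_config(n_hybrids = 1, seed = 1))
})

test_that("Mendelian gamete sampling matches expected segregation", {
  # het x hom segregates 1:1 -> heterozygote frequency 0.5 +- 3 sigma
  bc <- marker_spec("bc", "A:G", "G:G", a = 1, d = 0.5)
  sim <- simulate_f1_population(sim_config(
    n_hybrids = 10000, markers = list(bc), seed = 91))
  het <- mean(is_heterozygous(sim$genotypes$calls[, "bc"]))
  expect_true(abs(het - 0.5) < 0.015)

  # het x het segregates 1:2:1: chi-square GoF across seeded replicates
  f2 <- marker_spec("f2", "A:G", "A:G", a = 1, d = 0.5)
  pvals <- vapply(1:25, function(seed) {
    s <- simulate_f1_population(sim_config(
      n_hybrids = 4000, markers = list(f2), seed = seed))
    counts <- table(factor(s$genotypes$calls[, "f2"],
                           levels = c("A:A", "A:G", "G:G")))
    stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("realized heritability tracks the target as n grows", {
  for (n in c(500, 5000)) {
    sim <- random_fixture(n, 10, seed = 5, h2 = 0.8)
    g <- sim$truth$g
    y1 <- sim$phenotypes$opv[sim$phenotypes$year == 2001]
    realized <- var(g) / var(y1)
    tol <- if (n == 500) 0.06 else 0.03
    expect_true(abs(realized - 0.8) < tol, info = paste("n =", n))
  }
})

test_that("same seed gives byte-identical simulation output", {
  a <- random_fixture(50, 5, seed = 123, missing_rate = 0.1)
  b <- random_fixture(50, 5, seed = 123, missing_rate = 0.1)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$g, b$truth$g)
  c <- random_fixture(50, 5, seed = 124, missing_rate = 0.1)
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("integer mode truncates to the month grid", {
  sim <- random_fixture(300, 8, seed = 17, integer_mode = TRUE)
  opv <- sim$phenotypes$opv
  expect_true(all(opv == round(opv)))
  expect_true(all(opv >= 0 & opv <= 6))
})

test_that("default marker panel spans the requested range with mixed actions", {
  panel <- default_marker_panel(28, c(0.1, 3.5))
  spans <- vapply(panel, function(sp) {
    vals <- c(-sp$a, sp$d, sp$a)
    max(vals) - min(vals)
  }, numeric(1))
  expect_equal(min(spans), 0.1, tolerance = 1e-9)
  expect_equal(max(spans), 3.5, tolerance = 1e-9)
  actions <- vapply(panel, `[[`, character(1), "action")
  counts <- table(actions)
  expect_true(counts["partial_dominant"] > max(counts[names(counts) != "partial_dominant"]))
  expect_true(all(c("additive", "complete_dominant", "overdominant") %in%
                    names(counts)))
})

test_that("storage-series generator honours type contracts and rejects bad params", {
  thr <- trait_defaults()$firmness$threshold
  sI <- simulate_storage_series("I", "firmness", seed = 1)
  expect_lt(sI$values[1], thr)
  sIII <- simulate_storage_series("III", "firmness", seed = 2)
  recIII <- compute_retainability(sIII)
  expect_identical(recIII$retainability, 6L)
  expect_true(recIII$censored)
  sII <- simulate_storage_series("II", "firmness", seed = 3)
  expect_gte(sII$values[1] - sII$values[2],
             trait_defaults()$firmness$rapid_drop - 0.2)
  expect_identical(compute_retainability(sII)$retainability, 6L)

  # parameter sets that cannot satisfy the contract fail before emission
  expect_error(simulate_storage_series("I", "firmness",
                                       params = list(start = 8)), "threshold")
  expect_error(simulate_storage_series("II", "firmness",
                                       params = list(fast_drop = 4)),
               "below the acceptability")
  expect_error(simulate_storage_series("III", "firmness",
                                       params = list(slow_rate = 1.2)),
               "threshold")
})

test_that("candidate fixture manifest is exact by construction", {
  fx <- simulate_candidate_tables(n_genes = 20, n_variants = 40, seed = 7)
  expect_setequal(names(fx$manifest$scenario), fx$genes$gene_id)
  # survivors are exactly the genes generated under the pass scenario
  expect_setequal(fx$manifest$survivors,
                  fx$genes$gene_id[fx$genes$scenario == "pass"])
  # no variants -> nothing can survive the impact rule
  fx0 <- simulate_candidate_tables(n_genes = 10, n_variants = 0, seed = 7)
  expect_length(fx0$manifest$survivors, 0)
  expect_identical(nrow(fx0$variants), 0L)
})

test_that("candidate fixture files round-trip through their formats", {
  out <- withr::local_tempdir()
  fx <- simulate_candidate_tables(n_genes = 12, n_variants = 24, seed = 9,
                                  out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("qtls.bed", "genes.tsv", "variants.vcf", "expression.tsv",
           "degs.txt", "manifest.json")))))
  v <- read_minimal_vcf(file.path(out, "variants.vcf"))
  expect_identical(nrow(v), nrow(fx$variants))
  expect_setequal(v$gene_id, fx$variants$gene_id)
  bed <- read_bed(file.path(out, "qtls.bed"))
  expect_equal(bed$start, fx$qtls$start)
})
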