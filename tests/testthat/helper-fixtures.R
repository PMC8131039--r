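# In-code fixtures shared across test files.

# 4 hybrids x 2 markers with hand-computable effects:
# m1: AA {h1,h2}, AG {h3,h4}; m2: CC {h1,h3}, CT {h2,h4}
# opv 1,3,5,7 -> overall mean 4; m1 effects -2/+2; m2 effects -1/+1
toy_geno <- function() {
  calls <- matrix(c("A:A", "A:A", "A:G", "A:G",
                    "C:C", "C:T", "C:C", "C:T"),
                  nrow = 4,
                  dimnames = list(paste0("h", 1:4), c("m1", "m2")))
  genotype_table(calls)
}

toy_pheno <- function(trait = "firmness_retainability") {
  data.frame(hybrid_id = paste0("h", 1:4), trait = trait,
             opv = c(1, 3, 5, 7), year = NA_integer_,
             stringsAsFactors = FALSE)
}

# random genotype fixture via the F1 simulator (integer-mode phenotypes)
random_fixture <- function(n, n_markers, seed, h2 = 0.84,
                           integer_mode = FALSE, missing_rate = 0) {
  simulate_f1_population(sim_config(
    n_hybrids = n, markers = default_marker_panel(n_markers),
    seed = seed, target_h2 = h2, integer_mode = integer_mode,
    missing_rate = missing_rate))
}

# random monotone-ish storage series for property tests
random_series <- function(seed, trait = "firmness") {
  set.seed(seed)
  start <- stats::runif(1, 4, 10)
  drops <- stats::runif(6, 0, 1.5)
  storage_series("R", trait, 0:6, pmax(start - cumsum(c(0, drops)), 0))
}

# independent GPV oracle: naive per-hybrid loop over marker class-mean tables
oracle_gpv <- function(model, genotypes) {
  vapply(genotypes$hybrid_ids, function(h) {
    total <- model$overall_mean
    for (m in names(model$effects)) {
      call <- genotypes$calls[h, m]
      if (is.na(call)) return(NA_real_)
      cls <- model$effects[[m]]$classes
      row <- which(cls$class == call)
      total <- total + if (length(row)) cls$effect[row] else 0
    }
    total
  }, numeric(1))
}
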