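# Seeded generators for F1 bi-parental populations, storage trajectories
# and candidate-gene fixtures with construction-known truth.

#' Classify allelic action from additive and dominance components
#'
#' With homozygote half-difference `a` and heterozygote deviation `d` from the
#' homozygote midpoint, the dominance degree is `|d/a|`: <= 0.2 additive,
#' (0.2, 0.8) partial dominant, [0.8, 1.2] complete dominant, > 1.2
#' overdominant. `|a|` below `tol` is undetermined. The same bins label a
#' simulated marker's intended action and an estimated marker effect, closing
#' the recovery loop.
#'
#' @param a half-difference of homozygote class means (months).
#' @param d heterozygote deviation from the homozygote midpoint (months).
#' @param tol minimum `|a|` for the ratio to be meaningful.
#' @param cutoffs numeric vector `c(additive, complete_lo, complete_hi)`.
#' @return one of `"additive"`, `"partial_dominant"`, `"complete_dominant"`,
#'   `"overdominant"`, `"undetermined"`.
#' @export
allelic_action_from_ad <- function(a, d, tol = 1e-8,
                                   cutoffs = c(0.2, 0.8, 1.2)) {
  if (abs(a) < tol) return("undetermined")
  ratio <- abs(d / a)
  if (ratio <= cutoffs[1]) "additive"
  else if (ratio < cutoffs[2]) "partial_dominant"
  else if (ratio <= cutoffs[3]) "complete_dominant"
  else "overdominant"
}

#' Specify a simulated biallelic marker
#'
#' @param marker_id identifier.
#' @param parent1,parent2 parental genotype labels using the marker's
#'   alleles (e.g. `"A:G"`); at least one parent must be heterozygous for the
#'   marker to segregate in the F1.
#' @param a half-difference of homozygote genotypic values, months; the first
#'   allele in `alleles` is the increasing one.
#' @param d heterozygote deviation from the homozygote midpoint, months.
#' @param alleles length-2 character vector, increasing allele first.
#' @return an object of class `marker_spec`.
#' @export
marker_spec <- function(marker_id, parent1, parent2, a, d,
                        alleles = c("A", "G")) {
  stopifnot(length(alleles) == 2L, alleles[1] != alleles[2])
  parent1 <- normalize_call(parent1)
  parent2 <- normalize_call(parent2)
  for (p in c(parent1, parent2)) {
    if (!all(class_alleles(p) %in% alleles)) {
      stop("marker ", marker_id, ": parent genotype ", p,
           " uses alleles outside {", paste(alleles, collapse = ","), "}")
    }
  }
  if (!is_heterozygous(parent1) && !is_heterozygous(parent2)) {
    stop("marker ", marker_id,
         " is non-segregating: neither parent is heterozygous")
  }
  structure(list(marker_id = marker_id, parent1 = parent1, parent2 = parent2,
                 a = a, d = d, alleles = alleles,
                 action = allelic_action_from_ad(a, d)),
            class = "marker_spec")
}

# genotypic value of each normalized class for one marker spec
marker_class_values <- function(spec) {
  hi <- spec$alleles[1]; lo <- spec$alleles[2]
  vals <- c(spec$a, spec$d, -spec$a)
  names(vals) <- normalize_call(c(paste(hi, hi, sep = ":"),
                                  paste(hi, lo, sep = ":"),
                                  paste(lo, lo, sep = ":")))
  vals
}

# expected F1 class frequencies from the two parental genotypes
marker_class_freqs <- function(spec) {
  g1 <- strsplit(spec$parent1, ":", fixed = TRUE)[[1]]
  g2 <- strsplit(spec$parent2, ":", fixed = TRUE)[[1]]
  combos <- normalize_call(as.vector(outer(g1, g2, paste, sep = ":")))
  tab <- table(combos) / length(combos)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Default marker panel for the F1 simulator
#'
#' A deterministic panel of both-parent-heterozygous markers whose
#' genotype-class spans are evenly spaced across `span_range` (months) and
#' whose allelic actions cycle through a mixture dominated by partial
#' dominance, with additive, complete dominant and overdominant markers less
#' common, matching the action mix reported for fruit texture retainability
#' markers. The span of a marker's three class values
#' (`-a`, `d`, `+a`) is `a * (1 + max(1, |d/a|))`, so `a` is back-solved from
#' the target span.
#'
#' @param n_markers number of markers.
#' @param span_range length-2 numeric, months, smallest and largest class
#'   span.
#' @return list of [marker_spec] objects.
#' @export
default_marker_panel <- function(n_markers = 28, span_range = c(0.1, 3.5)) {
  stopifnot(n_markers >= 1, span_range[1] > 0, span_range[2] >= span_range[1])
  spans <- seq(span_range[1], span_range[2], length.out = n_markers)
  # dominance-degree cycle: partial dominance most common
  ratios <- rep(c(0.5, 0.5, 0, 0.5, 1.0, 0.5, 1.4, 0.5),
                length.out = n_markers)
  signs <- rep(c(1, -1), length.out = n_markers)
  allele_pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  lapply(seq_len(n_markers), function(i) {
    a <- spans[i] / (1 + max(1, ratios[i]))
    d <- signs[i] * ratios[i] * a
    al <- allele_pairs[[(i - 1L) %% length(allele_pairs) + 1L]]
    het <- paste(al, collapse = ":")
    marker_spec(sprintf("M%02d", i), het, het, a = a, d = d, alleles = al)
  })
}

#' Simulation configuration for an F1 population
#'
#' @param n_hybrids number of hybrids (>= 2).
#' @param markers list of [marker_spec]; defaults to [default_marker_panel()].
#' @param population_mean population mean retainability, months.
#' @param target_h2 target broad-sense heritability in (0, 1]; environmental
#'   variance is set to `Var(g) * (1 - h2) / h2`.
#' @param n_years yearly phenotype replicates per hybrid.
#' @param seed mandatory RNG seed.
#' @param trait phenotype trait label.
#' @param integer_mode when `TRUE`, yearly phenotypes are truncated to
#'   `[0, max_month]` and rounded to the month grid, mimicking observed
#'   retainability records; continuous values otherwise.
#' @param max_month storage horizon, months.
#' @param missing_rate fraction of genotype calls masked to missing.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_hybrids, markers = default_marker_panel(),
                       population_mean = 2.0, target_h2 = 0.84,
                       n_years = 2L, seed, trait = "firmness_retainability",
                       integer_mode = FALSE, max_month = 6L,
                       missing_rate = 0) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_hybrids >= 2, length(markers) >= 1,
            target_h2 > 0, target_h2 <= 1,
            n_years >= 1, missing_rate >= 0, missing_rate < 1)
  if (!all(vapply(markers, inherits, logical(1), "marker_spec"))) {
    stop("markers must be a list of marker_spec objects")
  }
  structure(list(n_hybrids = as.integer(n_hybrids), markers = markers,
                 population_mean = population_mean, target_h2 = target_h2,
                 n_years = as.integer(n_years), seed = as.integer(seed),
                 trait = trait, integer_mode = integer_mode,
                 max_month = as.integer(max_month),
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate an F1 bi-parental population
#'
#' Genotypes are drawn by Mendelian gamete sampling from the parental
#' genotypes of each marker (het x hom segregates 1:1, het x het 1:2:1). A
#' hybrid's genetic value is the sum of per-marker genotypic values (`-a`,
#' `d`, `+a`); yearly phenotypes add Gaussian environmental noise calibrated
#' so that the plug-in heritability `Var(g) / (Var(g) + sigma_e^2)` equals
#' `target_h2`.
#'
#' @param config a [sim_config].
#' @return list with `genotypes` ([genotype_table]), `phenotypes`
#'   (long data.frame `hybrid_id`, `trait`, `opv`, `year`) and `truth`
#'   (per-hybrid genetic values `g`, per-marker table `markers` with a, d,
#'   intended action and span, per-marker true class effects
#'   `class_effects` centred on the expected-frequency-weighted mean,
#'   `sigma_e`, `var_g`).
#' @export
simulate_f1_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_hybrids
  specs <- config$markers
  hybrid_ids <- sprintf("H%05d", seq_len(n))
  calls <- matrix(NA_character_, n, length(specs),
                  dimnames = list(hybrid_ids,
                                  vapply(specs, `[[`, character(1), "marker_id")))
  g <- numeric(n)
  marker_rows <- list()
  class_effects <- list()
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    g1 <- strsplit(sp$parent1, ":", fixed = TRUE)[[1]]
    g2 <- strsplit(sp$parent2, ":", fixed = TRUE)[[1]]
    gam1 <- g1[sample.int(2L, n, replace = TRUE)]
    gam2 <- g2[sample.int(2L, n, replace = TRUE)]
    cls <- normalize_call(paste(gam1, gam2, sep = ":"))
    calls[, j] <- cls
    vals <- marker_class_values(sp)
    g <- g + vals[cls]
    freqs <- marker_class_freqs(sp)
    vals_seg <- vals[names(freqs)]
    wmean <- sum(freqs * vals_seg)
    span <- max(vals_seg) - min(vals_seg)
    marker_rows[[j]] <- data.frame(
      marker_id = sp$marker_id, a = sp$a, d = sp$d,
      action = sp$action, span = span, stringsAsFactors = FALSE)
    class_effects[[sp$marker_id]] <- data.frame(
      class = names(freqs), value = unname(vals_seg),
      freq = unname(freqs), effect = unname(vals_seg - wmean),
      stringsAsFactors = FALSE)
  }
  g <- unname(g)
  var_g <- stats::var(g)
  if (var_g == 0) stop("all markers non-segregating in realized draw")
  sigma_e <- sqrt(var_g * (1 - config$target_h2) / config$target_h2)
  pheno <- do.call(rbind, lapply(seq_len(config$n_years), function(yr) {
    opv <- config$population_mean + g + stats::rnorm(n, 0, sigma_e)
    if (config$integer_mode) {
      opv <- round(pmin(pmax(opv, 0), config$max_month))
    }
    data.frame(hybrid_id = hybrid_ids, trait = config$trait, opv = opv,
               year = 2000L + yr, stringsAsFactors = FALSE)
  }))
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_character_
  }
  list(genotypes = genotype_table(calls),
       phenotypes = pheno,
       truth = list(g = stats::setNames(g, hybrid_ids),
                    markers = do.call(rbind, marker_rows),
                    class_effects = class_effects,
                    sigma_e = sigma_e, var_g = var_g))
}

#' Default storage-trajectory parameters per softening type
#'
#' Start values and softening rates (kg/cm^2 per month) chosen so each
#' deterministic trajectory satisfies its type's contract with a comfortable
#' margin relative to the measurement noise.
#' @param trait `"firmness"` or `"crispness"`.
#' @return nested list of parameters keyed by type.
#' @export
storage_defaults <- function(trait = c("firmness", "crispness")) {
  trait <- match.arg(trait)
  if (trait == "firmness") {
    list(I   = list(start = 6.0, decline = 0.8, noise_sd = 0.05),
         II  = list(start = 9.5, fast_drop = 1.8, slow_rate = 0.10,
                    noise_sd = 0.05),
         III = list(start = 8.5, slow_rate = 0.20, noise_sd = 0.05))
  } else {
    list(I   = list(start = 0.60, decline = 0.08, noise_sd = 0.005),
         II  = list(start = 0.95, fast_drop = 0.18, slow_rate = 0.010,
                    noise_sd = 0.005),
         III = list(start = 0.85, slow_rate = 0.020, noise_sd = 0.005))
  }
}

#' Simulate a cold-storage measurement series of a given softening type
#'
#' Type I starts below the acceptability threshold. Type II starts above,
#' drops by the fast-phase amount during the first month, then declines at
#' the slow rate, staying acceptable through month 6. Type III declines
#' linearly at a constant slow rate, staying acceptable through month 6.
#' Parameter sets whose deterministic trajectory cannot satisfy the type's
#' contract raise an error before any series is emitted.
#'
#' @param ptype `"I"`, `"II"` or `"III"`.
#' @param trait `"firmness"` or `"crispness"`.
#' @param params list overriding [storage_defaults()] entries for the type.
#' @param seed optional RNG seed.
#' @param hybrid_id identifier for the emitted series.
#' @param n_months last measured month.
#' @return a [storage_series].
#' @export
simulate_storage_series <- function(ptype = c("I", "II", "III"),
                                    trait = c("firmness", "crispness"),
                                    params = NULL, seed = NULL,
                                    hybrid_id = "SIM", n_months = 6L) {
  ptype <- match.arg(ptype)
  trait <- match.arg(trait)
  defs <- storage_defaults(trait)[[ptype]]
  if (!is.null(params)) defs[names(params)] <- params
  td <- trait_defaults()[[trait]]
  months <- 0:n_months
  traj <- switch(ptype,
    I = pmax(defs$start - defs$decline * months, 0),
    II = {
      v <- c(defs$start,
             defs$start - defs$fast_drop - defs$slow_rate * (months[-1] - 1))
      v
    },
    III = defs$start - defs$slow_rate * months)
  # contract checks on the noise-free trajectory
  if (ptype == "I" && traj[1] >= td$threshold) {
    stop("type I parameters start at/above the acceptability threshold")
  }
  if (ptype %in% c("II", "III") && any(traj < td$threshold)) {
    stop("type ", ptype,
         " parameters drop below the acceptability threshold before month ",
         n_months)
  }
  if (ptype == "II" && defs$fast_drop < td$rapid_drop) {
    stop("type II fast-phase drop below the rapid-drop cutoff")
  }
  if (ptype == "III" && defs$slow_rate >= td$rapid_drop) {
    stop("type III slow rate at/above the rapid-drop cutoff")
  }
  if (!is.null(seed)) set.seed(seed)
  values <- pmax(traj + stats::rnorm(length(months), 0, defs$noise_sd), 0)
  storage_series(hybrid_id, trait, months, values)
}

#' Simulate a candidate-gene fixture with construction-known truth
#'
#' Builds QTL intervals, gene spans, annotated variants, an expression matrix
#' and a DEG list in which each gene is assigned one generative scenario:
#' survive all filters, or fail exactly one of them (outside every QTL; no
#' impactful variant; expression undetectable; impactful variants confined to
#' the promoter without DEG support). The surviving set is recorded in the
#' returned manifest by construction, independently of the filtering code.
#' With `n_variants = 0` no variants are emitted and no gene can survive.
#'
#' @param n_genes number of genes.
#' @param n_variants approximate total variant budget; `0` suppresses all
#'   variants.
#' @param seed mandatory RNG seed.
#' @param out_dir optional directory to write `qtls.bed`, `genes.tsv`,
#'   `variants.vcf`, `expression.tsv`, `degs.txt` and `manifest.json`.
#' @return list with `qtls`, `genes` (with `expressed`/`is_deg` flags),
#'   `variants`, `expression`, `degs` and `manifest` (per-gene scenario plus
#'   the surviving gene ids).
#' @export
simulate_candidate_tables <- function(n_genes = 24, n_variants = 48, seed,
                                      out_dir = NULL) {
  if (missing(seed)) stop("simulate_candidate_tables requires a seed")
  stopifnot(n_genes >= 1, n_variants >= 0)
  set.seed(seed)
  qtls <- data.frame(
    chrom = c("chr03", "chr16", "chr11"),
    start = c(28500000, 38400000, 10000000),
    end   = c(29800000, 39500000, 11000000),
    label = c("Q03.1", "Q16.1", "Q11.1"),
    stringsAsFactors = FALSE)
  scenarios <- sample(c("pass", "fail_qtl", "fail_no_impact",
                        "fail_not_expressed", "fail_promoter_only"),
                      n_genes, replace = TRUE,
                      prob = c(0.30, 0.15, 0.20, 0.15, 0.20))
  per_gene <- if (n_variants == 0) 0L else
    max(1L, as.integer(round(n_variants / n_genes)))
  genes <- list(); variants <- list(); degs <- character()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("GENE%03d", i)
    sc <- scenarios[i]
    if (sc == "fail_qtl") {
      chrom <- "chr05"; gstart <- 1000000 + i * 10000
    } else {
      q <- qtls[sample.int(nrow(qtls), 1L), ]
      chrom <- q$chrom
      gstart <- q$start + sample.int(as.integer(q$end - q$start - 20000), 1L)
    }
    gend <- gstart + sample(2000:8000, 1L)
    expressed <- sc != "fail_not_expressed"
    is_deg <- FALSE
    gvars <- list()
    if (per_gene > 0L) {
      profile <- switch(sc,
        fail_no_impact = "none",
        fail_promoter_only = "promoter",
        pass = sample(c("domain", "promoter_deg"), 1L),
        sample(c("domain", "promoter_deg"), 1L))  # fail_qtl / fail_not_expressed
      if (profile == "promoter_deg") is_deg <- TRUE
      for (v in seq_len(per_gene)) {
        region <- switch(profile,
          none = sample(c("promoter", "CDS_other", "other"), 1L),
          promoter = "promoter",
          domain = if (v == 1L) "CDS_domain" else
            sample(c("CDS_other", "other"), 1L),
          promoter_deg = "promoter")
        impactful <- switch(profile,
          none = FALSE,
          promoter = v == 1L || stats::runif(1) < 0.5,
          domain = v == 1L,
          promoter_deg = v == 1L || stats::runif(1) < 0.5)
        variants[[length(variants) + 1L]] <- data.frame(
          chrom = chrom,
          pos0 = if (region == "promoter") gstart - sample(1:2000, 1L) else
            gstart + sample.int(gend - gstart, 1L),
          ref = sample(c("A", "C", "G", "T"), 1L),
          alt = sample(c("A", "C", "G", "T"), 1L),
          gene_id = gid, region = region,
          disrupts_cis_element = impactful && region == "promoter",
          disrupts_domain = impactful && region == "CDS_domain",
          stringsAsFactors = FALSE)
      }
    }
    # random DEG membership where the rules do not pin it down
    if (sc %in% c("fail_qtl", "fail_not_expressed", "fail_no_impact") &&
        stats::runif(1) < 0.3) is_deg <- TRUE
    if (sc == "fail_promoter_only") is_deg <- FALSE
    if (is_deg) degs <- c(degs, gid)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom,
                             start = gstart, end = gend,
                             expressed = expressed, is_deg = is_deg,
                             scenario = sc, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  variants <- if (length(variants)) do.call(rbind, variants) else
    utils::head(data.frame(chrom = character(), pos0 = numeric(),
                           ref = character(), alt = character(),
                           gene_id = character(), region = character(),
                           disrupts_cis_element = logical(),
                           disrupts_domain = logical(),
                           stringsAsFactors = FALSE), 0)
  n_samples <- 3L
  expr <- matrix(0, n_genes, n_samples,
                 dimnames = list(genes$gene_id, paste0("S", seq_len(n_samples))))
  on_rows <- which(genes$expressed)
  expr[on_rows, ] <- round(stats::runif(length(on_rows) * n_samples, 1, 100), 2)
  survivors <- if (n_variants == 0) character(0) else
    genes$gene_id[genes$scenario == "pass"]
  manifest <- list(seed = seed, n_genes = n_genes,
                   n_variants = nrow(variants),
                   scenario = stats::setNames(as.list(genes$scenario),
                                              genes$gene_id),
                   survivors = survivors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(qtls, file.path(out_dir, "qtls.bed"))
    utils::write.table(genes[c("gene_id", "chrom", "start", "end")],
                       file.path(out_dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_minimal_vcf(variants, file.path(out_dir, "variants.vcf"))
    utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                  check.names = FALSE),
                       file.path(out_dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(degs, file.path(out_dir, "degs.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(qtls = qtls, genes = genes, variants = variants,
       expression = expr, degs = degs, manifest = manifest)
}
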