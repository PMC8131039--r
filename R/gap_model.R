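# GAP model fitting, GPV prediction, Pearson accuracy, repeated k-fold CV.

#' Fit a genomics-assisted prediction (GAP) model
#'
#' Stores the pooled overall training mean together with every marker's
#' genotype-class effect table (see [estimate_genotype_effects()]). The
#' genomics-predicted value of a hybrid is the population mean plus the sum
#' of its genotype-class effects over all markers.
#'
#' @inheritParams estimate_genotype_effects
#' @return object of class `gap_model` with `trait`, `overall_mean`,
#'   `effects`, `training_ids`, `min_class_n`.
#' @export
gap_fit <- function(genotypes, phenotypes, trait = NULL, min_class_n = 3L) {
  effects <- estimate_genotype_effects(genotypes, phenotypes, trait,
                                       min_class_n = min_class_n)
  opv <- opv_by_hybrid(phenotypes, trait)
  structure(list(trait = if (is.null(trait)) unique(phenotypes$trait) else trait,
                 overall_mean = attr(effects, "overall_mean"),
                 effects = effects[seq_along(effects)],
                 training_ids = intersect(genotypes$hybrid_ids, names(opv)),
                 min_class_n = as.integer(min_class_n)),
            class = "gap_model")
}

#' @export
print.gap_model <- function(x, ...) {
  cat("gap_model:", x$trait, "| overall mean",
      sprintf("%.3f months |", x$overall_mean),
      length(x$effects), "markers |",
      length(x$training_ids), "training hybrids\n")
  invisible(x)
}

#' Predict genomics-predicted values (GPV)
#'
#' `gpv = overall_mean + sum over markers of the effect of the hybrid's
#' genotype class`. Only hybrids with a non-missing call at every model
#' marker receive a GPV (`complete = TRUE`); genotype classes unseen in
#' training contribute 0 and are counted in a single warning.
#'
#' @param object a `gap_model`.
#' @param genotypes a [genotype_table] covering all model markers.
#' @param warn_unseen emit a warning when unseen classes are encountered.
#' @param ... unused.
#' @return data.frame with `hybrid_id`, `gpv` (NA when incomplete),
#'   `complete`.
#' @export
predict.gap_model <- function(object, genotypes, warn_unseen = TRUE, ...) {
  stopifnot(inherits(genotypes, "genotype_table"))
  markers <- names(object$effects)
  absent <- setdiff(markers, genotypes$marker_ids)
  if (length(absent)) {
    stop("genotype table lacks model marker(s): ",
         paste(absent, collapse = ", "))
  }
  n <- length(genotypes$hybrid_ids)
  gpv <- rep(object$overall_mean, n)
  complete <- rep(TRUE, n)
  n_unseen <- 0L
  for (m in markers) {
    calls <- genotypes$calls[, m]
    complete <- complete & !is.na(calls)
    eff <- object$effects[[m]]$classes
    lookup <- stats::setNames(eff$effect, eff$class)
    contrib <- lookup[calls]
    unseen <- !is.na(calls) & is.na(contrib)
    n_unseen <- n_unseen + sum(unseen)
    contrib[is.na(contrib)] <- 0
    gpv <- gpv + unname(contrib)
  }
  if (n_unseen > 0L && warn_unseen) {
    warning(n_unseen, " genotype call(s) in classes unseen at training",
            " contributed zero effect")
  }
  gpv[!complete] <- NA_real_
  data.frame(hybrid_id = genotypes$hybrid_ids, gpv = gpv,
             complete = complete, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Join predictions with observed phenotype values
#'
#' @param predictions output of [predict.gap_model()].
#' @param phenotypes phenotype data.frame; multi-year records averaged.
#' @param trait trait to join on.
#' @return `predictions` with an `opv` column.
#' @export
add_opv <- function(predictions, phenotypes, trait = NULL) {
  opv <- opv_by_hybrid(phenotypes, trait)
  predictions$opv <- unname(opv[predictions$hybrid_id])
  predictions
}

#' Pearson prediction accuracy
#'
#' The accuracy of a GAP model is the Pearson correlation between GPV and
#' OPV over hybrids with both values.
#'
#' @param predictions data.frame with `gpv` and `opv` columns (rows with NA
#'   in either are dropped).
#' @return Pearson r.
#' @export
gap_accuracy <- function(predictions) {
  stopifnot(all(c("gpv", "opv") %in% names(predictions)))
  res <- correlate(predictions$gpv, predictions$opv)
  res$r
}

#' Repeated k-fold cross-validation of GAP accuracy
#'
#' Per run, hybrids with complete genotypes and phenotypes are partitioned at
#' random into k near-equal folds; each fold is predicted by a model fitted
#' (overall mean included) on the remaining folds and scored by Pearson
#' correlation. The reported accuracy is the unweighted mean over all
#' k x runs fold values. Folds whose correlation is undefined (constant
#' vectors) are skipped with a warning and counted.
#'
#' @inheritParams gap_fit
#' @param k number of folds (>= 2).
#' @param runs number of repeated random partitions.
#' @param seed RNG seed for the fold partitions.
#' @return object of class `cv_result`: `k`, `runs`, `fold_accuracy`
#'   (runs x k matrix), `mean_accuracy`, `n_skipped`, `n_hybrids`, `seed`.
#' @export
gap_cross_validate <- function(genotypes, phenotypes, trait = NULL,
                               k = 5L, runs = 5L, seed, min_class_n = 3L) {
  if (missing(seed)) stop("gap_cross_validate requires a seed")
  stopifnot(k >= 2L, runs >= 1L)
  opv <- opv_by_hybrid(phenotypes, trait)
  ids <- intersect(genotypes$hybrid_ids, names(opv))
  complete <- ids[!apply(is.na(genotypes$calls[ids, , drop = FALSE]), 1, any)]
  n <- length(complete)
  if (n < 2L * k) {
    stop("need >= 2k complete hybrids for ", k, "-fold CV; have ", n)
  }
  set.seed(seed)
  fold_acc <- matrix(NA_real_, runs, k)
  n_skipped <- 0L
  for (run in seq_len(runs)) {
    fold_of <- sample(rep_len(seq_len(k), n))
    for (fold in seq_len(k)) {
      test_ids <- complete[fold_of == fold]
      train_ids <- complete[fold_of != fold]
      gt_train <- subset_genotypes(genotypes, train_ids)
      gt_test <- subset_genotypes(genotypes, test_ids)
      ph_train <- phenotypes[phenotypes$hybrid_id %in% train_ids, ]
      model <- gap_fit(gt_train, ph_train, trait, min_class_n = min_class_n)
      pred <- predict(model, gt_test, warn_unseen = FALSE)
      pred$opv <- unname(opv[pred$hybrid_id])
      r <- tryCatch(gap_accuracy(pred), error = function(e) NA_real_)
      if (is.na(r)) n_skipped <- n_skipped + 1L else fold_acc[run, fold] <- r
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " fold(s) skipped: undefined correlation")
  }
  structure(list(k = as.integer(k), runs = as.integer(runs),
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc, na.rm = TRUE),
                 n_skipped = n_skipped, n_hybrids = n,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d runs on %d hybrids | mean accuracy %.4f\n",
              x$k, x$runs, x$n_hybrids, x$mean_accuracy))
  invisible(x)
}

#' Subset a genotype table by hybrid ids
#' @param genotypes a [genotype_table].
#' @param ids hybrid ids to keep (order preserved as given).
#' @return a [genotype_table].
#' @export
subset_genotypes <- function(genotypes, ids) {
  stopifnot(inherits(genotypes, "genotype_table"),
            all(ids %in% genotypes$hybrid_ids))
  # calls are already normalized and validated; rebuild without re-checking
  pop <- genotypes$population
  structure(list(calls = genotypes$calls[ids, , drop = FALSE],
                 hybrid_ids = ids,
                 marker_ids = genotypes$marker_ids,
                 population = if (is.null(pop)) NULL else pop[ids]),
            class = "genotype_table")
}
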