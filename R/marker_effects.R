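# Per-marker genotype-class effect estimation and dominance classification.

# per-hybrid observed phenotype values for one trait, averaging years
opv_by_hybrid <- function(phenotypes, trait = NULL) {
  if (!is.null(trait)) phenotypes <- phenotypes[phenotypes$trait == trait, ]
  if (length(unique(phenotypes$trait)) > 1L) {
    stop("several traits present; pass `trait`")
  }
  if (nrow(phenotypes) == 0L) stop("no phenotyped hybrids for trait ", trait)
  means <- tapply(phenotypes$opv, phenotypes$hybrid_id, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Estimate per-marker genotype-class effects
#'
#' A marker's genotype-class effect is the deviation between the average
#' observed phenotype value (OPV) of the hybrids carrying that genotype and
#' the overall mean OPV of the training population, pooled over crosses.
#' Hybrids with a missing call at a marker are excluded from that marker's
#' class means but stay in the overall mean. Classes with fewer than
#' `min_class_n` members are flagged and contribute a zero effect. The effect
#' span is the range (max - min) of retained class means, and the allelic
#' action is classified from the position of the heterozygote mean relative
#' to the homozygote midpoint (see [classify_allelic_action()]).
#'
#' @param genotypes a [genotype_table].
#' @param phenotypes phenotype data.frame (`hybrid_id`, `trait`, `opv`,
#'   optional `year`); multi-year records are averaged per hybrid.
#' @param trait trait to model.
#' @param min_class_n smallest class size whose mean is trusted.
#' @return list of per-marker effect entries, each with `marker_id`,
#'   `classes` (data.frame `class`, `count`, `mean`, `effect`, `retained`),
#'   `effect_span`, `action`, `empty`; plus attributes `overall_mean` and
#'   `n_train`.
#' @export
estimate_genotype_effects <- function(genotypes, phenotypes, trait = NULL,
                                      min_class_n = 3L) {
  stopifnot(inherits(genotypes, "genotype_table"))
  opv <- opv_by_hybrid(phenotypes, trait)
  ids <- intersect(genotypes$hybrid_ids, names(opv))
  if (length(ids) == 0L) stop("no phenotyped hybrids in the genotype table")
  opv <- opv[ids]
  overall_mean <- mean(opv)
  effects <- lapply(genotypes$marker_ids, function(m) {
    calls <- genotypes$calls[ids, m]
    ok <- !is.na(calls)
    if (!any(ok)) {
      return(list(marker_id = m,
                  classes = data.frame(class = character(), count = integer(),
                                       mean = numeric(), effect = numeric(),
                                       retained = logical(),
                                       stringsAsFactors = FALSE),
                  effect_span = 0, action = "undetermined", empty = TRUE))
    }
    cls <- sort(unique(calls[ok]))
    count <- vapply(cls, function(cl) sum(calls[ok] == cl), integer(1))
    cmean <- vapply(cls, function(cl) mean(opv[ok][calls[ok] == cl]), numeric(1))
    retained <- count >= min_class_n
    effect <- ifelse(retained, cmean - overall_mean, 0)
    span <- if (sum(retained) >= 2L) {
      max(cmean[retained]) - min(cmean[retained])
    } else 0
    entry <- list(marker_id = m,
                  classes = data.frame(class = cls, count = count,
                                       mean = cmean, effect = effect,
                                       retained = retained,
                                       row.names = NULL,
                                       stringsAsFactors = FALSE),
                  effect_span = span, empty = FALSE)
    entry$action <- classify_allelic_action(entry)
    entry
  })
  names(effects) <- genotypes$marker_ids
  attr(effects, "overall_mean") <- overall_mean
  attr(effects, "n_train") <- length(ids)
  effects
}

#' Classify a marker's allelic action from estimated class means
#'
#' Requires exactly three retained classes -- two homozygotes and the
#' heterozygote. With homozygote means `m1`, `m2` and heterozygote mean `mh`,
#' `a = (m1 - m2)/2` and `d = mh - (m1 + m2)/2`; the dominance degree
#' `|d/a|` is binned as in [allelic_action_from_ad()]. Markers segregating
#' into two classes (backcross-type het x hom markers) are
#' `"undetermined"` by construction.
#'
#' @param effect one per-marker entry from [estimate_genotype_effects()].
#' @param tol minimum `|a|` for classification.
#' @param cutoffs dominance-degree bin edges, see [allelic_action_from_ad()].
#' @return action label.
#' @export
classify_allelic_action <- function(effect, tol = 1e-8,
                                    cutoffs = c(0.2, 0.8, 1.2)) {
  cl <- effect$classes
  cl <- cl[cl$retained, , drop = FALSE]
  if (nrow(cl) != 3L) return("undetermined")
  het <- is_heterozygous(cl$class)
  if (sum(het) != 1L) return("undetermined")
  homs <- cl$mean[!het]
  a <- (homs[1] - homs[2]) / 2
  d <- cl$mean[het] - mean(homs)
  allelic_action_from_ad(a, d, tol = tol, cutoffs = cutoffs)
}

#' Flatten marker effects to a long table
#'
#' One row per (marker, genotype class), mirroring the usual
#' marker-effect supplementary-table shape.
#'
#' @param effects result of [estimate_genotype_effects()] or the `effects`
#'   element of a `gap_model`.
#' @return data.frame with `marker_id`, `class`, `count`, `mean`, `effect`,
#'   `retained`, `effect_span`, `action`.
#' @export
effects_table <- function(effects) {
  rows <- lapply(effects, function(e) {
    if (nrow(e$classes) == 0L) return(NULL)
    cbind(data.frame(marker_id = e$marker_id, stringsAsFactors = FALSE),
          e$classes,
          data.frame(effect_span = e$effect_span, action = e$action,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
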