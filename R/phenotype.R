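# Post-harvest phenotyping: retainability scoring, softening-type
# classification, broad-sense heritability, trait correlation.

#' Default acceptability thresholds and rapid-drop cutoffs (kg/cm^2)
#'
#' Acceptable flesh firmness is >= 7.0 kg/cm^2 and acceptable crispness
#' >= 0.7 kg/cm^2. The rapid-drop cutoff separating the fast first-month
#' softening of type II from the constant slow decline of type III is not a
#' published constant; the default mirrors the 10:1 firmness:crispness
#' threshold ratio.
#' @export
trait_defaults <- function() {
  list(firmness  = list(threshold = 7.0, rapid_drop = 1.0),
       crispness = list(threshold = 0.7, rapid_drop = 0.1))
}

#' Construct a cold-storage measurement series
#'
#' @param hybrid_id hybrid identifier.
#' @param trait `"firmness"` or `"crispness"`.
#' @param months strictly increasing integer months, starting at 0.
#' @param values measurements in kg/cm^2, same length as `months`, >= 0.
#' @return an object of class `storage_series`.
#' @export
storage_series <- function(hybrid_id, trait, months, values) {
  trait <- match.arg(trait, c("firmness", "crispness"))
  months <- as.integer(months)
  values <- as.numeric(values)
  if (length(months) == 0L) stop("empty storage series for ", hybrid_id)
  if (length(months) != length(values)) stop("months/values length mismatch")
  if (any(diff(months) <= 0L)) stop("months must be strictly increasing")
  if (months[1] != 0L) stop("series must include a month-0 measurement")
  if (any(values < 0)) stop("negative measurement value")
  structure(list(hybrid_id = hybrid_id, trait = trait,
                 months = months, values = values),
            class = "storage_series")
}

#' @export
print.storage_series <- function(x, ...) {
  cat("storage_series", x$hybrid_id, paste0("(", x$trait, "):"),
      paste(sprintf("%d:%.2f", x$months, x$values), collapse = " "), "\n")
  invisible(x)
}

#' Score retainability of a storage series
#'
#' Retainability is the maximum storage time, in whole months on the measured
#' grid, during which the trait stays at or above its acceptability threshold
#' (7.0 kg/cm^2 firmness, 0.7 kg/cm^2 crispness). It is the measured month
#' immediately before the first month whose value falls below the threshold;
#' 0 if acceptability is already lost at harvest; the last measured month,
#' flagged censored, if the series never crosses. A dip followed by recovery
#' still terminates retainability at the first crossing (acceptability is read
#' as maintained continuously).
#'
#' @param series a [storage_series].
#' @param threshold acceptability threshold in kg/cm^2; defaults to the
#'   trait's value from [trait_defaults()].
#' @return list with `hybrid_id`, `trait`, `retainability` (integer months)
#'   and `censored` (logical).
#' @export
compute_retainability <- function(series, threshold = NULL) {
  stopifnot(inherits(series, "storage_series"))
  if (is.null(threshold)) threshold <- trait_defaults()[[series$trait]]$threshold
  stopifnot(is.numeric(threshold), threshold > 0)
  below <- which(series$values < threshold)
  if (length(below) == 0L) {
    ret <- series$months[length(series$months)]
    censored <- TRUE
  } else if (below[1] == 1L) {
    ret <- 0L
    censored <- FALSE
  } else {
    ret <- series$months[below[1] - 1L]
    censored <- FALSE
  }
  list(hybrid_id = series$hybrid_id, trait = series$trait,
       retainability = as.integer(ret), censored = censored)
}

#' Classify the softening dynamics type of a hybrid
#'
#' Type I: acceptability lost already at harvest (retainability 0). Type II:
#' acceptability maintained until the sixth month after a rapid softening
#' during the first month of storage. Type III: maintained through the sixth
#' month with a constant slow softening rate. Series with intermediate
#' retainability (1-5 months) are the bulk of a segregating population and
#' stay `"unclassified"`.
#'
#' @param record result of [compute_retainability()].
#' @param series the [storage_series] the record was computed from.
#' @param rapid_drop month 0 to month 1 drop (kg/cm^2) at or above which a
#'   month-6 retainer is called type II rather than III; defaults per trait.
#' @return one of `"I"`, `"II"`, `"III"`, `"unclassified"`.
#' @export
classify_type <- function(record, series, rapid_drop = NULL) {
  stopifnot(inherits(series, "storage_series"))
  if (is.null(rapid_drop)) rapid_drop <- trait_defaults()[[series$trait]]$rapid_drop
  if (record$retainability == 0L) return("I")
  if (record$retainability >= 6L) {
    i0 <- match(0L, series$months)
    i1 <- match(1L, series$months)
    if (is.na(i1)) {
      warning("series ", record$hybrid_id,
              " lacks a month-1 point; type II/III indistinguishable")
      return("unclassified")
    }
    drop1 <- series$values[i0] - series$values[i1]
    return(if (drop1 >= rapid_drop) "II" else "III")
  }
  "unclassified"
}

#' Score and type a batch of storage series
#'
#' @param series_list list of [storage_series].
#' @param thresholds named list overriding [trait_defaults()] thresholds.
#' @param rapid_drops named list overriding rapid-drop cutoffs.
#' @return data.frame with `hybrid_id`, `trait`, `retainability`, `censored`,
#'   `ptype`.
#' @export
score_storage <- function(series_list, thresholds = NULL, rapid_drops = NULL) {
  defs <- trait_defaults()
  rows <- lapply(series_list, function(s) {
    thr <- if (!is.null(thresholds[[s$trait]])) thresholds[[s$trait]] else
      defs[[s$trait]]$threshold
    rd <- if (!is.null(rapid_drops[[s$trait]])) rapid_drops[[s$trait]] else
      defs[[s$trait]]$rapid_drop
    rec <- compute_retainability(s, thr)
    data.frame(hybrid_id = rec$hybrid_id, trait = rec$trait,
               retainability = rec$retainability, censored = rec$censored,
               ptype = classify_type(rec, s, rd), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Broad-sense heritability from multi-year phenotype records
#'
#' One-way ANOVA with hybrids as groups and years as replicates:
#' `var_g = (MS_hybrid - MS_error)/r` (clamped at 0), `var_e = MS_error`,
#' and on the default plot basis `H2 = var_g / (var_g + var_e)`. The
#' entry-mean basis (`var_g / (var_g + var_e/r)`) describes selection on
#' hybrid means across r years. Hybrids lacking a record in any observed year
#' are dropped so the design is balanced.
#'
#' @param phenotypes data.frame with `hybrid_id`, `trait`, `opv`, `year`.
#' @param trait trait to estimate for (required when several are present).
#' @param basis `"plot"` (default) or `"entry_mean"`.
#' @return list with `trait`, `h2`, `var_g`, `var_e`, `n_hybrids`, `n_years`,
#'   `basis`.
#' @export
estimate_h2 <- function(phenotypes, trait = NULL, basis = c("plot", "entry_mean")) {
  basis <- match.arg(basis)
  if (!is.null(trait)) phenotypes <- phenotypes[phenotypes$trait == trait, ]
  if (length(unique(phenotypes$trait)) > 1L) {
    stop("several traits present; pass `trait`")
  }
  if (anyNA(phenotypes$year)) stop("heritability needs per-year records")
  years <- sort(unique(phenotypes$year))
  r <- length(years)
  if (r < 2L) stop("heritability needs records from >= 2 years")
  tab <- table(phenotypes$hybrid_id)
  # balance: keep hybrids observed in every year
  wide <- stats::reshape(phenotypes[c("hybrid_id", "year", "opv")],
                         idvar = "hybrid_id", timevar = "year",
                         direction = "wide")
  complete <- wide[stats::complete.cases(wide), ]
  g <- nrow(complete)
  if (g < 2L) stop("need >= 2 hybrids with complete multi-year records")
  y <- as.matrix(complete[, -1, drop = FALSE])
  row_means <- rowMeans(y)
  grand <- mean(y)
  ss_between <- r * sum((row_means - grand)^2)
  ss_within <- sum((y - row_means)^2)
  ms_between <- ss_between / (g - 1)
  ms_within <- ss_within / (g * (r - 1))
  var_g <- max(0, (ms_between - ms_within) / r)
  var_e <- ms_within
  denom <- if (basis == "plot") var_g + var_e else var_g + var_e / r
  h2 <- if (denom == 0) 0 else var_g / denom
  list(trait = if (is.null(trait)) unique(phenotypes$trait) else trait,
       h2 = h2, var_g = var_g, var_e = var_e,
       n_hybrids = g, n_years = r, basis = basis)
}

#' Pearson correlation between two traits across hybrids
#'
#' Pairs with any missing value are dropped and the number of complete pairs
#' reported alongside r.
#'
#' @param x,y numeric vectors of per-hybrid values (aligned).
#' @return list with `r` and `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one trait")
  }
  list(r = stats::cor(x, y), n = n)
}
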