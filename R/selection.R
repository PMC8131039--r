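# Simulative truncation selection on genomics-predicted values.

#' Simulative selection by a GPV criterion
#'
#' Selects every hybrid whose GPV is at or above the criterion (ties are
#' selected). The selection rate is the selected fraction of hybrids with a
#' GPV (complete genotypes); the efficiency is the fraction of selected
#' hybrids whose observed phenotype value also meets the criterion, and is
#' undefined (NA) when nothing is selected.
#'
#' @param predictions data.frame with `hybrid_id`, `gpv`, `opv` (rows with
#'   NA gpv are ignored, they carry incomplete genotypes).
#' @param criterion selection threshold, months.
#' @return object of class `selection_result`: `criterion`, `selected_ids`,
#'   `n_total`, `n_selected`, `selection_rate`, `efficiency`.
#' @export
simulate_selection <- function(predictions, criterion) {
  stopifnot(is.finite(criterion),
            all(c("hybrid_id", "gpv", "opv") %in% names(predictions)))
  pool <- predictions[!is.na(predictions$gpv), ]
  n_total <- nrow(pool)
  if (n_total == 0L) stop("no hybrids with a GPV to select from")
  sel <- pool[pool$gpv >= criterion, ]
  n_sel <- nrow(sel)
  efficiency <- if (n_sel == 0L) NA_real_ else
    mean(sel$opv >= criterion, na.rm = FALSE)
  structure(list(criterion = criterion,
                 selected_ids = sel$hybrid_id,
                 n_total = n_total,
                 n_selected = n_sel,
                 selection_rate = n_sel / n_total,
                 efficiency = efficiency),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: criterion %.2f months | %d/%d selected (rate %.2f%%) | efficiency %s\n",
    x$criterion, x$n_selected, x$n_total, 100 * x$selection_rate,
    if (is.na(x$efficiency)) "undefined" else
      sprintf("%.2f%% (%d/%d)", 100 * x$efficiency,
              round(x$efficiency * x$n_selected), x$n_selected)))
  invisible(x)
}
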