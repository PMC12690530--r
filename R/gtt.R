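#' Glucose tolerance test AUC and diabetic classification
#'
#' Trapezoidal area under the blood-glucose curve, in mg.h/dl, with a
#' strict inclusion cutoff: an animal is classified diabetic only when
#' `auc > cutoff` (an AUC exactly at the cutoff is not diabetic). The
#' default cutoff is 435 mg.h/dl, the time- and species-adjusted criterion
#' used for study inclusion.
#'
#' @param series Data frame with columns `time_h` (strictly increasing,
#'   hours) and `glucose_mg_dl` (non-negative, mg/dl); at least 2 points.
#' @param cutoff Inclusion cutoff in mg.h/dl (default 435).
#'
#' @return A one-row tibble: `auc`, `cutoff`, `diabetic`.
#' @export
#' @examples
#' gtt_auc(generate_gtt_series(200, c(400, 400, 300))) # auc 525, diabetic
gtt_auc <- function(series, cutoff = 435) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "glucose_mg_dl") %in% names(series)))
  t <- series$time_h; g <- series$glucose_mg_dl
  if (length(t) < 2) stop_ivd("GTT series needs at least 2 time points.", "bad_gtt")
  if (any(diff(t) <= 0)) stop_ivd("GTT times must be strictly increasing.", "bad_gtt")
  if (any(!is.finite(g)) || any(g < 0)) {
    stop_ivd("Glucose values must be non-negative and finite.", "bad_gtt")
  }
  check_scalar_number(cutoff, "cutoff", 0)
  auc <- sum(diff(t) * (head(g, -1) + g[-1]) / 2)
  tibble(auc = auc, cutoff = cutoff, diabetic = auc > cutoff)
}
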