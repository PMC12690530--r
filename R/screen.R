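#' Collapse pseudo-replicates to one row per animal
#'
#' Each animal's technical pseudo-replicates are pared down to a single
#' representative value per cytokine by taking the median over the detected
#' (non-OOR) replicate values. An entry stays flagged (NA) only when every
#' replicate was out of range. Collapsing is idempotent: applying it to an
#' already collapsed panel is the identity.
#'
#' @param panel A cytokine panel tibble (`animal_id`, `group`, `replicate`,
#'   one numeric column per cytokine; `NA` = out of range).
#'
#' @return A tibble with one row per animal (`replicate` set to 1).
#' @export
collapse_pseudoreplicates <- function(panel) {
  check_panel(panel)
  cyt <- cytokine_cols(panel)
  out <- panel %>%
    as_tibble() %>%
    group_by(.data$animal_id, .data$group) %>%
    summarise(
      across(all_of(cyt), ~ {
        v <- .x[!is.na(.x)]
        if (length(v) == 0) NA_real_ else median(v)
      }),
      .groups = "drop"
    ) %>%
    mutate(replicate = 1L) %>%
    select(all_of(panel_id_cols), all_of(cyt))
  # preserve input animal order
  out[match(unique(panel$animal_id), out$animal_id), ]
}

#' Exclude cytokines with excessive out-of-range missingness
#'
#' A cytokine is excluded when the fraction of flagged (out-of-range)
#' animals, pooled across all experimental groups, is strictly greater than
#' `max_fraction`; exactly `max_fraction` is retained.
#'
#' @param panel A collapsed cytokine panel (one row per animal).
#' @param max_fraction Exclusion threshold on the missing fraction
#'   (default 0.25).
#'
#' @return A list with `panel` (retained cytokines) and `excluded`, a tibble
#'   of excluded cytokines and their missing fractions.
#' @export
filter_missingness <- function(panel, max_fraction = 0.25) {
  check_panel(panel)
  check_scalar_number(max_fraction, "max_fraction", 0, 1)
  cyt <- cytokine_cols(panel)
  frac <- vapply(panel[cyt], function(v) mean(is.na(v)), numeric(1))
  drop <- names(frac)[frac > max_fraction]
  list(
    panel = panel %>% select(-all_of(drop)),
    excluded = tibble(cytokine = drop, missing_fraction = unname(frac[drop]))
  )
}

#' Welch's unpaired two-sample t-test
#'
#' The unequal-variance t statistic
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student t distribution. When both samples have zero variance the test is
#' degenerate: p = 1 if the means are equal, otherwise p = 0 with
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors with at least 2 non-missing values each.
#'
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `degenerate`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, df = 4, p ~ 0.0214
welch_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_ivd("Both samples need at least 2 detected values.", "too_few_values")
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- var(a) / na; vb <- var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    equal <- isTRUE(all.equal(ma, mb))
    return(tibble(t = if (equal) 0 else sign(ma - mb) * Inf,
                  df = na + nb - 2, p = if (equal) 1 else 0,
                  mean_a = ma, mean_b = mb, n_a = na, n_b = nb,
                  degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  tibble(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
         n_a = na, n_b = nb, degenerate = FALSE)
}

#' Differential cytokine screen between two groups
#'
#' Runs Welch's t-test per cytokine between a case and a control group on a
#' collapsed, missingness-filtered panel. A cytokine is flagged upregulated
#' when `p < alpha` and the case mean exceeds the control mean (the screen
#' is directional; no multiple-testing correction is applied, matching the
#' single-panel screening design).
#'
#' @param panel Collapsed panel tibble.
#' @param case_group,control_group Group labels present in `panel`.
#' @param alpha Significance level (default 0.05).
#'
#' @return A tibble sorted by p-value: `cytokine`, `mean_case`,
#'   `mean_control`, `t`, `df`, `p`, `upregulated`; cytokines with fewer
#'   than 2 detected values in either group carry `NA` statistics and are
#'   never flagged.
#' @export
differential_screen <- function(panel, case_group, control_group, alpha = 0.05) {
  check_panel(panel)
  check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  for (g in c(case_group, control_group)) {
    if (!g %in% panel$group) {
      stop_ivd(sprintf("Group '%s' not present in panel.", g), "unknown_group")
    }
  }
  cyt <- cytokine_cols(panel)
  rows_case <- panel$group == case_group
  rows_ctrl <- panel$group == control_group
  res <- purrr::map_dfr(cyt, function(cy) {
    a <- panel[[cy]][rows_case]; b <- panel[[cy]][rows_ctrl]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      return(tibble(cytokine = cy, mean_case = mean(a, na.rm = TRUE),
                    mean_control = mean(b, na.rm = TRUE),
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    upregulated = FALSE))
    }
    w <- welch_test(a, b)
    tibble(cytokine = cy, mean_case = w$mean_a, mean_control = w$mean_b,
           t = w$t, df = w$df, p = w$p,
           upregulated = !is.na(w$p) & w$p < alpha & w$mean_a > w$mean_b)
  })
  res %>% arrange(.data$p)
}

#' Per-animal fold changes over the control-group mean
#'
#' For each case animal and cytokine, the fold change is the animal's
#' concentration divided by the control group's mean concentration of that
#' cytokine (detected values only). Scale-invariant: multiplying all values
#' of a cytokine by a constant leaves its fold changes unchanged.
#'
#' @param panel Collapsed panel tibble.
#' @param model_case Case (model) group label.
#' @param model_control Matched control group label.
#' @param cytokines Optional character vector restricting the analysis
#'   (e.g. the upregulated set from [differential_screen()]); default all.
#' @param model_label Label recorded in the output's `model` column
#'   (default `model_case`).
#'
#' @return A long tibble: `model`, `animal_id`, `cytokine`, `fc`.
#' @export
fold_change_analysis <- function(panel, model_case, model_control,
                                 cytokines = NULL, model_label = model_case) {
  check_panel(panel)
  for (g in c(model_case, model_control)) {
    if (!g %in% panel$group) {
      stop_ivd(sprintf("Group '%s' not present in panel.", g), "unknown_group")
    }
  }
  cyt <- cytokine_cols(panel)
  if (!is.null(cytokines)) {
    unknown <- setdiff(cytokines, cyt)
    if (length(unknown) > 0) {
      stop_ivd(paste0("Unknown cytokine(s): ", paste(unknown, collapse = ", ")),
               "unknown_cytokine")
    }
    cyt <- cytokines
  }
  ctrl <- panel[panel$group == model_control, ]
  case <- panel[panel$group == model_case, ]
  purrr::map_dfr(cyt, function(cy) {
    cm <- mean(ctrl[[cy]], na.rm = TRUE)
    if (!is.finite(cm) || cm <= 0) {
      stop_ivd(sprintf("Control mean for '%s' is zero or undefined.", cy),
               "bad_control_mean")
    }
    v <- case[[cy]]
    keep <- !is.na(v)
    tibble(model = model_label, animal_id = case$animal_id[keep],
           cytokine = cy, fc = v[keep] / cm)
  })
}

#' Compare fold-change distributions between two models
#'
#' Welch's t-test on the per-animal fold changes of each cytokine shared by
#' two fold-change tables (e.g. the STZ-HFD and db/db models), reporting the
#' direction of the difference.
#'
#' @param fc_model1,fc_model2 Fold-change tibbles from
#'   [fold_change_analysis()].
#' @param cytokines Cytokines to compare; default the intersection. A
#'   requested cytokine absent from either table is an error, not a silent
#'   `NA`.
#'
#' @return A tibble per cytokine: means, `t`, `df`, `p`, and `higher_model`
#'   (label of the model with the larger mean fold change; `NA` when equal).
#' @export
compare_fold_changes <- function(fc_model1, fc_model2, cytokines = NULL) {
  stopifnot(all(c("model", "cytokine", "fc") %in% names(fc_model1)),
            all(c("model", "cytokine", "fc") %in% names(fc_model2)))
  if (is.null(cytokines)) {
    cytokines <- intersect(unique(fc_model1$cytokine), unique(fc_model2$cytokine))
  }
  lab1 <- fc_model1$model[1]; lab2 <- fc_model2$model[1]
  purrr::map_dfr(cytokines, function(cy) {
    a <- fc_model1$fc[fc_model1$cytokine == cy]
    b <- fc_model2$fc[fc_model2$cytokine == cy]
    if (length(a) == 0 || length(b) == 0) {
      stop_ivd(sprintf("Cytokine '%s' absent from one of the models.", cy),
               "unknown_cytokine")
    }
    w <- welch_test(a, b)
    tibble(cytokine = cy, model_1 = lab1, model_2 = lab2,
           mean_fc_1 = w$mean_a, mean_fc_2 = w$mean_b,
           t = w$t, df = w$df, p = w$p,
           higher_model = if (w$mean_a == w$mean_b) NA_character_
                          else if (w$mean_a > w$mean_b) lab1 else lab2)
  })
}
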