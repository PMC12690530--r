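# Internal helpers shared across modules.

# Run `expr` under a local RNG seeded with `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_ivd <- function(msg, class) {
  rlang::abort(msg, class = paste0("ivdnet_", class))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_ivd(sprintf("`%s` must be a single finite number.", name), "bad_argument")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_ivd(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ), "bad_argument")
  }
  invisible(x)
}

# Identify the cytokine measurement columns of a panel tibble.
panel_id_cols <- c("animal_id", "group", "replicate")

cytokine_cols <- function(panel) {
  setdiff(names(panel), panel_id_cols)
}

check_panel <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    stop_ivd("`panel` must be a non-empty data frame.", "bad_panel")
  }
  missing_ids <- setdiff(panel_id_cols, names(panel))
  if (length(missing_ids) > 0) {
    stop_ivd(paste0(
      "`panel` is missing required column(s): ",
      paste(missing_ids, collapse = ", ")
    ), "bad_panel")
  }
  if (length(cytokine_cols(panel)) == 0) {
    stop_ivd("`panel` has no cytokine columns.", "bad_panel")
  }
  invisible(panel)
}
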