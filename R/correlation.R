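#' Per-group Pearson correlation matrix of cytokine concentrations
#'
#' Pairwise-complete Pearson correlations over the animals of one group,
#' computed on a collapsed, missingness-filtered panel. Pairs with fewer
#' than 3 complete observations, or involving a constant cytokine, have an
#' undefined correlation (`NA`), which downstream thresholding treats as
#' below threshold. The per-pair sample counts are retained because with
#' n = 3 animals a Pearson r at |r| > 0.7 is extremely noisy.
#'
#' @param panel Collapsed panel tibble.
#' @param group Group label; at least 3 animals required.
#'
#' @return A `correlation_matrix`: list with `r` (symmetric matrix, unit
#'   diagonal), `n_pairs` (complete-observation counts) and `group`.
#' @export
correlation_matrix <- function(panel, group) {
  check_panel(panel)
  if (!group %in% panel$group) {
    stop_ivd(sprintf("Group '%s' not present in panel.", group), "unknown_group")
  }
  sub <- panel[panel$group == group, cytokine_cols(panel), drop = FALSE]
  if (nrow(sub) < 3) {
    stop_ivd("Need at least 3 animals in the group after collapse.", "too_few_animals")
  }
  m <- as.matrix(sub)
  obs <- !is.na(m)
  n_pairs <- crossprod(obs)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r[n_pairs < 3] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, n_pairs = n_pairs, group = group),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> group '%s', %d cytokines\n",
              x$group, ncol(x$r)))
  invisible(x)
}
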