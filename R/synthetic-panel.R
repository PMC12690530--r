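#' Describe the group layout of a simulated study
#'
#' A group design records the experimental groups, the number of animals per
#' group, and how many technical pseudo-replicates are assayed per animal.
#' The default reproduces the four-arm diabetic mouse layout used throughout
#' the package: two genetic arms (db/+ control, db/db) and two induced arms
#' (Con+Veh control, STZ-HFD), with small per-group n.
#'
#' @param groups Character vector of unique group labels (at least 2).
#' @param n_per_group Integer vector of animals per group (each >= 2),
#'   recycled to `length(groups)` if scalar.
#' @param pseudoreplicates_per_animal Technical replicates per animal (>= 1).
#'
#' @return A `group_design` list.
#' @export
#' @examples
#' group_design(c("ctrl", "case"), n_per_group = c(3, 9))
group_design <- function(groups = c("db/+", "db/db", "Con+Veh", "STZ-HFD"),
                         n_per_group = c(3, 3, 3, 9),
                         pseudoreplicates_per_animal = 2) {
  groups <- as.character(groups)
  if (length(groups) < 2 || anyDuplicated(groups) > 0) {
    stop_ivd("`groups` must hold at least 2 unique labels.", "bad_design")
  }
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, length(groups))
  if (length(n_per_group) != length(groups) || any(n_per_group < 2) ||
      any(n_per_group != round(n_per_group))) {
    stop_ivd("`n_per_group` must give an integer >= 2 for every group.", "bad_design")
  }
  check_scalar_number(pseudoreplicates_per_animal, "pseudoreplicates_per_animal", lower = 1)
  structure(
    list(
      groups = groups,
      n_per_group = as.integer(n_per_group),
      pseudoreplicates_per_animal = as.integer(pseudoreplicates_per_animal)
    ),
    class = "group_design"
  )
}

#' Describe the planted correlation structure of a simulated cytokine panel
#'
#' Cytokine concentrations are simulated log-normally; correlation between
#' cytokines is induced on the log scale by shared latent factors, one per
#' block plus one global factor, so that the population Pearson correlation
#' equals `within_block_r` inside a block and `between_block_r` across
#' blocks. Group-specific mean shifts are planted as multiplicative fold
#' changes. Out-of-range (OOR) missingness is left-censored: per cytokine,
#' the lowest `missing_rate` fraction of simulated values is flagged,
#' matching the detection-limit mechanism of multiplex assays.
#'
#' @param blocks Named (or unnamed) list of character vectors partitioning
#'   the cytokine names into disjoint co-regulation modules.
#' @param within_block_r Target log-scale correlation within a block, in \[0, 1).
#' @param between_block_r Target correlation across blocks, in
#'   \[0, `within_block_r`).
#' @param upregulated Named list: group label -> named numeric vector of
#'   fold multipliers (> 0) applied to that group's mean concentrations.
#' @param missing_rate Fraction of entries flagged out-of-range, in \[0, 1).
#' @param noise_sd Log-scale standard deviation of the concentrations
#'   (default 0.3, about a 30% coefficient of variation — typical for
#'   multiplex immunoassays).
#' @param base_mean Baseline concentration in pg/ml around which all
#'   cytokines are centred.
#' @param technical_sd Log-scale standard deviation of the pseudo-replicate
#'   (technical) noise added around each animal's value.
#'
#' @return A `correlation_structure` list.
#' @export
#' @examples
#' correlation_structure(
#'   blocks = list(A = c("CCL2", "CCL3"), B = c("IL-6", "CXCL1")),
#'   within_block_r = 0.9, between_block_r = 0
#' )
correlation_structure <- function(blocks,
                                  within_block_r = 0.7,
                                  between_block_r = 0.1,
                                  upregulated = list(),
                                  missing_rate = 0,
                                  noise_sd = 0.3,
                                  base_mean = 100,
                                  technical_sd = 0.05) {
  if (!is.list(blocks) || length(blocks) == 0) {
    stop_ivd("`blocks` must be a non-empty list of cytokine name vectors.", "bad_structure")
  }
  cytokines <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(cytokines) > 0) {
    stop_ivd("`blocks` must partition the cytokines: duplicates found.", "bad_structure")
  }
  check_scalar_number(within_block_r, "within_block_r", 0, 1, strict_upper = TRUE)
  check_scalar_number(between_block_r, "between_block_r", 0, within_block_r,
                      strict_upper = within_block_r > 0)
  check_scalar_number(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  check_scalar_number(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_scalar_number(base_mean, "base_mean", 0, strict_lower = TRUE)
  check_scalar_number(technical_sd, "technical_sd", 0)
  for (g in names(upregulated)) {
    fm <- upregulated[[g]]
    if (!is.numeric(fm) || is.null(names(fm)) || any(fm <= 0)) {
      stop_ivd("`upregulated` entries must be named numeric vectors of fold multipliers > 0.",
               "bad_structure")
    }
    unknown <- setdiff(names(fm), cytokines)
    if (length(unknown) > 0) {
      stop_ivd(paste0("Unknown cytokine(s) in `upregulated`: ",
                      paste(unknown, collapse = ", ")), "bad_structure")
    }
  }
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  structure(
    list(
      blocks = blocks, cytokines = cytokines,
      within_block_r = within_block_r, between_block_r = between_block_r,
      upregulated = upregulated, missing_rate = missing_rate,
      noise_sd = noise_sd, base_mean = base_mean, technical_sd = technical_sd
    ),
    class = "correlation_structure"
  )
}

#' Simulate a multiplex cytokine panel with planted ground truth
#'
#' Generates one row per (animal, pseudo-replicate) in wide format:
#' `animal_id`, `group`, `replicate`, then one numeric column per cytokine
#' (pg/ml). Entries flagged out-of-range are `NA`. The planted truth —
#' block partition, fold multipliers, flagged cells — is attached as the
#' `"ground_truth"` attribute so downstream recovery can be scored.
#'
#' Concentrations are log-normal: on the log scale each animal draws a
#' global factor, one factor per block, and an independent residual, mixed
#' so the population correlation is `within_block_r` within blocks and
#' `between_block_r` across blocks. Pseudo-replicates add independent
#' technical noise around the animal-level value.
#'
#' @param design A [group_design()].
#' @param structure A [correlation_structure()].
#' @param seed Integer seed; identical `(design, structure, seed)` give
#'   bit-identical panels.
#'
#' @return A tibble of class `cytokine_panel` with attribute `ground_truth`.
#' @export
#' @examples
#' des <- group_design(c("ctrl", "case"), c(3, 3), pseudoreplicates_per_animal = 2)
#' str <- correlation_structure(list(c("CCL2", "CCL3", "IL-6")),
#'                              within_block_r = 0.8, between_block_r = 0)
#' panel <- generate_cytokine_panel(des, str, seed = 1)
generate_cytokine_panel <- function(design, structure, seed) {
  stopifnot(inherits(design, "group_design"), inherits(structure, "correlation_structure"))
  cyt <- structure$cytokines
  n_cyt <- length(cyt)
  block_of <- rep(names(structure$blocks), lengths(structure$blocks))
  names(block_of) <- unlist(structure$blocks, use.names = FALSE)
  block_of <- block_of[cyt]

  # Variance split: z = sqrt(b)*g0 + sqrt(w-b)*g_block + sqrt(1-w)*eps
  # gives corr w within block, b across blocks, unit variance.
  w <- structure$within_block_r
  b <- structure$between_block_r
  load_global <- sqrt(b)
  load_block <- sqrt(w - b)
  load_resid <- sqrt(1 - w)

  groups_rep <- rep(design$groups, design$n_per_group)
  n_animals <- length(groups_rep)
  animal_ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", ".", groups_rep),
                        unlist(lapply(design$n_per_group, seq_len)))

  with_seed(seed, {
    g0 <- rnorm(n_animals)
    gb <- matrix(rnorm(n_animals * length(structure$blocks)), n_animals,
                 dimnames = list(NULL, names(structure$blocks)))
    eps <- matrix(rnorm(n_animals * n_cyt), n_animals, n_cyt)
    z <- load_global * g0 + load_block * gb[, block_of, drop = FALSE] +
      load_resid * eps

    log_mu <- matrix(log(structure$base_mean), n_animals, n_cyt,
                     dimnames = list(NULL, cyt))
    for (g in names(structure$upregulated)) {
      fm <- structure$upregulated[[g]]
      rows <- groups_rep == g
      log_mu[rows, names(fm)] <- sweep(log_mu[rows, names(fm), drop = FALSE],
                                       2, log(fm), "+")
    }
    animal_log <- log_mu + structure$noise_sd * z

    n_rep <- design$pseudoreplicates_per_animal
    rep_rows <- rep(seq_len(n_animals), each = n_rep)
    tech <- matrix(rnorm(n_animals * n_rep * n_cyt, sd = structure$technical_sd),
                   n_animals * n_rep, n_cyt)
    values <- exp(animal_log[rep_rows, , drop = FALSE] + tech)

    # Left-censored OOR flags: per cytokine, values below the missing_rate
    # quantile are outside the assay range.
    flagged <- matrix(FALSE, nrow(values), n_cyt)
    if (structure$missing_rate > 0) {
      for (j in seq_len(n_cyt)) {
        thr <- quantile(values[, j], probs = structure$missing_rate,
                        names = FALSE, type = 7)
        flagged[, j] <- values[, j] < thr
      }
    }
    values[flagged] <- NA_real_

    panel <- tibble(
      animal_id = animal_ids[rep_rows],
      group = groups_rep[rep_rows],
      replicate = rep(seq_len(n_rep), times = n_animals)
    )
    panel[cyt] <- as.data.frame(values)
    class(panel) <- c("cytokine_panel", class(panel))
    attr(panel, "ground_truth") <- list(
      blocks = structure$blocks,
      block_of = block_of,
      upregulated = structure$upregulated,
      flagged = which(flagged, arr.ind = TRUE),
      animal_log_means = animal_log
    )
    panel
  })
}
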