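#' Simulate expert pairwise-comparison matrices
#'
#' Draws reciprocal comparison matrices scattered around a common consistent
#' matrix: each upper-triangle entry of the consistent matrix `w[i]/w[j]` is
#' perturbed by a lognormal factor `exp(N(0, jitter_sd))` and the lower
#' triangle is filled with the reciprocals, emulating a panel of experts who
#' share an underlying ranking but judge with noise.
#'
#' @param n_experts Number of matrices to draw.
#' @param weights Positive named vector of true factor weights.
#' @param jitter_sd Standard deviation of the log-scale judgment noise;
#'   0 returns perfectly consistent copies.
#' @return List of `comparison_matrix` objects.
#' @export
rcomparison_matrices <- function(n_experts, weights, jitter_sd = 0.15) {
  stopifnot(n_experts >= 1, all(weights > 0), jitter_sd >= 0)
  if (is.null(names(weights))) names(weights) <- paste0("f", seq_along(weights))
  n <- length(weights)
  base <- outer(weights, weights, `/`)
  lapply(seq_len(n_experts), function(e) {
    m <- base
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- base[i, j] * exp(stats::rnorm(1, 0, jitter_sd))
        m[j, i] <- 1 / m[i, j]
      }
    }
    diag(m) <- 1
    validate_matrix(m, names(weights))
  })
}

#' Simulate a Delphi score table
#'
#' Generates an expert-by-factor table of 9-point Likert scores around
#' per-factor consensus locations: expert scores are the consensus plus
#' integer-rounded Gaussian noise, clamped to 1..9. Useful for exercising the
#' band rules on panels whose true consensus is known.
#'
#' @param n_experts Panel size.
#' @param consensus Named numeric vector of per-factor consensus scores in
#'   `[1, 9]`.
#' @param noise_sd Standard deviation of the expert noise (score points).
#' @param dimension Passed to [delphi_scores()].
#' @return A `delphi_scores` object.
#' @export
rdelphi_scores <- function(n_experts, consensus, noise_sd = 1,
                           dimension = "importance") {
  stopifnot(n_experts >= 1, all(consensus >= 1 & consensus <= 9))
  if (is.null(names(consensus))) {
    names(consensus) <- paste0("factor", seq_along(consensus))
  }
  raw <- vapply(consensus, function(mu) {
    pmin(9L, pmax(1L, as.integer(round(stats::rnorm(n_experts, mu, noise_sd)))))
  }, integer(n_experts))
  if (n_experts == 1) raw <- matrix(raw, nrow = 1,
                                    dimnames = list(NULL, names(consensus)))
  delphi_scores(raw, dimension = dimension,
                expert_ids = paste0("expert", seq_len(n_experts)),
                factor_ids = names(consensus))
}

#' Simulate a patient roster
#'
#' Draws a cross-sectional roster with the latent-severity structure used by
#' the waiting-list simulator (see [generate_patients()]) but with referral
#' dates instead of arrival weeks, for exercising the scoring and ranking
#' functions directly.
#'
#' @param n Number of patients.
#' @param config A `framework_config`.
#' @param severity_shape1,severity_shape2 Beta parameters of the latent
#'   severity.
#' @param start_date First referral date; patients are spread over `n` days.
#' @return Roster data frame accepted by [score_patients()].
#' @export
rroster <- function(n, config = default_framework(),
                    severity_shape1 = 1, severity_shape2 = 1,
                    start_date = as.Date("2021-01-01")) {
  stopifnot(n >= 1)
  ids <- config$factors$factor_id
  u <- stats::rbeta(n, severity_shape1, severity_shape2)
  roster <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    referral_date = start_date + sample.int(n, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE
  )
  for (f in ids) {
    roster[[f]] <- stats::rbinom(n, config$score_max, u)
  }
  roster
}
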