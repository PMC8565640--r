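#' Construct a table of Delphi panel scores
#'
#' One round of a modified-Delphi exercise asks every panellist to score every
#' candidate factor on a 9-point Likert scale along one dimension (how
#' important the factor is for prioritising patients, or how measurable it
#' is). This constructor validates a complete expert-by-factor score matrix.
#'
#' @param scores Integer matrix, experts in rows and factors in columns, all
#'   entries in 1..9 with no gaps.
#' @param dimension `"importance"` or `"measurement_capability"`.
#' @param expert_ids,factor_ids Optional identifiers; default to the matrix
#'   dimnames or generated labels.
#' @return A `delphi_scores` object.
#' @export
delphi_scores <- function(scores,
                          dimension = c("importance", "measurement_capability"),
                          expert_ids = rownames(scores),
                          factor_ids = colnames(scores)) {
  dimension <- match.arg(dimension)
  scores <- as.matrix(scores)
  if (nrow(scores) < 1) stop("at least one expert is required", call. = FALSE)
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1, ]
    stop(sprintf("missing score for expert %d, factor %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (any(scores != round(scores)) || any(scores < 1) || any(scores > 9)) {
    stop("all scores must be integers on the 9-point scale (1..9)",
         call. = FALSE)
  }
  if (is.null(expert_ids)) expert_ids <- paste0("expert", seq_len(nrow(scores)))
  if (is.null(factor_ids)) factor_ids <- paste0("factor", seq_len(ncol(scores)))
  dimnames(scores) <- list(as.character(expert_ids), as.character(factor_ids))
  structure(list(scores = scores, dimension = dimension),
            class = "delphi_scores")
}

#' @export
print.delphi_scores <- function(x, ...) {
  cat(sprintf("Delphi round scores: %d experts x %d factors, dimension '%s'\n",
              nrow(x$scores), ncol(x$scores), x$dimension))
  invisible(x)
}

#' Per-factor median (and mean) summaries of a Delphi round
#'
#' The decision bands work off the median score over experts; with an even
#' panel the median is the midpoint of the two central order statistics. The
#' mean is also returned because panels often report it alongside, but it is
#' never decisive here.
#'
#' @param s A `delphi_scores` object.
#' @return Data frame with `factor_id`, `median`, `mean`, one row per factor.
#' @export
summarize_scores <- function(s) {
  stopifnot(inherits(s, "delphi_scores"))
  data.frame(
    factor_id = colnames(s$scores),
    median = apply(s$scores, 2, stats::median),
    mean = colMeans(s$scores),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Likert decision band of a score
#'
#' Bands on the 9-point scale: below 4 is the elimination band, 4 through 7
#' the undecided band, above 7 the selection band. Medians can be
#' half-integers, which the open interval boundaries place unambiguously.
#'
#' @param x Numeric scores or medians in `[1, 9]`.
#' @return Character vector: `"low"`, `"mid"` or `"high"`.
#' @export
likert_band <- function(x) {
  ifelse(x < 4, "low", ifelse(x <= 7, "mid", "high"))
}

#' Classify a factor from its two dimension medians
#'
#' A factor is *selected* only when its median exceeds 7 on both dimensions
#' (important **and** measurable), *eliminated* as soon as either median
#' falls below 4, and otherwise *advances* to the next round. Medians of
#' exactly 7 or exactly 4 advance.
#'
#' @param median_importance,median_measurement Medians in `[1, 9]`
#'   (vectorised).
#' @return Character vector: `"selected"`, `"advance"` or `"eliminated"`.
#' @export
classify_factor <- function(median_importance, median_measurement) {
  stopifnot(all(median_importance >= 1 & median_importance <= 9),
            all(median_measurement >= 1 & median_measurement <= 9))
  ifelse(median_importance < 4 | median_measurement < 4, "eliminated",
         ifelse(median_importance > 7 & median_measurement > 7, "selected",
                "advance"))
}

#' Agreement rate of the panel on one factor
#'
#' Fraction of experts whose score falls in the same Likert band
#' (see [likert_band()]) as the factor's median. This operationalises the
#' "agreement between the opinions" stopping quantity: when the panel's
#' scores cluster in the median's band, the round has converged for that
#' factor.
#'
#' @param s A `delphi_scores` object.
#' @param factor_id Factor to assess.
#' @return Fraction in `[0, 1]`.
#' @export
agreement_rate <- function(s, factor_id) {
  stopifnot(inherits(s, "delphi_scores"))
  if (!factor_id %in% colnames(s$scores)) {
    stop(sprintf("unknown factor id '%s'", factor_id), call. = FALSE)
  }
  col <- s$scores[, factor_id]
  med_band <- likert_band(stats::median(col))
  mean(likert_band(col) == med_band)
}

#' Run one modified-Delphi round
#'
#' Applies the band rule to every factor using the medians of both scored
#' dimensions, computes agreement rates, and decides whether the Delphi can
#' stop. A factor's agreement rate is the smaller of its two per-dimension
#' rates (the panel must have converged on both judgments). The round
#' terminates when every factor that was not eliminated has an agreement rate
#' at or above the threshold.
#'
#' @param importance,measurement `delphi_scores` for the two dimensions, over
#'   identical factors.
#' @param round_number Positive integer, recorded in the output.
#' @param agreement_threshold Stopping threshold on the agreement rate;
#'   default 0.80, with rates of exactly 0.80 counting as converged.
#' @param select_override Optional character vector of factor ids forced to
#'   `"selected"` regardless of their bands (the expert-panel override that
#'   real Delphi studies apply after the arithmetic); recorded in the
#'   `overridden` column, never silent.
#' @return Data frame with one row per factor — `round`, `factor_id`,
#'   `median_importance`, `median_measurement`, `mean_importance`,
#'   `mean_measurement`, `agreement_rate`, `decision`, `overridden` — with
#'   attribute `terminated` (logical).
#' @export
run_round <- function(importance, measurement, round_number = 1L,
                      agreement_threshold = 0.80, select_override = NULL) {
  stopifnot(inherits(importance, "delphi_scores"),
            inherits(measurement, "delphi_scores"))
  if (round_number < 1) stop("round_number must be >= 1", call. = FALSE)
  if (!identical(colnames(importance$scores), colnames(measurement$scores))) {
    stop("the two dimensions must cover identical factors in the same order",
         call. = FALSE)
  }
  imp <- summarize_scores(importance)
  mea <- summarize_scores(measurement)
  ids <- imp$factor_id
  agree <- pmin(
    vapply(ids, function(f) agreement_rate(importance, f), numeric(1)),
    vapply(ids, function(f) agreement_rate(measurement, f), numeric(1))
  )
  decision <- classify_factor(imp$median, mea$median)
  overridden <- ids %in% select_override
  decision[overridden] <- "selected"
  out <- data.frame(
    round = as.integer(round_number),
    factor_id = ids,
    median_importance = imp$median,
    median_measurement = mea$median,
    mean_importance = imp$mean,
    mean_measurement = mea$mean,
    agreement_rate = unname(agree),
    decision = decision,
    overridden = overridden,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  live <- out$decision != "eliminated"
  attr(out, "terminated") <- all(out$agreement_rate[live] >= agreement_threshold)
  out
}
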