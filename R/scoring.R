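#' Score one patient against the framework
#'
#' Each factor's physician-assigned score (0-10) is multiplied by the
#' factor's weight and the point scale, and the contributions are summed into
#' the patient's total on the 100-point scale. Under the default weights the
#' per-factor maxima are 22, 18, 15, 15, 12, 10 and 8 points.
#'
#' @param patient List or one-row data frame with `patient_id`,
#'   `referral_date` (a `Date` or ISO-8601 string) and one integer score per
#'   configured factor, named by `factor_id`.
#' @param config A `framework_config`.
#' @return A `scored_patient` list: `patient_id`, `referral_date`,
#'   `contributions` (named, points per factor), `total_points`, `tier`,
#'   `max_wait_weeks`.
#' @examples
#' cfg <- default_framework()
#' p <- list(patient_id = "P1", referral_date = "2021-03-01",
#'           pain_symptoms = 8, stress_test = 5, underlying_disease = 10,
#'           mi_count = 0, socioeconomic_performance = 3, waiting_time = 7,
#'           special_circumstances = 1)
#' compute_total(p, cfg)$total_points  # 53
#' @export
compute_total <- function(patient, config) {
  stopifnot(inherits(config, "framework_config"))
  ids <- config$factors$factor_id
  missing <- setdiff(ids, names(patient))
  if (length(missing) > 0) {
    stop(sprintf("patient %s is missing scores for: %s",
                 patient$patient_id %||% "?",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scores <- vapply(ids, function(f) as.numeric(patient[[f]]), numeric(1))
  if (anyNA(scores)) {
    stop(sprintf("patient %s has a non-numeric factor score",
                 patient$patient_id %||% "?"), call. = FALSE)
  }
  out_of_bounds <- scores < config$score_min | scores > config$score_max |
    scores != round(scores)
  if (any(out_of_bounds)) {
    f <- ids[which(out_of_bounds)[1]]
    stop(sprintf(
      "patient %s: score %g for factor '%s' outside integer bounds [%d, %d]",
      patient$patient_id %||% "?", scores[[f]], f,
      config$score_min, config$score_max), call. = FALSE)
  }
  contributions <- scores * config$factors$weight * config$scale
  total <- sum(contributions)
  tier <- assign_tier(total, config)
  structure(
    list(patient_id = patient$patient_id,
         referral_date = as.Date(patient$referral_date),
         contributions = contributions,
         total_points = total,
         tier = tier$tier,
         max_wait_weeks = tier$max_wait_weeks),
    class = "scored_patient"
  )
}

#' @export
print.scored_patient <- function(x, ...) {
  cat(sprintf("Patient %s: %.1f points, tier %d (see within %d weeks)\n",
              x$patient_id, x$total_points, x$tier, x$max_wait_weeks))
  invisible(x)
}

#' Assign a priority tier to a total score
#'
#' Tier bounds are inclusive at the lower edge: with the default tiers a
#' total of exactly 80 is tier 1 (seen within 4 weeks), exactly 50 is tier 2
#' (8 weeks), and anything below 50 is tier 3 (16 weeks).
#'
#' @param total_points Numeric vector of totals in `[0, score_max * scale]`.
#' @param config A `framework_config`.
#' @return Data frame with columns `tier` and `max_wait_weeks`, one row per
#'   total.
#' @export
assign_tier <- function(total_points, config) {
  stopifnot(inherits(config, "framework_config"))
  max_total <- config$score_max * config$scale
  if (any(total_points < 0 | total_points > max_total)) {
    stop(sprintf("total points must lie in [0, %g]", max_total),
         call. = FALSE)
  }
  tiers <- config$tiers
  # first tier whose inclusive minimum the total reaches (minima decrease)
  idx <- vapply(total_points,
                function(t) which(t >= tiers$min_points)[1], integer(1))
  data.frame(tier = tiers$tier[idx],
             max_wait_weeks = tiers$max_wait_weeks[idx])
}

#' Score a roster of patients
#'
#' Vectorised form of [compute_total()]: scores every patient in a roster
#' data frame and returns one row per patient with per-factor point
#' contributions, the total, and the assigned tier.
#'
#' @param roster Data frame with columns `patient_id`, `referral_date` and
#'   one integer score column per configured factor.
#' @param config A `framework_config`.
#' @return Data frame: `patient_id`, `referral_date`, `<factor_id>_points`
#'   columns, `total_points`, `tier`, `max_wait_weeks`.
#' @export
score_patients <- function(roster, config) {
  stopifnot(is.data.frame(roster), inherits(config, "framework_config"))
  if (nrow(roster) == 0) {
    stop("empty roster", call. = FALSE)
  }
  if (anyDuplicated(roster$patient_id)) {
    stop("duplicate patient ids in roster", call. = FALSE)
  }
  scored <- lapply(seq_len(nrow(roster)),
                   function(i) compute_total(as.list(roster[i, ]), config))
  ids <- config$factors$factor_id
  pts <- do.call(rbind, lapply(scored, function(s) s$contributions))
  colnames(pts) <- paste0(ids, "_points")
  out <- data.frame(
    patient_id = roster$patient_id,
    referral_date = as.Date(roster$referral_date),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(pts))
  out$total_points <- vapply(scored, `[[`, numeric(1), "total_points")
  out$tier <- vapply(scored, `[[`, integer(1), "tier")
  out$max_wait_weeks <- vapply(scored, `[[`, integer(1), "max_wait_weeks")
  rownames(out) <- NULL
  out
}

#' Rank a waiting list by priority score
#'
#' Orders patients by total points (descending). Ties are broken
#' deterministically: higher waiting-time factor score first, then earlier
#' referral date, then patient id, so the ranking is a pure function of the
#' roster and never of its input order.
#'
#' @inheritParams score_patients
#' @param waiting_factor Factor id used for the first tie-break; defaults to
#'   `"waiting_time"` when the configuration has it, otherwise skipped.
#' @return The scored roster (see [score_patients()]) sorted by priority,
#'   with a `rank` column `1..n`.
#' @export
rank_waitlist <- function(roster, config, waiting_factor = "waiting_time") {
  scored <- score_patients(roster, config)
  keys <- list(-scored$total_points)
  if (waiting_factor %in% config$factors$factor_id) {
    keys <- c(keys, list(-roster[[waiting_factor]][match(scored$patient_id,
                                                         roster$patient_id)]))
  }
  keys <- c(keys, list(scored$referral_date, scored$patient_id))
  ord <- do.call(order, keys)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
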