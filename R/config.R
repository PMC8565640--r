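#' The packaged CAA prioritisation framework
#'
#' The default configuration carries the seven factors of the published
#' coronary-angiography prioritisation framework with their expert-derived
#' weights, the 0-10 physician score bounds, the x10 scale that maps weighted
#' scores onto a 100-point total, and the three urgency tiers: 80 points and
#' above must be seen within 4 weeks, 50 to below 80 within 8 weeks, and all
#' others within 16 weeks.
#'
#' @return A `framework_config` object.
#' @seealso [load_framework()] for reading a custom configuration from JSON.
#' @export
default_framework <- function() {
  framework_config(
    factors = data.frame(
      factor_id = c("pain_symptoms", "stress_test", "underlying_disease",
                    "mi_count", "socioeconomic_performance", "waiting_time",
                    "special_circumstances"),
      name = c(
        "Pain severity and clinical symptoms",
        "Stress test result",
        "Underlying diseases and risk factors",
        "Number of myocardial infarctions (heart failure rate)",
        "Decreased economic and social performance",
        "Duration of waiting time",
        "Special circumstances"
      ),
      weight = c(0.22, 0.18, 0.15, 0.15, 0.12, 0.10, 0.08),
      stringsAsFactors = FALSE
    ),
    score_min = 0L,
    score_max = 10L,
    scale = 10,
    tiers = data.frame(
      tier = 1:3,
      min_points = c(80, 50, 0),
      max_wait_weeks = c(4L, 8L, 16L)
    )
  )
}

#' Construct and validate a framework configuration
#'
#' @param factors Data frame with columns `factor_id` (unique), `name` and
#'   `weight`; weights must sum to 1.
#' @param score_min,score_max Integer bounds of the physician-assigned factor
#'   score.
#' @param scale Multiplier mapping the weighted score sum onto points
#'   (`score_max * scale` = the total-point ceiling, 100 by default).
#' @param tiers Data frame with columns `tier`, `min_points` (inclusive lower
#'   bound, strictly decreasing, last row 0 so every total is covered) and
#'   `max_wait_weeks`.
#' @return A validated `framework_config` object.
#' @export
framework_config <- function(factors, score_min = 0L, score_max = 10L,
                             scale = 10, tiers = NULL) {
  stopifnot(is.data.frame(factors),
            all(c("factor_id", "name", "weight") %in% names(factors)))
  if (anyDuplicated(factors$factor_id)) {
    stop("duplicate factor ids in configuration", call. = FALSE)
  }
  if (any(factors$weight < 0)) {
    stop("factor weights must be nonnegative", call. = FALSE)
  }
  if (abs(sum(factors$weight) - 1) > 1e-9) {
    stop(sprintf("factor weights must sum to 1, got %.6f",
                 sum(factors$weight)), call. = FALSE)
  }
  if (score_min >= score_max) {
    stop("score_min must be below score_max", call. = FALSE)
  }
  if (is.null(tiers)) {
    tiers <- data.frame(tier = 1:3, min_points = c(80, 50, 0),
                        max_wait_weeks = c(4L, 8L, 16L))
  }
  stopifnot(all(c("tier", "min_points", "max_wait_weeks") %in% names(tiers)))
  if (any(diff(tiers$min_points) >= 0)) {
    stop("tier minimum points must be strictly decreasing", call. = FALSE)
  }
  if (tiers$min_points[nrow(tiers)] != 0) {
    stop("the last tier must start at 0 points so every total is covered",
         call. = FALSE)
  }
  max_total <- score_max * scale
  if (tiers$min_points[1] > max_total) {
    stop("top tier threshold exceeds the maximum attainable total",
         call. = FALSE)
  }
  structure(
    list(factors = factors, score_min = as.integer(score_min),
         score_max = as.integer(score_max), scale = scale, tiers = tiers),
    class = "framework_config"
  )
}

#' @export
print.framework_config <- function(x, ...) {
  cat(sprintf("Prioritisation framework: %d factors, scores %d-%d, %d tiers\n",
              nrow(x$factors), x$score_min, x$score_max, nrow(x$tiers)))
  f <- x$factors
  f$max_points <- f$weight * x$score_max * x$scale
  print(f, row.names = FALSE)
  cat("Tiers (inclusive lower bounds):\n")
  print(x$tiers, row.names = FALSE)
  invisible(x)
}

#' Load a framework configuration from JSON
#'
#' The JSON document mirrors [framework_config()]: an object with a `factors`
#' array (each element `factor_id`, `name`, `weight`), optional `score_min`,
#' `score_max`, `scale`, and an optional `tiers` array (each element `tier`,
#' `min_points`, `max_wait_weeks`). Validation is identical to constructing
#' the configuration in code. See
#' `system.file("extdata", "default_framework.json", package = "caaprior")`
#' for the packaged default.
#'
#' @param path Path to a JSON file, or `NULL` for the packaged default.
#' @return A validated `framework_config`.
#' @export
load_framework <- function(path = NULL) {
  if (is.null(path)) {
    return(default_framework())
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$factors)) {
    stop("configuration is missing the 'factors' array", call. = FALSE)
  }
  framework_config(
    factors = as.data.frame(doc$factors, stringsAsFactors = FALSE),
    score_min = doc$score_min %||% 0L,
    score_max = doc$score_max %||% 10L,
    scale = doc$scale %||% 10,
    tiers = if (!is.null(doc$tiers)) as.data.frame(doc$tiers) else NULL
  )
}

#' Write a framework configuration to JSON
#'
#' @param config A `framework_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_framework <- function(config, path) {
  stopifnot(inherits(config, "framework_config"))
  jsonlite::write_json(
    list(factors = config$factors, score_min = config$score_min,
         score_max = config$score_max, scale = config$scale,
         tiers = config$tiers),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
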