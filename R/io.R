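#' Read comparison matrices from CSV
#'
#' Two dialects are accepted. A *wide* file holds one expert's matrix: the
#' header row lists the factor ids and the n data rows hold the n x n
#' entries. A *long* file holds any number of experts with columns
#' `expert_id, factor_row, factor_col, value`; diagonal cells may be omitted
#' (they are 1) and each (row, col) pair must appear together with its
#' reciprocal cell or alone (the reciprocal is then filled in).
#'
#' @param path CSV file path.
#' @param tol Reciprocity tolerance forwarded to [validate_matrix()]; the
#'   default accommodates reciprocals hand-rounded to a few decimals.
#' @return Named list of `comparison_matrix` objects (names are expert ids;
#'   a wide file yields one matrix named after the file).
#' @export
read_comparison_csv <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  long_cols <- c("expert_id", "factor_row", "factor_col", "value")
  if (all(long_cols %in% names(df))) {
    return(comparison_from_long(df, tol = tol))
  }
  ids <- names(df)
  if (nrow(df) != length(ids)) {
    stop(sprintf(
      "wide comparison file must be square: %d factor columns but %d rows",
      length(ids), nrow(df)), call. = FALSE)
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      stop(sprintf("non-numeric cell in column '%s'", ids[j]), call. = FALSE)
    }
  }
  m <- validate_matrix(as.matrix(df), ids, tol = tol)
  stats::setNames(list(m), tools::file_path_sans_ext(basename(path)))
}

comparison_from_long <- function(df, tol = 1e-6) {
  if (!is.numeric(df$value)) {
    stop("'value' column must be numeric", call. = FALSE)
  }
  experts <- unique(df$expert_id)
  out <- lapply(experts, function(e) {
    sub <- df[df$expert_id == e, , drop = FALSE]
    ids <- unique(c(sub$factor_row, sub$factor_col))
    n <- length(ids)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- 1
    for (k in seq_len(nrow(sub))) {
      m[sub$factor_row[k], sub$factor_col[k]] <- sub$value[k]
    }
    # fill reciprocals where only one orientation was recorded
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (is.na(m[i, j]) && !is.na(m[j, i])) m[i, j] <- 1 / m[j, i]
    }
    if (anyNA(m)) {
      bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
      stop(sprintf("expert '%s': no judgment for pair (%s, %s)", e,
                   ids[bad[1]], ids[bad[2]]), call. = FALSE)
    }
    validate_matrix(m, ids, tol = tol)
  })
  stats::setNames(out, as.character(experts))
}

#' Write comparison matrices to long-format CSV
#'
#' Upper-triangle judgments only, one row per (expert, pair); reciprocals and
#' the unit diagonal are implied and restored by [read_comparison_csv()].
#'
#' @param matrices Named list of `comparison_matrix` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(matrices, path) {
  if (inherits(matrices, "comparison_matrix")) {
    matrices <- list(expert1 = matrices)
  }
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("expert", seq_along(matrices))
  }
  rows <- lapply(names(matrices), function(e) {
    m <- matrices[[e]]
    ids <- rownames(m)
    n <- nrow(m)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(expert_id = e,
               factor_row = ids[pairs[, 1]],
               factor_col = ids[pairs[, 2]],
               value = m[pairs],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write derived weights to CSV or JSON
#'
#' @param weights A `weight_vector` (named numeric summing to 1).
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @param consistency Optional `consistency_report` embedded in JSON output
#'   (ignored for CSV).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, consistency = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- list(weights = as.list(unclass(weights)))
    if (!is.null(consistency)) {
      payload$consistency <- unclass(consistency)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(factor_id = names(weights), weight = as.numeric(weights)),
      path, row.names = FALSE)
  }
  invisible(path)
}

#' Read Delphi scores from long-format CSV
#'
#' Expected columns: `round, expert_id, factor_id, dimension, score` with
#' `dimension` in `{importance, measurement_capability}` and integer scores
#' 1..9. Every (expert, factor) cell must be present within a
#' (round, dimension) block.
#'
#' @param path CSV file path.
#' @return Nested list: one element per round (named by round number), each a
#'   list of `delphi_scores` named by dimension.
#' @export
read_delphi_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "expert_id", "factor_id", "dimension", "score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("Delphi CSV is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rounds <- sort(unique(df$round))
  out <- lapply(rounds, function(r) {
    sub_r <- df[df$round == r, , drop = FALSE]
    dims <- unique(sub_r$dimension)
    per_dim <- lapply(dims, function(d) {
      sub <- sub_r[sub_r$dimension == d, , drop = FALSE]
      experts <- unique(sub$expert_id)
      factors <- unique(sub$factor_id)
      m <- matrix(NA_integer_, length(experts), length(factors),
                  dimnames = list(experts, factors))
      m[cbind(match(sub$expert_id, experts),
              match(sub$factor_id, factors))] <- sub$score
      delphi_scores(m, dimension = d)
    })
    stats::setNames(per_dim, dims)
  })
  stats::setNames(out, as.character(rounds))
}

#' Read a patient roster from CSV
#'
#' Columns: `patient_id`, `referral_date` (ISO-8601), then one integer score
#' column per configured factor, named by factor id. Extra columns are kept;
#' missing factor columns are an error naming the factors.
#'
#' @param path CSV file path.
#' @param config `framework_config` the roster must satisfy.
#' @return Roster data frame for [score_patients()] / [rank_waitlist()].
#' @export
read_roster_csv <- function(path, config = default_framework()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "referral_date", config$factors$factor_id)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("roster is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$referral_date <- as.Date(df$referral_date)
  if (anyNA(df$referral_date)) {
    stop("unparseable referral_date (expect ISO-8601, e.g. 2021-03-01)",
         call. = FALSE)
  }
  df
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a command-line run: package
#' version, MD5 digests of the input files, the configuration snapshot, the
#' seed and a timestamp.
#'
#' @param inputs Character vector of input file paths.
#' @param config `framework_config` used (or `NULL`).
#' @param seed Integer seed of the run (or `NULL`).
#' @return A list; write it with [write_manifest()].
#' @export
run_manifest <- function(inputs = character(0), config = NULL, seed = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else list()
  list(
    tool = "caaprior",
    version = as.character(utils::packageVersion("caaprior")),
    inputs = digests,
    config = if (!is.null(config)) {
      list(factors = config$factors, score_min = config$score_min,
           score_max = config$score_max, scale = config$scale,
           tiers = config$tiers)
    },
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' @rdname run_manifest
#' @param manifest List from [run_manifest()].
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
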