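# Published weights in framework order, used as the reference throughout.
table2_weights <- function() {
  c(pain_symptoms = 0.22, stress_test = 0.18, underlying_disease = 0.15,
    mi_count = 0.15, socioeconomic_performance = 0.12, waiting_time = 0.10,
    special_circumstances = 0.08)
}

# Independent AHP oracle: full dense eigendecomposition, eigenvector of the
# largest-real-part eigenvalue, L1-normalised. Never calls derive_weights.
eigen_weights <- function(m) {
  A <- unclass(m)
  e <- eigen(A)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  lambda <- Re(e$values[k])
  n <- nrow(A)
  ci <- (lambda - n) / (n - 1)
  ri <- caaprior::saaty_random_index[as.character(n)]
  list(weights = v, lambda_max = lambda, ci = ci,
       cr = if (n <= 2) 0 else ci / unname(ri))
}

# Random reciprocal matrix: upper triangle drawn from the Saaty scale
# {1/9..1/2, 1..9}, reciprocals below, unit diagonal.
random_reciprocal_matrix <- function(n) {
  vals <- c(1 / (9:2), 1:9)
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    m[i, j] <- sample(vals, 1)
    m[j, i] <- 1 / m[i, j]
  }
  validate_matrix(m, paste0("f", seq_len(n)))
}

# Independent Delphi band oracle, coded directly from the selection rules:
# both medians above 7 select, any median below 4 eliminates, else advance.
band_oracle <- function(m1, m2) {
  if (m1 < 4 || m2 < 4) return("eliminated")
  if (m1 > 7 && m2 > 7) return("selected")
  "advance"
}

decision_rank <- c(eliminated = 0L, advance = 1L, selected = 2L)

# Small ready-made roster matching the default framework's factor ids.
toy_roster <- function() {
  data.frame(
    patient_id = c("A", "B", "C"),
    referral_date = as.Date(c("2021-01-10", "2021-02-01", "2021-01-05")),
    pain_symptoms = c(10, 6, 2),
    stress_test = c(9, 6, 2),
    underlying_disease = c(9, 5, 3),
    mi_count = c(8, 5, 1),
    socioeconomic_performance = c(7, 4, 2),
    waiting_time = c(5, 5, 5),
    special_circumstances = c(6, 3, 1),
    stringsAsFactors = FALSE
  )
}
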