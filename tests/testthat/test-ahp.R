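test_that("validate_matrix accepts well-formed matrices and reports cells", {
  m <- validate_matrix(matrix(1, 3, 3), c("a", "b", "c"))
  expect_s3_class(m, "comparison_matrix")

  m2 <- validate_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE),
                        c("a", "b"))
  expect_equal(unname(m2["b", "a"]), 0.5)

  expect_error(validate_matrix(matrix(1, 2, 3), c("a", "b")), "square")
  expect_error(validate_matrix(matrix(1, 2, 2), c("a", "a")), "unique")
  expect_error(
    validate_matrix(matrix(c(1, -2, -0.5, 1), 2, 2), c("a", "b")),
    "non-positive")
  expect_error(
    validate_matrix(matrix(c(2, 2, 0.5, 1), 2, 2, byrow = TRUE),
                    c("a", "b")),
    "diagonal entry at \\(1,1\\)")
  expect_error(
    validate_matrix(matrix(c(1, 2, 0.4, 1), 2, 2, byrow = TRUE),
                    c("a", "b")),
    "reciprocity violated at cell \\(2,1\\)")
})

test_that("indifference matrix gives uniform weights and zero inconsistency", {
  m <- validate_matrix(matrix(1, 3, 3), c("a", "b", "c"))
  res <- derive_weights(m)
  expect_equal(unclass(res$weights), c(a = 1, b = 1, c = 1) / 3,
               tolerance = 1e-12)
  expect_equal(res$consistency$consistency_ratio, 0, tolerance = 1e-12)
})

test_that("weights of the published seven-factor matrix are recovered", {
  w <- table2_weights()
  m <- consistent_matrix_from_weights(w)
  expect_equal(unname(m["pain_symptoms", "special_circumstances"]),
               0.22 / 0.08)
  res <- derive_weights(m)
  expect_equal(unclass(res$weights), w, tolerance = 1e-6)
  expect_lt(res$consistency$consistency_ratio, 1e-9)
  expect_equal(res$consistency$lambda_max, 7, tolerance = 1e-9)
})

test_that("inconsistent 3x3 matrix matches the dense eigensolver oracle", {
  m <- validate_matrix(
    matrix(c(1, 2, 1 / 2,
             1 / 2, 1, 4,
             2, 1 / 4, 1), 3, 3, byrow = TRUE),
    c("a", "b", "c"))
  res <- derive_weights(m)
  oracle <- eigen_weights(m)
  expect_equal(unname(unclass(res$weights)), oracle$weights,
               tolerance = 1e-8)
  expect_equal(res$consistency$lambda_max, oracle$lambda_max,
               tolerance = 1e-8)
  expect_equal(res$consistency$consistency_ratio, oracle$cr,
               tolerance = 1e-8)
  expect_gt(res$consistency$lambda_max, 3)
  expect_false(res$consistency$acceptable)
})

test_that("any 2x2 reciprocal matrix is perfectly consistent", {
  for (v in c(1, 3, 9, 1 / 7)) {
    m <- validate_matrix(matrix(c(1, v, 1 / v, 1), 2, 2, byrow = TRUE),
                         c("a", "b"))
    expect_equal(consistency_ratio(m)$consistency_ratio, 0)
  }
})

test_that("geometric-mean aggregation preserves structure and judgments", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  m <- consistent_matrix_from_weights(w)
  expect_equal(unclass(aggregate_experts(list(m))), unclass(m),
               tolerance = 1e-12)

  m1 <- validate_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE),
                        c("a", "b"))
  m2 <- validate_matrix(matrix(c(1, 8, 0.125, 1), 2, 2, byrow = TRUE),
                        c("a", "b"))
  agg <- aggregate_experts(list(m1, m2))
  expect_equal(unname(agg["a", "b"]), 4)
  expect_equal(unname(agg["b", "a"]), 0.25)

  m3 <- validate_matrix(matrix(c(1, 2, 0.5, 1), 2, 2, byrow = TRUE),
                        c("x", "y"))
  expect_error(aggregate_experts(list(m1, m3)), "different factor ids")
})

test_that("aggregating a noisy panel beats its worst member", {
  set.seed(42)
  w <- table2_weights()
  panel <- rcomparison_matrices(10, w, jitter_sd = 0.3)
  per_expert <- vapply(panel, function(m) {
    sum(abs(unclass(derive_weights(m)$weights) - w))
  }, numeric(1))
  agg_err <- sum(abs(unclass(derive_weights(aggregate_experts(panel))$weights) - w))
  expect_lt(agg_err, max(per_expert))
})

test_that("round-trip through a consistent matrix recovers random weights", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    w <- runif(n, 0.05, 1)
    w <- w / sum(w)
    names(w) <- paste0("f", seq_len(n))
    res <- derive_weights(consistent_matrix_from_weights(w))
    expect_equal(unclass(res$weights), w, tolerance = 1e-9)
    expect_lt(res$consistency$consistency_ratio, 1e-9)
  }
  expect_error(consistent_matrix_from_weights(c(a = 0, b = 1)), "positive")
})

test_that("weights are permutation-equivariant and CR permutation-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    m <- random_reciprocal_matrix(n)
    res <- derive_weights(m)
    perm <- sample(n)
    mp <- validate_matrix(unclass(m)[perm, perm], rownames(m)[perm])
    resp <- derive_weights(mp)
    expect_equal(unclass(resp$weights), unclass(res$weights)[perm],
                 tolerance = 1e-9)
    expect_equal(resp$consistency$consistency_ratio,
                 res$consistency$consistency_ratio, tolerance = 1e-9)
    # Perron root of a reciprocal matrix never falls below its order
    expect_gte(res$consistency$lambda_max, n - 1e-9)
    expect_gte(res$consistency$consistency_index, 0)
    expect_gte(res$consistency$consistency_ratio, 0)
  }
})

test_that("power iteration agrees with the dense eigensolver on random matrices", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:9, 1)
    m <- random_reciprocal_matrix(n)
    res <- derive_weights(m)
    oracle <- eigen_weights(m)
    expect_equal(unname(unclass(res$weights)), oracle$weights,
                 tolerance = 1e-8)
    expect_equal(res$consistency$lambda_max, oracle$lambda_max,
                 tolerance = 1e-8)
  }
})
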