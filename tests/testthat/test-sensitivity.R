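test_that("percent change is plain arithmetic with a guarded base", {
  expect_equal(percent_change(300, 250), 20)
  expect_equal(percent_change(250, 250), 0)
  expect_equal(percent_change(225, 250), -10)
  expect_error(percent_change(1, 0), "zero")
})

test_that("sensitivity index is the two-point slope", {
  expect_equal(sensitivity_index(5, 5, 2), 0)
  expect_equal(sensitivity_index(-10, 22, 2), 16)
  expect_equal(sensitivity_index(22, -10, 2), -16)
  expect_error(sensitivity_index(1, 2, 0), "zero")
})

make_results <- function(S, D = S) {
  data.frame(
    characteristic = rep(rownames(S), ncol(S)),
    parameter = rep(colnames(S), each = nrow(S)),
    D1 = 0, D2 = as.vector(D), delta_a = 1, S = as.vector(S))
}

test_that("a single-cell matrix normalizes to +/-1", {
  S <- matrix(-3, 1, 1, dimnames = list("APD90", "INaL"))
  m <- build_matrix(make_results(S))
  expect_equal(unname(m$matrix[1, 1]), -1)
})

test_that("row normalization is invariant to positive rescaling", {
  S <- matrix(c(2, -1, 0.5, 4, 1, -2), 2, 3,
              dimnames = list(c("APD90", "nai"), c("a", "b", "c")))
  m1 <- build_matrix(make_results(S))
  m2 <- build_matrix(make_results(S * 7))
  expect_equal(m1$matrix, m2$matrix)
  # every row has a unit-magnitude cell, all cells within [-1, 1]
  expect_true(all(apply(abs(m1$matrix), 1, max) == 1))
  expect_true(all(abs(m1$matrix) <= 1))
})

test_that("missing runs are reported by name", {
  S <- matrix(c(2, -1, 0.5, 4), 2, 2,
              dimnames = list(c("APD90", "nai"), c("a", "b")))
  res <- make_results(S)[-2, ]
  expect_error(build_matrix(res), "nai/a")
})

test_that("row maxima report the dominant parameter's percent change", {
  S <- matrix(c(2, -8), 1, 2, dimnames = list("APD90", c("a", "b")))
  D <- matrix(c(10, -40), 1, 2)
  m <- build_matrix(make_results(S, D))
  expect_equal(unname(m$row_max_abs["APD90"]), 40)
})
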