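# shared fixtures for the test suite

table2 <- doe_example("bbd_runs")
table2_directions <- doe_example_directions()
table2_factors <- doe_example_factors()

# coefficients of the published fitted OD surface, canonical term order
published_coef <- c(
  `(Intercept)` = 0.7588,
  X1 = -0.1362, X2 = 0.0767, X3 = -0.1491,
  `X1:X2` = 0.1129, `X1:X3` = -0.1476, `X2:X3` = 0.0442,
  `X1^2` = -0.2556, `X2^2` = -0.0907, `X3^2` = -0.1192
)

# independent polynomial evaluation: never calls predict.rsm_fit
eval_quadratic <- function(b, x) {
  m <- length(x)
  v <- b[["(Intercept)"]] + sum(b[paste0("X", 1:m)] * x) +
    sum(b[paste0("X", 1:m, "^2")] * x^2)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    v <- v + b[[paste0("X", i, ":X", j)]] * x[i] * x[j]
  }
  unname(v)
}

# gradient system of a quadratic surface, assembled from first principles
stationary_oracle <- function(b) {
  g <- unname(b[c("X1", "X2", "X3")])
  H <- matrix(c(2 * b[["X1^2"]], b[["X1:X2"]], b[["X1:X3"]],
                b[["X1:X2"]], 2 * b[["X2^2"]], b[["X2:X3"]],
                b[["X1:X3"]], b[["X2:X3"]], 2 * b[["X3^2"]]), 3, 3)
  drop(solve(H, -g))
}

# the published equation was fit to the study's own OD column
fit_table2 <- function() fit_rsm(table2, "od")
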