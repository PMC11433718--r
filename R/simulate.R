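#' Default dialysis sampling time grid
#'
#' The sampling schedule of the packaged release study: 0, 0.25, 0.5, 0.75,
#' 1, 2, 4, 6, 8, 12, 24 and 48 hours.
#'
#' @return Numeric vector of hours.
#' @export
release_times <- function() {
  c(0, 0.25, 0.5, 0.75, 1, 2, 4, 6, 8, 12, 24, 48)
}

#' Simulate Box-Behnken responses from a known quadratic surface
#'
#' Generates a three-factor Box-Behnken design and a response
#' `y = quadratic(truth) + Normal(0, noise_sd)` with i.i.d. Gaussian noise —
#' the generative model the response-surface analysis assumes. With
#' `noise_sd = 0` the fitted coefficients recover `coef` to numerical
#' precision, giving a self-consistency oracle for [fit_rsm()].
#'
#' @param coef True coefficient vector, length 10, in the canonical term
#'   order `(Intercept), X1, X2, X3, X1:X2, X1:X3, X2:X3, X1^2, X2^2, X3^2`
#'   (names optional).
#' @param n_center Number of center replicates (default 5).
#' @param noise_sd Response noise standard deviation (default 0.154, the
#'   residual scale of the packaged study).
#' @param seed Optional integer seed; identical inputs give identical
#'   output.
#' @return The design tibble from [design_bbd()] with a `y` column and the
#'   truth stored in `attr(, "truth")`.
#' @examples
#' sim <- sim_bbd(c(0.76, -0.14, 0.08, -0.15, 0.11, -0.15, 0.04,
#'                  -0.26, -0.09, -0.12), noise_sd = 0, seed = 1)
#' coef(fit_rsm(sim, "y")$lm)
#' @export
sim_bbd <- function(coef, n_center = 5, noise_sd = 0.154, seed = NULL) {
  check_number(coef, "coef")
  if (length(coef) != 10) {
    stop_invalid("`coef` must have length 10 (intercept, 3 linear, 3 interaction, 3 quadratic).")
  }
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  design <- design_bbd(n_center)
  X <- quadratic_model_matrix(as.matrix(design[c("X1", "X2", "X3")]))
  mu <- drop(X %*% unname(coef))
  if (!is.null(seed)) withr::local_seed(seed)
  design$y <- mu + stats::rnorm(length(mu), 0, noise_sd)
  attr(design, "truth") <- stats::setNames(unname(coef), colnames(X))
  attr(design, "factor_cols") <- c("X1", "X2", "X3")
  design
}

#' Simulate Plackett-Burman responses with known active factors
#'
#' Generates a 12-run Plackett-Burman design and a response
#' `y = mean + sum(effect_f / 2 * x_f) + Normal(0, noise_sd)`, so each named
#' factor's high-minus-low main effect equals `effect_f` exactly in
#' expectation. Screening the result with [screen_pbd()] should flag the
#' active set when effects are large relative to the noise.
#'
#' @param effects Named numeric vector of true main effects (names must be
#'   among the design's real factor columns); unnamed factors are inert.
#' @param n_factors Number of real factors (default 6).
#' @param noise_sd Gaussian noise standard deviation.
#' @param mean Baseline response level (default 0).
#' @param seed Optional integer seed.
#' @return The design tibble from [design_pbd()] with a `y` column.
#' @examples
#' screen_pbd(sim_pbd(c(A = 10), noise_sd = 0.5, seed = 3), responses = "y")
#' @export
sim_pbd <- function(effects = numeric(), n_factors = 6, noise_sd = 1,
                    mean = 0, seed = NULL) {
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  design <- design_pbd(n_factors)
  fac <- attr(design, "factor_cols")
  if (length(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% fac)) {
      stop_invalid("`effects` must be named after real factor columns.")
    }
  }
  mu <- rep(mean, nrow(design))
  for (f in names(effects)) mu <- mu + effects[[f]] / 2 * design[[f]]
  if (!is.null(seed)) withr::local_seed(seed)
  design$y <- mu + stats::rnorm(length(mu), 0, noise_sd)
  design
}

#' Simulate a drug-release curve from a kinetic model
#'
#' Evaluates one of the four kinetic model families (see [eval_release()])
#' on a time grid and adds Gaussian noise truncated to keep the curve inside
#' `[0, 100]`. The value at `t = 0` is 0 by convention (no noise, and the
#' zero-order/Higuchi intercepts are not applied at the origin), matching
#' how a dialysis experiment starts from zero release.
#'
#' @param model Model name: `"zero"`, `"first"`, `"higuchi"`, `"peppas"`.
#' @param params Named parameters for the model (see [eval_release()]).
#' @param times Time grid in hours (default [release_times()]).
#' @param noise_sd Noise standard deviation on the release-percent scale.
#' @param seed Optional integer seed.
#' @param monotonize If `TRUE`, enforce a nondecreasing curve with a running
#'   maximum after adding noise (off by default).
#' @return A tibble with `time_h` and `release_pct`.
#' @examples
#' sim_release("first", c(Qinf = 83.5, k1 = 0.10))
#' @export
sim_release <- function(model, params, times = release_times(), noise_sd = 0,
                        seed = NULL, monotonize = FALSE) {
  model <- match.arg(model, release_model_names)
  check_number(times, "times", nonneg = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  p <- as.list(params)
  bad <- switch(model,
    zero    = is.null(p$Q0) || is.null(p$k0) || p$k0 <= 0,
    first   = is.null(p$Qinf) || is.null(p$k1) || p$Qinf <= 0 || p$Qinf > 100 || p$k1 <= 0,
    higuchi = is.null(p$kH) || p$kH <= 0,
    peppas  = is.null(p$kP) || is.null(p$n) || p$kP <= 0 || p$n <= 0
  )
  if (isTRUE(bad)) stop_invalid(sprintf("invalid parameters for model `%s`.", model))
  q <- eval_release(model, params, times)
  q[times == 0] <- 0
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    noise <- stats::rnorm(length(q), 0, noise_sd)
    noise[times == 0] <- 0
    q <- pmin(pmax(q + noise, 0), 100)
  }
  if (monotonize) q <- cummax(q)
  tibble::tibble(time_h = times, release_pct = q)
}
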