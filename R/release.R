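#' Cumulative release from replacement-sampling dialysis measurements
#'
#' Converts sampled medium concentrations into the cumulative percentage of
#' the loaded drug released, correcting for the drug removed with each
#' withdrawn sample that was replaced by fresh medium:
#' `Qn = 100 * (Cn * V + v * sum(Ci, i < n)) / m`
#' with vessel volume `V` (mL), sample volume `v` (mL), sampled
#' concentrations `Ci` (mg/mL) and loaded drug mass `m` (mg). Values above
#' 100% (possible with measurement error) are clipped to 100 with a warning.
#'
#' @param data Data frame with a time column (hours) and a concentration
#'   column (mg/mL), in sampling order.
#' @param volume Vessel (release medium) volume in mL.
#' @param sample_volume Withdrawn-and-replaced sample volume in mL.
#' @param mass Loaded drug mass in mg.
#' @param time,conc Column names (defaults `time_h`, `conc_mg_ml`).
#'
#' @return A tibble with `time_h` and `release_pct`.
#' @examples
#' d <- data.frame(time_h = c(1, 2), conc_mg_ml = c(0.2, 0.3))
#' cumulative_release(d, volume = 100, sample_volume = 1, mass = 100)
#' @export
cumulative_release <- function(data, volume, sample_volume = 0, mass,
                               time = "time_h", conc = "conc_mg_ml") {
  missing <- setdiff(c(time, conc), names(data))
  if (length(missing)) {
    stop_invalid(paste0("column(s) not in `data`: ", paste(missing, collapse = ", ")),
                 class = "schema")
  }
  check_number(volume, "volume", positive = TRUE)
  check_number(mass, "mass", positive = TRUE)
  check_number(sample_volume, "sample_volume", nonneg = TRUE)
  cc <- data[[conc]]
  check_number(cc, "concentrations", nonneg = TRUE)
  withdrawn <- sample_volume * dplyr::lag(cumsum(cc), default = 0)
  q <- 100 * (cc * volume + withdrawn) / mass
  if (any(q > 100)) {
    warn(sprintf("%d cumulative release value(s) exceeded 100%% and were clipped.",
                 sum(q > 100)))
    q <- pmin(q, 100)
  }
  tibble::tibble(time_h = data[[time]], release_pct = q)
}

release_model_names <- c("zero", "first", "higuchi", "peppas")

#' Evaluate a release kinetic model
#'
#' Model forms (Q = cumulative release \%, t = hours):
#' * `zero`: `Q = Q0 + k0 * t`
#' * `first` (plateau first-order): `Q = Qinf * (1 - exp(-k1 * t))`
#' * `higuchi`: `Q = kH * sqrt(t) + c`
#' * `peppas` (Ritger-Peppas power law): `Q = kP * t^n`
#'
#' @param model One of `"zero"`, `"first"`, `"higuchi"`, `"peppas"`.
#' @param params Named numeric vector of that model's parameters
#'   (`Q0, k0` / `Qinf, k1` / `kH, c` / `kP, n`).
#' @param t Time points in hours.
#' @return Numeric vector of release percentages.
#' @examples
#' eval_release("first", c(Qinf = 83.5, k1 = 0.10), c(1, 48))
#' @export
eval_release <- function(model, params, t) {
  model <- match.arg(model, release_model_names)
  p <- as.list(params)
  switch(model,
    zero    = p$Q0 + p$k0 * t,
    first   = p$Qinf * (1 - exp(-p$k1 * t)),
    higuchi = p$kH * sqrt(t) + (p$c %||% 0),
    peppas  = p$kP * ifelse(t > 0, t^p$n, 0)
  )
}

#' Fit a drug-release kinetic model
#'
#' Fits one of the four classical release models (see [eval_release()] for
#' the functional forms) by least squares on the untransformed release
#' scale. The linear models (`zero`, `higuchi`) use ordinary least squares;
#' the nonlinear ones (`first`, `peppas`) use Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) initialized from the standard linearizations —
#' `-log(1 - Q/Qinf)` vs `t` for first-order and log-log regression for the
#' power law — with `t = 0` points excluded from the initialization but
#' included in the nonlinear objective. `r2 = 1 - SSres/SStot` is always
#' computed on the raw Q scale, so linear and nonlinear fits are comparable.
#'
#' @param data Data frame with `time_h` and `release_pct` columns (a
#'   [cumulative_release()] output, a [sim_release()] output, or any curve).
#' @param model Model name.
#' @param higuchi_intercept Fit the Higuchi model with a free additive
#'   intercept `c` (default); `FALSE` forces `c = 0`.
#' @param n_fixed For `model = "peppas"` only: fix the release exponent `n`
#'   and fit only `kP` (e.g. `n_fixed = 0.5` recovers the intercept-free
#'   Higuchi model).
#'
#' @return An object of class `release_fit`: list with `model`, `params`
#'   (named numeric), `r2`, `fitted`, `data`, `converged`. Methods:
#'   [tidy()], [glance()], [predict()], [autoplot()].
#' @examples
#' curve <- sim_release("first", c(Qinf = 83.5, k1 = 0.10))
#' fit_release(curve, "first")
#' @export
fit_release <- function(data, model = release_model_names,
                        higuchi_intercept = TRUE, n_fixed = NULL) {
  model <- match.arg(model)
  d <- check_release_curve(data)
  t <- d$time_h; q <- d$release_pct
  pos <- t > 0
  min_pos <- if (model == "first") 4 else 3
  if (sum(pos) < min_pos) {
    stop_invalid(sprintf("model `%s` needs at least %d points with t > 0.",
                         model, min_pos), class = "insufficient_runs")
  }

  params <- switch(model,
    zero = {
      co <- stats::coef(stats::lm(q ~ t))
      c(Q0 = unname(co[1]), k0 = unname(co[2]))
    },
    higuchi = {
      if (higuchi_intercept) {
        co <- stats::coef(stats::lm(q ~ sqrt(t)))
        c(kH = unname(co[2]), c = unname(co[1]))
      } else {
        co <- stats::coef(stats::lm(q ~ 0 + sqrt(t)))
        c(kH = unname(co[1]), c = 0)
      }
    },
    first = fit_first_order(t, q),
    peppas = fit_peppas(t, q, n_fixed)
  )

  fitted <- eval_release(model, params, t)
  ss_res <- sum((q - fitted)^2)
  ss_tot <- sum((q - mean(q))^2)
  structure(list(
    model = model,
    params = params,
    r2 = 1 - ss_res / ss_tot,
    ss_res = ss_res,
    fitted = fitted,
    data = tibble::tibble(time_h = t, release_pct = q),
    converged = TRUE
  ), class = "release_fit")
}

fit_first_order <- function(t, q) {
  qinf0 <- min(100, max(q) * 1.05)
  pos <- t > 0 & q / qinf0 < 1
  z <- -log(1 - q[pos] / qinf0)
  k0 <- max(stats::coef(stats::lm(z ~ 0 + t[pos]))[1], 1e-4)
  starts <- list(
    c(Qinf = qinf0, k1 = unname(k0)),
    c(Qinf = min(100, max(q)), k1 = 0.1),
    c(Qinf = 90, k1 = 0.05)
  )
  nls_with_restarts(
    q ~ Qinf * (1 - exp(-k1 * time)),
    data = data.frame(q = q, time = t),
    starts = starts,
    lower = c(Qinf = 1e-6, k1 = 1e-8),
    upper = c(Qinf = 100, k1 = Inf)
  )
}

fit_peppas <- function(t, q, n_fixed = NULL) {
  if (!is.null(n_fixed)) {
    check_number(n_fixed, "n_fixed", positive = TRUE)
    tn <- ifelse(t > 0, t^n_fixed, 0)
    kp <- stats::coef(stats::lm(q ~ 0 + tn))[1]
    return(c(kP = unname(kp), n = n_fixed))
  }
  pos <- t > 0 & q > 0
  if (sum(pos) < 3) {
    stop_invalid("too few positive points for log-log initialization.",
                 class = "insufficient_runs")
  }
  co <- stats::coef(stats::lm(log(q[pos]) ~ log(t[pos])))
  starts <- list(
    c(kP = exp(unname(co[1])), n = unname(co[2])),
    c(kP = max(q) / max(t)^0.5, n = 0.5)
  )
  nls_with_restarts(
    q ~ kP * ifelse(time > 0, time^n, 0),
    data = data.frame(q = q, time = t),
    starts = starts,
    lower = c(kP = 1e-8, n = 1e-6),
    upper = c(kP = Inf, n = Inf)
  )
}

nls_with_restarts <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), ifelse(is.finite(upper), upper, st))
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("nonlinear least squares failed to converge from all starting points.",
          class = "nanodoe_error_fit_failure", starts = starts)
  }
  stats::coef(best$fit)
}

check_release_curve <- function(data) {
  missing <- setdiff(c("time_h", "release_pct"), names(data))
  if (length(missing)) {
    stop_invalid(paste0("column(s) not in `data`: ", paste(missing, collapse = ", ")),
                 class = "schema")
  }
  d <- tibble::as_tibble(data)[c("time_h", "release_pct")]
  if (anyNA(d)) stop_invalid("missing values in release curve.")
  if (is.unsorted(d$time_h)) stop_invalid("`time_h` must be nondecreasing.")
  d
}

#' Fit all release models and select the best by R-squared
#'
#' Fits the four kinetic model families and returns the one with the highest
#' raw-scale R-squared. Ties (within 1e-9) are broken by the fixed model
#' order zero-order, first-order, Higuchi, Ritger-Peppas, which prefers the
#' more parsimonious special case: a curve generated by an intercept-free
#' Higuchi process ties the power law at `n = 0.5` and is reported as
#' Higuchi. Models that fail to fit are skipped with a warning; an error is
#' raised only if every model fails.
#'
#' @inheritParams fit_release
#' @param models Candidate model names (default all four).
#' @return The winning `release_fit`, with all candidate fits in
#'   `attr(, "candidates")`.
#' @examples
#' curve <- sim_release("first", c(Qinf = 83.5, k1 = 0.10), noise_sd = 1, seed = 7)
#' select_release_model(curve)$model
#' @export
select_release_model <- function(data, models = release_model_names,
                                 higuchi_intercept = TRUE) {
  fits <- purrr::map(models, function(m) {
    tryCatch(fit_release(data, m, higuchi_intercept = higuchi_intercept),
             error = function(e) {
               warn(sprintf("model `%s` failed to fit: %s", m, conditionMessage(e)))
               NULL
             })
  })
  names(fits) <- models
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    abort("all release models failed to fit.", class = "nanodoe_error_fit_failure")
  }
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  contenders <- which(r2 >= max(r2) - 1e-9)
  best <- fits[[contenders[1]]]
  attr(best, "candidates") <- fits
  best
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("Release kinetic fit: %s\n", x$model))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "), "\n")
  cat(sprintf("  R2 = %.4f (raw release scale, n = %d)\n", x$r2, nrow(x$data)))
  invisible(x)
}

#' @method tidy release_fit
#' @export
tidy.release_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance release_fit
#' @export
glance.release_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r2, ss_res = x$ss_res,
                 nobs = nrow(x$data))
}

#' @export
predict.release_fit <- function(object, newdata = object$data, ...) {
  t <- if (is.data.frame(newdata)) newdata$time_h else newdata
  eval_release(object$model, object$params, t)
}

#' Release curve with fitted model overlay
#'
#' @param object A `release_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot release_fit
#' @export
autoplot.release_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_h), length.out = 200)
  line <- tibble::tibble(time_h = tt, release_pct = predict(object, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$release_pct)) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "cumulative release (%)",
                  title = sprintf("%s model, R² = %.4f", object$model, object$r2)) +
    ggplot2::theme_minimal()
}
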