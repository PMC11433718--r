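#' Fit a full second-order response-surface model
#'
#' Fits, by ordinary least squares, the full quadratic polynomial
#' `y = b0 + sum(bi xi) + sum(bij xi xj) + sum(bii xi^2)` to a coded design
#' — the standard response-surface model for a Box-Behnken design, where the
#' coded columns make linear and interaction terms mutually orthogonal.
#'
#' @param data Data frame holding the coded factor columns and the response.
#' @param response Name of the response column (string).
#' @param factors Character vector of coded factor column names; defaults to
#'   `attr(data, "factor_cols")` when `data` came from [design_bbd()], else
#'   to every column matching `^X[0-9]+$`.
#'
#' @return An object of class `rsm_fit`: a list with the underlying `lm`
#'   fit, canonical term names, the coefficient vector split into
#'   `intercept`, `linear`, `interaction` and `quadratic` parts, and the
#'   diagnostics `r2`, `adj_r2`, `cv_percent` (`100 * sqrt(MSres) / mean(y)`)
#'   and `sigma`. Methods: [tidy()], [glance()], [predict()],
#'   [anova_rsm()], [rsm_optimum()], [autoplot()].
#' @examples
#' runs <- doe_example("bbd_runs")
#' fit <- fit_rsm(runs, "od")
#' tidy(fit)
#' glance(fit)
#' @export
fit_rsm <- function(data, response, factors = NULL) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    stop_invalid(sprintf("response column `%s` not found.", response), class = "schema")
  }
  factors <- factors %||% attr(data, "factor_cols") %||%
    grep("^X[0-9]+$", names(data), value = TRUE)
  factors <- setdiff(factors, response)
  if (!length(factors)) stop_invalid("no factor columns identified.", class = "schema")
  check_factor_cols(data, tibble::tibble(name = factors))

  y <- data[[response]]
  X <- quadratic_model_matrix(as.matrix(data[factors]))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop_invalid(sprintf(
      "need more runs (%d) than model parameters (%d) for the quadratic fit.", n, p
    ), class = "insufficient_runs")
  }
  if (qr(X)$rank < p) {
    stop_invalid("model matrix is rank deficient: design cannot support the full quadratic model.",
                 class = "singular_design")
  }
  df_fit <- tibble::as_tibble(as.data.frame(X[, -1, drop = FALSE]))
  names(df_fit) <- colnames(X)[-1]
  df_fit$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + ")
  ))
  lmfit <- stats::lm(fml, data = df_fit)

  b <- stats::coef(lmfit)
  names(b) <- colnames(X)
  res <- stats::residuals(lmfit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  m <- length(factors)
  structure(list(
    lm = lmfit,
    factors = factors,
    response = response,
    terms = colnames(X),
    coefficients = b,
    intercept = unname(b[1]),
    linear = b[factors],
    interaction = b[grep(":", names(b), fixed = TRUE)],
    quadratic = b[paste0(factors, "^2")],
    data = data,
    y = y,
    fitted = unname(stats::fitted(lmfit)),
    residuals = unname(res),
    ss_res = ss_res,
    ss_tot = ss_tot,
    r2 = 1 - ss_res / ss_tot,
    adj_r2 = 1 - (ss_res / (n - p)) / (ss_tot / (n - 1)),
    cv_percent = 100 * sqrt(ss_res / (n - p)) / mean(y),
    sigma = sqrt(ss_res / (n - p)),
    df_residual = n - p
  ), class = "rsm_fit")
}

# columns: intercept, linear, pairwise interactions (i < j), squares
quadratic_model_matrix <- function(Z) {
  f <- colnames(Z)
  m <- ncol(Z)
  cols <- list(`(Intercept)` = rep(1, nrow(Z)))
  for (i in seq_len(m)) cols[[f[i]]] <- Z[, i]
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cols[[paste0(f[i], ":", f[j])]] <- Z[, i] * Z[, j]
    }
  }
  for (i in seq_len(m)) cols[[paste0(f[i], "^2")]] <- Z[, i]^2
  do.call(cbind, cols)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Second-order response-surface fit\n")
  cat(sprintf("  response: %s | factors: %s | n = %d\n",
              x$response, paste(x$factors, collapse = ", "), length(x$y)))
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, CV%% = %.2f\n",
              x$r2, x$adj_r2, x$cv_percent))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @method tidy rsm_fit
#' @export
tidy.rsm_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @method glance rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  an <- anova_rsm(x, warn_no_reps = FALSE)
  mod <- an[an$source == "model", ]
  tibble::tibble(
    r.squared = x$r2,
    adj.r.squared = x$adj_r2,
    cv_percent = x$cv_percent,
    sigma = x$sigma,
    statistic = mod$statistic,
    p.value = mod$p.value,
    df = mod$df,
    df.residual = x$df_residual,
    nobs = length(x$y)
  )
}

#' Predict from a response-surface fit at coded points
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame with the fit's coded factor columns, or a
#'   numeric vector/matrix of coded coordinates (one point per row).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  Z <- coerce_points(object, newdata)
  unname(drop(quadratic_model_matrix(Z) %*% object$coefficients))
}

coerce_points <- function(fit, newdata) {
  m <- length(fit$factors)
  if (is.data.frame(newdata)) {
    check_factor_cols(newdata, tibble::tibble(name = fit$factors))
    Z <- as.matrix(newdata[fit$factors])
  } else if (is.numeric(newdata)) {
    Z <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
    if (ncol(Z) != m) {
      stop_invalid(sprintf("point has %d coordinates; fit has %d factors.",
                           ncol(Z), m))
    }
    colnames(Z) <- fit$factors
  } else {
    stop_invalid("`newdata` must be a data frame or numeric point(s).")
  }
  Z
}

#' ANOVA decomposition of a response-surface fit
#'
#' Produces the standard response-surface ANOVA: the overall model row,
#' per-term partial sums of squares (the increase in residual SS when that
#' single column is dropped from the full model), the residual, its split
#' into lack of fit and pure error (from replicated design points, typically
#' the center runs), and the total. On an orthogonal coded design the
#' partial SS of linear and interaction terms equal their contrast SS
#' (`8 b^2` and `4 b^2` on a 3-factor Box-Behnken design); quadratic terms
#' are non-orthogonal to the intercept, so drop-one refits are used
#' throughout. F statistics test each mean square against the residual mean
#' square, except lack of fit which is tested against pure error; p-values
#' are upper-tail F probabilities without multiplicity correction.
#'
#' @param fit An `rsm_fit`.
#' @param warn_no_reps Warn (default) when the design has no replicated
#'   points, in which case the lack-of-fit/pure-error rows are omitted.
#' @return A tibble with columns `source`, `sumsq`, `df`, `meansq`,
#'   `statistic`, `p.value`.
#' @examples
#' fit <- fit_rsm(doe_example("bbd_runs"), "od")
#' anova_rsm(fit)
#' @export
anova_rsm <- function(fit, warn_no_reps = TRUE) {
  stopifnot(inherits(fit, "rsm_fit"))
  X <- quadratic_model_matrix(as.matrix(fit$data[fit$factors]))
  y <- fit$y
  n <- nrow(X); p <- ncol(X)
  ss_res <- fit$ss_res
  ss_tot <- fit$ss_tot
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1
  df_res <- n - p
  ms_res <- ss_res / df_res

  part <- vapply(2:p, function(j) {
    Xr <- X[, -j, drop = FALSE]
    sum(stats::lm.fit(Xr, y)$residuals^2) - ss_res
  }, numeric(1))
  term_names <- colnames(X)[-1]

  f_mod <- (ss_mod / df_mod) / ms_res
  rows <- list(
    tibble::tibble(source = "model", sumsq = ss_mod, df = df_mod,
                   meansq = ss_mod / df_mod, statistic = f_mod,
                   p.value = stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE)),
    tibble::tibble(source = term_names, sumsq = part, df = 1L,
                   meansq = part, statistic = part / ms_res,
                   p.value = stats::pf(part / ms_res, 1, df_res, lower.tail = FALSE)),
    tibble::tibble(source = "residual", sumsq = ss_res, df = df_res,
                   meansq = ms_res, statistic = NA_real_, p.value = NA_real_)
  )

  key <- apply(fit$data[fit$factors], 1, paste, collapse = "\r")
  reps <- split(y, key)
  reps <- reps[lengths(reps) > 1]
  if (length(reps)) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- if (df_lof > 0) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
    rows <- c(rows, list(
      tibble::tibble(source = "lack of fit", sumsq = ss_lof, df = df_lof,
                     meansq = if (df_lof > 0) ss_lof / df_lof else NA_real_,
                     statistic = f_lof,
                     p.value = if (df_lof > 0)
                       stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
                     else NA_real_),
      tibble::tibble(source = "pure error", sumsq = ss_pe, df = df_pe,
                     meansq = ss_pe / df_pe, statistic = NA_real_,
                     p.value = NA_real_)
    ))
  } else if (warn_no_reps) {
    warn("no replicated design points: lack-of-fit and pure-error rows omitted.")
  }
  rows <- c(rows, list(
    tibble::tibble(source = "total", sumsq = ss_tot, df = n - 1L,
                   meansq = NA_real_, statistic = NA_real_, p.value = NA_real_)
  ))
  dplyr::bind_rows(rows)
}

#' Locate the optimum of a fitted response surface in the design cube
#'
#' Solves the stationary linear system `grad(yhat) = 0` of the fitted
#' quadratic. If the stationary point lies inside the coded cube
#' `[-1, 1]^m` and the Hessian is definite in the goal's direction
#' (eigenvalue signs, tolerance 1e-10), it is returned as an interior
#' optimum. Otherwise the surface is searched over the cube on a dense grid
#' refined by box-constrained local polish (`optim(method = "L-BFGS-B")`),
#' giving a boundary optimum (classification `"saddle-fallback"` when the
#' Hessian was singular or indefinite).
#'
#' When a factor table is supplied the coded optimum is uncoded to natural
#' units and additionally reported rounded half-up to `step` (a scalar or
#' per-factor vector, in each factor's own units) — the convention for
#' turning a stationary point into an operational recipe.
#'
#' @param fit An `rsm_fit`.
#' @param factors Optional [doe_factors()] table (with centers) for uncoding.
#' @param goal `"maximize"` or `"minimize"`.
#' @param step Reporting step for the rounded natural optimum (default 0.1).
#' @param grid_step Grid resolution for the constrained fallback search.
#' @return An object of class `rsm_optimum`: list with `coded`, `natural`,
#'   `natural_rounded`, `predicted`, `classification`, `goal`.
#' @examples
#' fit <- fit_rsm(doe_example("bbd_runs"), "od")
#' rsm_optimum(fit, factors = doe_example_factors())
#' @export
rsm_optimum <- function(fit, factors = NULL, goal = c("maximize", "minimize"),
                        step = 0.1, grid_step = 0.01) {
  stopifnot(inherits(fit, "rsm_fit"))
  goal <- match.arg(goal)
  m <- length(fit$factors)
  b <- fit$coefficients
  g <- unname(b[fit$factors])
  H <- matrix(0, m, m)
  diag(H) <- 2 * unname(b[paste0(fit$factors, "^2")])
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      H[i, j] <- H[j, i] <- unname(b[paste0(fit$factors[i], ":", fit$factors[j])])
    }
  }
  tol <- 1e-10
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  singular <- any(abs(ev) <= tol * max(1, max(abs(ev))))
  definite_ok <- if (goal == "maximize") all(ev < -tol) else all(ev > tol)

  coded <- NULL
  classification <- NULL
  if (!singular) {
    sp <- drop(solve(H, -g))
    if (all(abs(sp) <= 1 + 1e-9) && definite_ok) {
      coded <- pmin(pmax(sp, -1), 1)
      classification <- if (goal == "maximize") "interior maximum" else "interior minimum"
    }
  }
  if (is.null(coded)) {
    coded <- cube_search(fit, goal, grid_step)
    classification <- if (singular || !definite_ok) "saddle-fallback" else
      if (goal == "maximize") "boundary maximum" else "boundary minimum"
  }
  names(coded) <- fit$factors
  predicted <- unname(predict(fit, coded))

  natural <- natural_rounded <- NULL
  if (!is.null(factors)) {
    ord <- match(fit$factors, factors$name)
    if (anyNA(ord)) stop_invalid("`factors` does not cover all fit factors.", class = "schema")
    factors <- factors[ord, ]
    natural <- setNames(
      unlist(uncode_levels(tibble::as_tibble(as.list(coded)), factors)[factors$name]),
      fit$factors
    )
    step <- rep_len(step, m)
    natural_rounded <- setNames(round_half_up(natural, step), fit$factors)
  }
  structure(list(
    coded = coded, natural = natural, natural_rounded = natural_rounded,
    predicted = predicted, classification = classification, goal = goal
  ), class = "rsm_optimum")
}

round_half_up <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

# dense grid over [-1,1]^m (chunked to bound memory) + L-BFGS-B polish
cube_search <- function(fit, goal, grid_step) {
  m <- length(fit$factors)
  sgn <- if (goal == "maximize") 1 else -1
  ax <- seq(-1, 1, by = grid_step)
  grid <- as.matrix(expand.grid(rep(list(ax), m)))
  best_val <- -Inf
  best <- rep(0, m)
  chunk <- 2e5L
  for (s in seq(1, nrow(grid), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(grid))
    v <- sgn * predict(fit, grid[idx, , drop = FALSE])
    j <- which.max(v)
    if (v[j] > best_val) {
      best_val <- v[j]
      best <- grid[idx[j], ]
    }
  }
  polish <- stats::optim(
    best, function(x) -sgn * predict(fit, x),
    method = "L-BFGS-B", lower = rep(-1, m), upper = rep(1, m)
  )
  unname(polish$par)
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat(sprintf("Response-surface optimum (%s, %s)\n", x$goal, x$classification))
  cat("  coded: ", paste(sprintf("%s = %.4f", names(x$coded), x$coded), collapse = ", "), "\n")
  if (!is.null(x$natural)) {
    cat("  natural: ",
        paste(sprintf("%s = %.4f", names(x$natural), x$natural), collapse = ", "), "\n")
    cat("  rounded: ",
        paste(sprintf("%s = %g", names(x$natural_rounded), x$natural_rounded),
              collapse = ", "), "\n")
  }
  cat(sprintf("  predicted response: %.4f\n", x$predicted))
  invisible(x)
}

#' Contour plot of a fitted response surface
#'
#' Draws the predicted surface over two coded factors with the remaining
#' factors held at fixed coded values.
#'
#' @param object An `rsm_fit`.
#' @param vars Two factor names (or indices) to span the plot.
#' @param fix Coded value(s) for the remaining factors (default 0).
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsm_fit
#' @export
autoplot.rsm_fit <- function(object, vars = object$factors[1:2], fix = 0,
                             n = 60, ...) {
  if (is.numeric(vars)) vars <- object$factors[vars]
  stopifnot(length(vars) == 2, all(vars %in% object$factors))
  others <- setdiff(object$factors, vars)
  ax <- seq(-1, 1, length.out = n)
  grid <- expand.grid(a = ax, b = ax)
  names(grid) <- vars
  for (i in seq_along(others)) grid[[others[i]]] <- rep_len(fix, length(others))[i]
  grid$.pred <- predict(object, grid[object$factors])
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[vars[1]]], y = .data[[vars[2]]],
                                     z = .data$.pred, fill = .data$.pred)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = object$response) +
    ggplot2::labs(x = paste(vars[1], "(coded)"), y = paste(vars[2], "(coded)")) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
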