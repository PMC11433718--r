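#' Main-effects screening ANOVA for a Plackett-Burman experiment
#'
#' For each response, estimates every factor's main effect as the difference
#' of response means at the high and low level,
#' `effect = mean(y[x == +1]) - mean(y[x == -1])`, with sum of squares
#' `SS = N * effect^2 / 4` (`3 * effect^2` for the 12-run design). On the
#' orthogonal Plackett-Burman design these contrast effects equal twice the
#' OLS slopes. Unassigned (dummy) columns are pooled into the residual:
#' `SS_resid = SS_total - sum(SS over real factors)` with
#' `df_resid = N - 1 - n_factors`. Each factor is tested with
#' `F = SS / MS_resid` on (1, df_resid) degrees of freedom; a model row
#' aggregates the real factors.
#'
#' @param data Data frame holding coded factor columns (from [design_pbd()],
#'   possibly with responses joined on) — values must be -1/+1.
#' @param responses Character vector of response column names in `data`.
#' @param factors Character vector of real-factor column names; defaults to
#'   `attr(data, "factor_cols")`.
#' @param alpha Significance level for flagging (default 0.05).
#'
#' @return A tibble of class `pbd_screen` with one row per response x term
#'   (factors plus `"(model)"`): `response`, `term`, `effect`, `sumsq`, `df`,
#'   `meansq`, `statistic`, `p.value`, `significant`.
#' @examples
#' sim <- sim_pbd(c(A = 8), n_factors = 6, noise_sd = 0.5, seed = 1)
#' screen_pbd(sim, responses = "y")
#' @export
screen_pbd <- function(data, responses, factors = NULL, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  factors <- factors %||% attr(data, "factor_cols")
  if (is.null(factors)) {
    stop_invalid("`factors` not given and `data` carries no factor_cols attribute.",
                 class = "schema")
  }
  missing <- setdiff(c(factors, responses), names(data))
  if (length(missing)) {
    stop_invalid(paste0("column(s) not in `data`: ", paste(missing, collapse = ", ")),
                 class = "schema")
  }
  n <- nrow(data)
  k <- length(factors)
  df_res <- n - 1 - k
  if (df_res < 1) {
    stop_invalid(paste(
      "no residual degrees of freedom left for testing:",
      "use fewer factors or add replicate runs."
    ), class = "cannot_test")
  }
  for (f in factors) {
    if (!all(data[[f]] %in% c(-1, 1))) {
      stop_invalid(sprintf("factor column `%s` must be coded -1/+1.", f))
    }
  }
  out <- purrr::map_dfr(responses, function(r) {
    y <- data[[r]]
    ss_tot <- sum((y - mean(y))^2)
    effects <- vapply(factors, function(f) {
      x <- data[[f]]
      mean(y[x == 1]) - mean(y[x == -1])
    }, numeric(1))
    ss_f <- n * effects^2 / 4
    ss_res <- ss_tot - sum(ss_f)
    # guard against catastrophic cancellation on noiseless inputs
    ss_res <- max(ss_res, 0)
    ms_res <- ss_res / df_res
    f_stat <- if (ms_res > 0) ss_f / ms_res else ifelse(ss_f > 0, Inf, NaN)
    p <- stats::pf(f_stat, 1, df_res, lower.tail = FALSE)
    ss_mod <- sum(ss_f)
    f_mod <- if (ms_res > 0) (ss_mod / k) / ms_res else ifelse(ss_mod > 0, Inf, NaN)
    dplyr::bind_rows(
      tibble::tibble(
        response = r, term = "(model)", effect = NA_real_, sumsq = ss_mod,
        df = k, meansq = ss_mod / k, statistic = f_mod,
        p.value = stats::pf(f_mod, k, df_res, lower.tail = FALSE),
        significant = stats::pf(f_mod, k, df_res, lower.tail = FALSE) < alpha
      ),
      tibble::tibble(
        response = r, term = factors, effect = unname(effects),
        sumsq = unname(ss_f), df = 1L, meansq = unname(ss_f),
        statistic = unname(f_stat), p.value = unname(p),
        significant = unname(p) < alpha
      ),
      tibble::tibble(
        response = r, term = "(residual)", effect = NA_real_, sumsq = ss_res,
        df = df_res, meansq = ms_res, statistic = NA_real_,
        p.value = NA_real_, significant = NA
      )
    )
  })
  class(out) <- c("pbd_screen", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Heat map of screening p-values
#'
#' @param object A `pbd_screen` result.
#' @param ... Unused.
#' @return A ggplot object: factors x responses, tiles shaded by
#'   `-log10(p)`, significant cells outlined.
#' @method autoplot pbd_screen
#' @export
autoplot.pbd_screen <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      !.data$term %in% c("(model)", "(residual)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$term,
                                   fill = -log10(.data$p.value))) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "response", y = "factor") +
    ggplot2::theme_minimal()
}
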