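#' Min-max (Hassan) desirability of a single response
#'
#' Rescales a response to `[0, 1]` against the observed (or supplied) column
#' extremes, oriented so that larger desirability is always better:
#' `d = (y - ymin) / (ymax - ymin)` for a maximized response and
#' `d = (ymax - y) / (ymax - ymin)` for a minimized one. For any `y` in
#' range, the two orientations sum to 1.
#'
#' @param y Numeric response values.
#' @param direction `"maximize"` or `"minimize"` (abbreviations allowed).
#' @param ymin,ymax Extremes used for scaling; default to the observed
#'   `range(y)`, which is the convention for scoring a design's own runs.
#'
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @examples
#' desirability(c(122.5, 435.2, 200), "minimize")
#' desirability(71.74, "maximize", ymin = 37.93, ymax = 83.23)
#' @export
desirability <- function(y, direction = c("maximize", "minimize"),
                         ymin = min(y), ymax = max(y)) {
  direction <- match.arg(direction)
  check_number(y, "y")
  if (ymax <= ymin) {
    stop_invalid("response column is constant (ymin == ymax): desirability undefined.",
                 class = "degenerate_column")
  }
  if (any(y < ymin - 1e-12 | y > ymax + 1e-12)) {
    stop_invalid("`y` outside [ymin, ymax].", class = "out_of_range")
  }
  if (direction == "maximize") (y - ymin) / (ymax - ymin) else (ymax - y) / (ymax - ymin)
}

#' Score runs with the overall desirability (OD)
#'
#' Normalizes each response column to `[0, 1]` with [desirability()] (extremes
#' taken over the table's own runs) and combines the k per-response values by
#' their geometric mean, `OD = (d1 d2 ... dk)^(1/k)`. A run that is worst in
#' any response has `d = 0` there and hence `OD = 0`; a run best in every
#' response has `OD = 1`. The geometric mean is computed as
#' `exp(mean(log(d)))` with an explicit zero short-circuit, so zeros propagate
#' exactly rather than through `log(0)`.
#'
#' @param data Data frame with one row per run.
#' @param directions Named character vector mapping response column names to
#'   `"maximize"`/`"minimize"` (abbreviations allowed), e.g.
#'   `c(size_nm = "minimize", ee_pct = "maximize")`. Its names select the
#'   response columns entering the OD.
#'
#' @return `data` as a tibble with one `d_<response>` column per response and
#'   an `od` column appended. The number of responses is recorded in
#'   `attr(, "k")`.
#' @examples
#' runs <- doe_example("bbd_runs")
#' score_od(runs, c(size_nm = "minimize", potential_mV = "maximize",
#'                  ee_pct = "maximize", dl_pct = "maximize"))
#' @export
score_od <- function(data, directions) {
  if (is.null(names(directions)) || any(names(directions) == "")) {
    stop_invalid("`directions` must be a named vector of maximize/minimize.")
  }
  responses <- names(directions)
  missing <- setdiff(responses, names(data))
  if (length(missing)) {
    stop_invalid(paste0("response column(s) not in `data`: ",
                        paste(missing, collapse = ", ")), class = "schema")
  }
  directions <- vapply(
    directions,
    function(d) match.arg(d, c("maximize", "minimize")),
    character(1)
  )
  out <- tibble::as_tibble(data)
  if (anyNA(out[responses])) {
    stop_invalid("missing values in response columns.", class = "invalid_argument")
  }
  d_mat <- vapply(responses, function(r) {
    desirability(out[[r]], directions[[r]])
  }, numeric(nrow(out)))
  d_mat <- matrix(d_mat, nrow = nrow(out),
                  dimnames = list(NULL, paste0("d_", responses)))
  out[colnames(d_mat)] <- tibble::as_tibble(d_mat)
  out$od <- geometric_mean_rows(d_mat)
  attr(out, "k") <- length(responses)
  out
}

geometric_mean_rows <- function(d) {
  apply(d, 1, function(x) if (any(x == 0)) 0 else exp(mean(log(x))))
}

#' Bar chart of per-run overall desirability
#'
#' @param scores Output of [score_od()].
#' @param run Name of the run-id column (default `"run"`; falls back to row
#'   number if absent).
#' @return A ggplot object.
#' @export
plot_od <- function(scores, run = "run") {
  df <- tibble::as_tibble(scores)
  df$.run <- if (run %in% names(df)) factor(df[[run]], levels = df[[run]]) else
    factor(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.run, y = .data$od)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "run", y = "overall desirability (OD)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
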