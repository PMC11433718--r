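#' Define factors and their natural-unit levels
#'
#' A factor table maps each design factor to the natural-unit values of its
#' coded levels: `low` (coded -1), optional `center` (coded 0) and `high`
#' (coded +1). Three-level response-surface designs (Box-Behnken) require a
#' center; two-level screening designs (Plackett-Burman) do not.
#'
#' @param name Character vector of factor names.
#' @param low,high Natural-unit values at coded -1 and +1.
#' @param center Optional natural-unit values at coded 0. For a Box-Behnken
#'   factor the spacing must be symmetric: `high - center == center - low`.
#' @param units Optional character vector of unit labels.
#'
#' @return A tibble with columns `name`, `units`, `low`, `center`, `high` and
#'   `step` (half-range `(high - low) / 2`).
#' @examples
#' doe_factors(
#'   name   = c("X1", "X2", "X3"),
#'   low    = c(1.5, 1, 1),
#'   center = c(2.0, 2, 2),
#'   high   = c(2.5, 3, 3),
#'   units  = c("mg/mL", "mg/mL", "ratio")
#' )
#' @export
doe_factors <- function(name, low, high, center = NULL, units = "") {
  name <- as.character(name)
  check_number(low, "low")
  check_number(high, "high")
  if (any(low >= high)) stop_invalid("`low` must be strictly less than `high`.")
  if (is.null(center)) {
    center <- rep(NA_real_, length(name))
  } else {
    check_number(center, "center")
    if (any(center <= low | center >= high)) {
      stop_invalid("`center` must lie strictly between `low` and `high`.")
    }
    if (any(abs((high - center) - (center - low)) > 1e-8 * (high - low))) {
      stop_invalid("levels must be equally spaced: high - center must equal center - low.",
                   class = "invalid_spec")
    }
  }
  tibble::tibble(
    name = name,
    units = rep_len(as.character(units), length(name)),
    low = as.numeric(low),
    center = as.numeric(center),
    high = as.numeric(high),
    step = (as.numeric(high) - as.numeric(low)) / 2
  )
}

# standard 12-run Plackett-Burman generator row (first column of the cyclic
# construction); rows 1..11 are cyclic rotations, row 12 is all -1
pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate a 12-run Plackett-Burman screening design
#'
#' Builds the standard 12-run Plackett-Burman design by cyclic rotation of
#' the 11-element generator row `+ + - + + + - - - + -` followed by a final
#' all-`-1` row. The first `n_factors` columns are assigned to real factors;
#' the remaining columns are kept as dummy columns whose apparent effects
#' estimate error in the screening ANOVA.
#'
#' @param n_factors Number of real factors, between 1 and 11.
#' @param factors Optional factor table from [doe_factors()] supplying names
#'   (and natural levels) for the real columns; its rows must match
#'   `n_factors`.
#' @param randomize If `TRUE`, shuffle the run order (seeded). The default
#'   keeps the deterministic generator order so designs are reproducible.
#' @param seed Optional integer seed used only when `randomize = TRUE`.
#'
#' @return A 12-row tibble with a `run` column and one coded column per
#'   factor. Real-factor columns come first; dummy columns are named
#'   `dum1`, `dum2`, ... and recorded in `attr(, "dummy_cols")`.
#'   `attr(, "factor_cols")` names the real columns and
#'   `attr(, "design_kind")` is `"pbd"`.
#' @examples
#' pbd <- design_pbd(6)
#' colSums(pbd[attr(pbd, "factor_cols")]) # all balanced to 0
#' @export
design_pbd <- function(n_factors, factors = NULL, randomize = FALSE, seed = NULL) {
  if (length(n_factors) != 1 || n_factors != round(n_factors) ||
      n_factors < 1 || n_factors > 11) {
    stop_invalid("`n_factors` must be a single integer in 1..11.")
  }
  n_factors <- as.integer(n_factors)
  rows <- vapply(0:10, function(s) {
    idx <- ((seq_len(11) - 1 + s) %% 11) + 1
    pb12_generator[idx]
  }, numeric(11))
  mat <- rbind(t(rows), rep(-1, 11))
  fac_names <- if (!is.null(factors)) {
    if (nrow(factors) != n_factors) {
      stop_invalid("`factors` must have one row per real factor.")
    }
    factors$name
  } else {
    LETTERS[seq_len(n_factors)]
  }
  dummy_names <- if (n_factors < 11) paste0("dum", seq_len(11 - n_factors)) else character()
  colnames(mat) <- c(fac_names, dummy_names)
  out <- tibble::as_tibble(mat)
  if (randomize) {
    if (!is.null(seed)) withr::local_seed(seed)
    out <- out[sample.int(12), ]
  }
  out <- dplyr::bind_cols(tibble::tibble(run = 1:12), out)
  attr(out, "design_kind") <- "pbd"
  attr(out, "factor_cols") <- fac_names
  attr(out, "dummy_cols") <- dummy_names
  out
}

# Box-Behnken edge runs for 3 factors in the run order of the packaged
# 17-run example study (n_center = 5); generic order is lexicographic pairs.
bbd3_edges_lex <- function() {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  signs <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  out <- matrix(0, nrow = 12, ncol = 3)
  k <- 1
  for (p in pairs) {
    for (i in seq_len(4)) {
      out[k, p] <- c(signs$a[i], signs$b[i])
      k <- k + 1
    }
  }
  out
}

bbd3_rows_study <- function() {
  matrix(c(
     0,  1, -1,
     0,  0,  0,
     0,  1,  1,
     0, -1, -1,
     0,  0,  0,
    -1,  1,  0,
     0, -1,  1,
     0,  0,  0,
     0,  0,  0,
     1,  0,  1,
     1,  0, -1,
    -1, -1,  0,
     0,  0,  0,
     1,  1,  0,
    -1,  0, -1,
     1, -1,  0,
    -1,  0,  1
  ), ncol = 3, byrow = TRUE)
}

#' Generate a three-factor Box-Behnken design
#'
#' The three-factor Box-Behnken design places 12 runs at the edge midpoints
#' of the coded factor cube (every +/-1 pair of two factors with the third at
#' 0) plus `n_center` replicated center runs `(0, 0, 0)`; the center
#' replicates provide the pure-error estimate for the lack-of-fit test.
#'
#' With `n_center = 5` the runs follow the row order of the packaged 17-run
#' chitosan/TPP nanoparticle study (see [doe_example()]) so fixtures align
#' row by row; otherwise edge runs come first in lexicographic factor-pair
#' order, followed by the center runs.
#'
#' @param n_center Number of center-point replicates (>= 1).
#' @param factors Optional 3-row factor table from [doe_factors()] supplying
#'   column names.
#'
#' @return A tibble with `run` and coded columns (default `X1`, `X2`, `X3`);
#'   `attr(, "design_kind")` is `"bbd"`, `attr(, "factor_cols")` names the
#'   factor columns.
#' @examples
#' design_bbd(5)
#' @export
design_bbd <- function(n_center = 5, factors = NULL) {
  if (length(n_center) != 1 || n_center != round(n_center) || n_center < 1) {
    stop_invalid("`n_center` must be a single integer >= 1.")
  }
  n_center <- as.integer(n_center)
  fac_names <- if (!is.null(factors)) {
    if (nrow(factors) != 3) stop_invalid("`factors` must have exactly 3 rows.")
    factors$name
  } else {
    c("X1", "X2", "X3")
  }
  mat <- if (n_center == 5) {
    bbd3_rows_study()
  } else {
    rbind(bbd3_edges_lex(), matrix(0, nrow = n_center, ncol = 3))
  }
  colnames(mat) <- fac_names
  out <- dplyr::bind_cols(
    tibble::tibble(run = seq_len(nrow(mat))),
    tibble::as_tibble(mat)
  )
  attr(out, "design_kind") <- "bbd"
  attr(out, "factor_cols") <- fac_names
  out
}

#' Convert between natural and coded factor levels
#'
#' `code_levels()` maps natural-unit columns to coded units via
#' `(natural - center) / step`, where `step = (high - low) / 2`;
#' `uncode_levels()` inverts the map. Columns of `data` not named in
#' `factors` pass through unchanged, so response columns can ride along.
#'
#' @param data Data frame containing one column per factor named in
#'   `factors`.
#' @param factors Factor table from [doe_factors()]; `code_levels()` requires
#'   a `center` for every factor.
#'
#' @return `data` with the factor columns transformed, as a tibble.
#' @examples
#' levs <- doe_factors("X2", low = 1, center = 2, high = 3, units = "mg/mL")
#' code_levels(data.frame(X2 = 2.3), levs)     # 0.3
#' uncode_levels(data.frame(X2 = -0.545), levs) # 1.455
#' @export
code_levels <- function(data, factors) {
  check_factor_cols(data, factors)
  if (anyNA(factors$center)) {
    stop_invalid("every factor needs a `center` to code levels.", class = "invalid_spec")
  }
  if (any(factors$step == 0)) {
    stop_invalid("factor step must be non-zero.", class = "invalid_spec")
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(factors))) {
    nm <- factors$name[i]
    out[[nm]] <- (out[[nm]] - factors$center[i]) / factors$step[i]
  }
  out
}

#' @rdname code_levels
#' @export
uncode_levels <- function(data, factors) {
  check_factor_cols(data, factors)
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(factors))) {
    nm <- factors$name[i]
    x <- out[[nm]]
    if (is.na(factors$center[i])) {
      # two-level factor: only +/-1 are defined
      if (any(!x %in% c(-1, 1))) {
        stop_invalid(sprintf(
          "factor `%s` has no center; only coded -1/+1 can be uncoded.", nm
        ), class = "invalid_spec")
      }
      out[[nm]] <- ifelse(x > 0, factors$high[i], factors$low[i])
    } else {
      out[[nm]] <- factors$center[i] + x * factors$step[i]
    }
  }
  out
}

check_factor_cols <- function(data, factors) {
  missing <- setdiff(factors$name, names(data))
  if (length(missing)) {
    stop_invalid(paste0(
      "missing factor column(s): ", paste(missing, collapse = ", ")
    ), class = "schema")
  }
  invisible(TRUE)
}
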