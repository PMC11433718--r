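#' Read design/response and release-curve CSV files
#'
#' Thin, schema-checked readers around [readr::read_csv()]. Headers are
#' matched case-insensitively against common aliases and normalized to the
#' package's canonical column names, so column order never matters.
#'
#' `read_design_csv()` expects a run-id column (`run`, `group` or `id`) plus
#' numeric factor/response columns. `read_release_csv()` expects a time
#' column (`time_h`, `time`, `t`, `hours`) and either a cumulative-release
#' column (`release_pct`, `q`, `q_percent`, `release`) or a raw
#' concentration column (`conc_mg_ml`, `conc`, `concentration`) to be
#' converted later with [cumulative_release()].
#'
#' @param path CSV file path.
#' @return A tibble with canonical column names.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' readr::write_csv(doe_example("bbd_runs"), p)
#' read_design_csv(p)
#' @export
read_design_csv <- function(path) {
  df <- read_checked_csv(path)
  names(df) <- rename_aliases(names(df), list(run = c("run", "group", "id")))
  if (!"run" %in% names(df)) {
    stop_invalid(paste0(
      "no run-id column found: expected one of run/group/id, got ",
      paste(names(df), collapse = ", ")
    ), class = "schema")
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num)) {
    for (col in non_num) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      if (length(bad)) {
        stop_invalid(sprintf("non-numeric value in column `%s`, row %d.", col, bad[1]),
                     class = "parse")
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  df
}

#' @rdname read_design_csv
#' @export
read_release_csv <- function(path) {
  df <- read_checked_csv(path)
  names(df) <- rename_aliases(names(df), list(
    time_h = c("time_h", "time", "t", "hours", "time_hr"),
    release_pct = c("release_pct", "q", "q_percent", "q_pct", "release",
                    "cumulative_release"),
    conc_mg_ml = c("conc_mg_ml", "conc", "concentration", "conc_mg_per_ml")
  ))
  if (!"time_h" %in% names(df) ||
      !any(c("release_pct", "conc_mg_ml") %in% names(df))) {
    stop_invalid(paste0(
      "expected a time column and a release or concentration column; found: ",
      paste(names(df), collapse = ", ")
    ), class = "schema")
  }
  df
}

read_checked_csv <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("file not found: ", path), class = "schema")
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_invalid(paste0("cannot parse CSV: ", conditionMessage(e)),
                                     class = "parse")
  )
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop_invalid("file is empty or has no data rows.", class = "schema")
  }
  df
}

rename_aliases <- function(nm, alias_map) {
  low <- tolower(nm)
  for (canon in names(alias_map)) {
    hit <- which(low %in% tolower(alias_map[[canon]]))
    if (length(hit)) nm[hit[1]] <- canon
  }
  nm
}

#' Write a table to CSV
#'
#' Round-trip companion to the readers: `read_design_csv(write_doe_csv(x))`
#' is value-identical.
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_doe_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Run the full design -> OD -> fit -> ANOVA -> optimum pipeline
#'
#' Chains the package's analysis stages on one design/response table:
#' [score_od()] computes the overall desirability, [fit_rsm()] fits the
#' quadratic surface to it, [anova_rsm()] decomposes it, and
#' [rsm_optimum()] locates and uncodes the constrained optimum. Every
#' section of the report equals the corresponding module output exactly.
#'
#' @param data Design/response table (coded factor columns + responses).
#' @param directions Named response orientations for [score_od()].
#' @param factors Optional [doe_factors()] table for uncoding the optimum.
#' @param goal Optimization goal (default `"maximize"`).
#' @param step Rounding step for the reported natural optimum.
#' @param response Name of the OD column created by [score_od()].
#' @return An object of class `doe_report`: list with `od_scores`,
#'   `coefficients`, `diagnostics`, `anova`, `optimum`.
#' @examples
#' rep <- run_report(doe_example("bbd_runs"), doe_example_directions(),
#'                   factors = doe_example_factors())
#' rep$optimum
#' @export
run_report <- function(data, directions, factors = NULL,
                       goal = "maximize", step = 0.1, response = "od") {
  scores <- score_od(data, directions)
  fit <- fit_rsm(scores, response)
  structure(list(
    od_scores = scores,
    coefficients = tidy(fit),
    diagnostics = glance(fit),
    anova = anova_rsm(fit),
    optimum = rsm_optimum(fit, factors = factors, goal = goal, step = step),
    fit = fit
  ), class = "doe_report")
}

#' @export
print.doe_report <- function(x, ...) {
  cat("== Design-of-experiments report ==\n\nCoefficients:\n")
  print(as.data.frame(dplyr::mutate(x$coefficients,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 4)))))
  cat("\nANOVA:\n")
  print(as.data.frame(dplyr::mutate(x$anova,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 4)))))
  cat("\n")
  print(x$optimum)
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the report sections with stable key order and full numeric
#' precision (display rounding is left to the print method), so two runs on
#' the same input produce byte-identical files.
#'
#' @param report A `doe_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "doe_report"))
  opt <- report$optimum
  payload <- list(
    od_scores = report$od_scores,
    coefficients = report$coefficients,
    diagnostics = report$diagnostics,
    anova = report$anova,
    optimum = list(
      coded = as.list(opt$coded),
      natural = as.list(opt$natural),
      natural_rounded = as.list(opt$natural_rounded),
      predicted = opt$predicted,
      classification = opt$classification,
      goal = opt$goal
    )
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
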