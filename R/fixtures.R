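#' Packaged example study tables
#'
#' Plain-text snapshots of the published chitosan/TPP nanoparticle
#' optimization study the package's worked examples reproduce:
#'
#' * `"bbd_runs"` — the 17-run Box-Behnken experiment: coded factors
#'   `X1` (chitosan concentration), `X2` (TPP concentration), `X3`
#'   (chitosan:TPP mass ratio), the four measured responses (`size_nm`,
#'   `potential_mV`, `ee_pct`, `dl_pct`) and the published overall
#'   desirability column `od`.
#' * `"bbd_levels"` — the natural-unit level map of the three Box-Behnken
#'   factors (low/center/high).
#' * `"pbd_levels"` — the two-level map of the six Plackett-Burman
#'   screening factors A-F.
#' * `"release_models"` — the published kinetic-equation parameters per
#'   release medium and model family (`p1`, `p2` in the order of
#'   [eval_release()] parameters; for Higuchi `p2` is the intercept).
#' * `"lyoprotectant"` — the mannitol mass-fraction series
#'   (mean +/- sd of size, potential, PDI, EE, DL).
#'
#' @param name Table name.
#' @return A tibble.
#' @examples
#' doe_example("bbd_runs")
#' @export
doe_example <- function(name = c("bbd_runs", "bbd_levels", "pbd_levels",
                                 "release_models", "lyoprotectant")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "nanodoe",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "bbd_runs") attr(out, "factor_cols") <- c("X1", "X2", "X3")
  out
}

#' Factor table of the packaged Box-Behnken study
#'
#' Convenience wrapper turning the `"bbd_levels"` example table into a
#' [doe_factors()] object ready for [code_levels()] / [rsm_optimum()].
#'
#' @return A factor tibble with centers.
#' @examples
#' doe_example_factors()
#' @export
doe_example_factors <- function() {
  lv <- doe_example("bbd_levels")
  doe_factors(name = lv$name, low = lv$low, center = lv$center,
              high = lv$high, units = lv$units)
}

#' Response orientations of the packaged Box-Behnken study
#'
#' Particle size is minimized; zeta potential, encapsulation efficiency and
#' drug loading are maximized.
#'
#' @return Named character vector suitable for [score_od()].
#' @export
doe_example_directions <- function() {
  c(size_nm = "minimize", potential_mV = "maximize",
    ee_pct = "maximize", dl_pct = "maximize")
}
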