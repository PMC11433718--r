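#' Closed-form formulation and bioassay metrics
#'
#' Vectorized implementations of the standard closed-form assay formulas
#' used to characterize drug-loaded nanoparticles:
#'
#' * `ee_percent()` — encapsulation efficiency,
#'   `EE% = (Wtotal - Wdissociate) / Wtotal * 100`, from the total drug mass
#'   and the free (dissociated) drug recovered in the supernatant.
#' * `dl_percent()` — drug loading,
#'   `DL% = Wtotal / Wlyophilized * 100`, drug mass per lyophilized powder
#'   mass.
#' * `dpph_scavenging()` — DPPH radical scavenging,
#'   `(A0 - A1 + A2) / A0 * 100`, with blank-control absorbance `A0`,
#'   sample + reagent `A1` and sample-control `A2`.
#' * `abts_scavenging()` — ABTS+ radical scavenging, `(A0 - A1) / A0 * 100`.
#' * `cell_viability()` — CCK-8 viability. `mode = "as-printed"` computes
#'   `(OD_sample - OD_control) / OD_control` (the difference form, which is
#'   0 for the control itself); `mode = "ratio"` computes the conventional
#'   `OD_sample / OD_control`.
#'
#' @param w_total Total drug mass (mg).
#' @param w_dissociate Free drug mass in the supernatant (mg).
#' @param w_lyophilized Lyophilized powder mass (mg).
#' @param a0,a1,a2 Absorbances: blank control, sample + reagent, sample
#'   control.
#' @param od_sample,od_control Optical densities of the sample and control
#'   wells.
#' @param mode Viability convention, `"as-printed"` (default) or `"ratio"`.
#' @return Numeric vector: a percentage for the first four metrics, a ratio
#'   for `cell_viability()`.
#' @examples
#' ee_percent(10, 2)        # 80
#' dl_percent(1, 10)        # 10
#' abts_scavenging(0.8, 0.2) # 75
#' cell_viability(1.2, 1.0, mode = "ratio")
#' @name assay_metrics
NULL

#' @rdname assay_metrics
#' @export
ee_percent <- function(w_total, w_dissociate) {
  check_number(w_total, "w_total", positive = TRUE)
  check_number(w_dissociate, "w_dissociate", nonneg = TRUE)
  if (any(w_dissociate > w_total)) {
    stop_invalid("`w_dissociate` cannot exceed `w_total`.")
  }
  (w_total - w_dissociate) / w_total * 100
}

#' @rdname assay_metrics
#' @export
dl_percent <- function(w_total, w_lyophilized) {
  check_number(w_total, "w_total", nonneg = TRUE)
  check_number(w_lyophilized, "w_lyophilized", positive = TRUE)
  w_total / w_lyophilized * 100
}

#' @rdname assay_metrics
#' @export
dpph_scavenging <- function(a0, a1, a2) {
  check_number(a0, "a0", positive = TRUE)
  check_number(a1, "a1", nonneg = TRUE)
  check_number(a2, "a2", nonneg = TRUE)
  (a0 - a1 + a2) / a0 * 100
}

#' @rdname assay_metrics
#' @export
abts_scavenging <- function(a0, a1) {
  check_number(a0, "a0", positive = TRUE)
  check_number(a1, "a1", nonneg = TRUE)
  (a0 - a1) / a0 * 100
}

#' @rdname assay_metrics
#' @export
cell_viability <- function(od_sample, od_control, mode = c("as-printed", "ratio")) {
  mode <- match.arg(mode)
  check_number(od_sample, "od_sample", nonneg = TRUE)
  check_number(od_control, "od_control", positive = TRUE)
  if (mode == "as-printed") {
    (od_sample - od_control) / od_control
  } else {
    od_sample / od_control
  }
}
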