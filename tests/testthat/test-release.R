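test_that("cumulative release applies the replacement-sampling correction", {
  z <- cumulative_release(data.frame(time_h = 1:3, conc_mg_ml = c(0, 0, 0)),
                          volume = 100, sample_volume = 1, mass = 100)
  expect_equal(z$release_pct, c(0, 0, 0))
  one <- cumulative_release(data.frame(time_h = 1, conc_mg_ml = 0.5),
                            volume = 100, sample_volume = 1, mass = 100)
  expect_equal(one$release_pct, 50)
  two <- cumulative_release(data.frame(time_h = c(1, 2), conc_mg_ml = c(0.2, 0.3)),
                            volume = 100, sample_volume = 1, mass = 100)
  expect_equal(two$release_pct, c(20, 30.2))
  expect_warning(
    over <- cumulative_release(data.frame(time_h = 1, conc_mg_ml = 2),
                               volume = 100, sample_volume = 0, mass = 100),
    "clipped"
  )
  expect_equal(over$release_pct, 100)
  expect_error(cumulative_release(data.frame(time_h = 1, conc_mg_ml = 1),
                                  volume = 0, sample_volume = 1, mass = 10),
               class = "nanodoe_error_invalid_argument")
})

test_that("cumulative release is nondecreasing when concentrations are nondecreasing", {
  withr::with_seed(14, {
    for (i in 1:10) {
      cc <- sort(runif(8, 0, 0.6))
      q <- cumulative_release(data.frame(time_h = 1:8, conc_mg_ml = cc),
                              volume = 100, sample_volume = 2, mass = 120)
      expect_true(all(diff(q$release_pct) >= -1e-12))
    }
  })
})

test_that("all four model families round-trip noiselessly through generation and fitting", {
  pars <- doe_example("release_models")
  times <- release_times()[-1] # linear intercept models are defined for t > 0
  param_names <- list(zero = c("Q0", "k0"), first = c("Qinf", "k1"),
                      higuchi = c("kH", "c"), peppas = c("kP", "n"))
  for (i in seq_len(nrow(pars))) {
    mod <- pars$model[i]
    truth <- stats::setNames(c(pars$p1[i], pars$p2[i]), param_names[[mod]])
    curve <- sim_release(mod, truth, times = times, noise_sd = 0)
    fit <- fit_release(curve, mod)
    expect_equal(unname(fit$params[names(truth)]), unname(truth),
                 tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("the power law with a fixed exponent of one half is the intercept-free Higuchi model", {
  curve <- sim_release("first", c(Qinf = 80, k1 = 0.12), noise_sd = 2, seed = 10)
  hig <- fit_release(curve, "higuchi", higuchi_intercept = FALSE)
  pep <- fit_release(curve, "peppas", n_fixed = 0.5)
  expect_equal(hig$ss_res, pep$ss_res, tolerance = 1e-10)
  expect_equal(unname(hig$params["kH"]), unname(pep$params["kP"]), tolerance = 1e-10)
})

test_that("model selection prefers the generating family and breaks ties parsimoniously", {
  lin <- tibble::tibble(time_h = release_times(), release_pct = 2 * release_times())
  best <- select_release_model(lin)
  expect_equal(best$model, "zero")
  expect_equal(best$r2, 1, tolerance = 1e-12)
  # intercept-free Higuchi data tie the power law at n = 0.5; Higuchi wins
  hig_curve <- sim_release("higuchi", c(kH = 12.5, c = 0), times = release_times()[-1])
  expect_equal(select_release_model(hig_curve)$model, "higuchi")
  cand <- attr(select_release_model(hig_curve), "candidates")
  expect_equal(cand$peppas$params[["n"]], 0.5, tolerance = 1e-6)
})

test_that("the release exponent is invariant to rescaling the time axis", {
  curve <- sim_release("peppas", c(kP = 13.2, n = 0.48), times = release_times()[-1])
  for (s in c(1 / 60, 2, 24)) {
    scaled <- dplyr::mutate(curve, time_h = time_h * s)
    fit <- fit_release(scaled, "peppas")
    expect_equal(unname(fit$params["n"]), 0.48, tolerance = 1e-5)
    expect_equal(unname(fit$params["kP"]), 13.2 / s^0.48, tolerance = 1e-4)
  }
})

test_that("release fitting validates its inputs", {
  expect_error(fit_release(tibble::tibble(time_h = c(0, 1, 2), release_pct = c(0, 5, 9)),
                           "first"),
               class = "nanodoe_error_insufficient_runs")
  expect_error(fit_release(tibble::tibble(time_h = c(2, 1, 3), release_pct = c(1, 2, 3)),
                           "zero"),
               class = "nanodoe_error_invalid_argument")
  expect_error(fit_release(tibble::tibble(time_h = 1:5, q = 1:5), "zero"),
               class = "nanodoe_error_schema")
})
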