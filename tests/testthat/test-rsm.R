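test_that("noiseless synthetic responses are recovered to numerical precision", {
  truth <- c(0.7, -0.15, 0.08, -0.12, 0.11, -0.14, 0.05, -0.25, -0.09, -0.11)
  sim <- sim_bbd(truth, noise_sd = 0)
  fit <- fit_rsm(sim, "y")
  expect_lt(max(abs(unname(fit$coefficients) - truth)), 1e-10)
  expect_lt(fit$ss_res, 1e-18)
  # fitted surface reproduces the generating values at every design point
  expect_equal(predict(fit, sim[c("X1", "X2", "X3")]), sim$y, tolerance = 1e-10)
})

test_that("a constant response gives a pure-intercept fit", {
  sim <- design_bbd(5)
  sim$y <- 0.42
  fit <- fit_rsm(sim, "y")
  expect_equal(fit$intercept, 0.42)
  expect_equal(max(abs(fit$coefficients[-1])), 0, tolerance = 1e-12)
})

test_that("OLS coefficients equal the orthogonal-contrast estimates on any Box-Behnken response", {
  withr::with_seed(21, {
    for (i in 1:20) {
      sim <- sim_bbd(rnorm(10), noise_sd = 0.3)
      fit <- fit_rsm(sim, "y")
      for (f in c("X1", "X2", "X3")) {
        expect_equal(fit$coefficients[[f]], sum(sim[[f]] * sim$y) / 8,
                     tolerance = 1e-10)
      }
      for (pp in list(c("X1", "X2"), c("X1", "X3"), c("X2", "X3"))) {
        expect_equal(fit$coefficients[[paste(pp, collapse = ":")]],
                     sum(sim[[pp[1]]] * sim[[pp[2]]] * sim$y) / 4,
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("the fit is invariant to run reordering", {
  sc <- score_od(table2, table2_directions)
  withr::with_seed(5, perm <- sample.int(nrow(sc)))
  fit1 <- fit_rsm(sc, "od", factors = c("X1", "X2", "X3"))
  fit2 <- fit_rsm(sc[perm, ], "od", factors = c("X1", "X2", "X3"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
})

test_that("the packaged study's published equation is reproduced from its OD column", {
  fit <- fit_table2()
  expect_lt(max(abs(unname(fit$coefficients) - unname(published_coef[fit$terms]))),
            1e-4)
})

test_that("ANOVA sums of squares are additive and split residual into lack of fit and pure error", {
  withr::with_seed(31, {
    for (i in 1:10) {
      sim <- sim_bbd(rnorm(10), noise_sd = 0.2)
      an <- anova_rsm(fit_rsm(sim, "y"))
      get <- function(s) an$sumsq[an$source == s]
      expect_equal(get("model") + get("residual"), get("total"),
                   tolerance = 1e-9)
      expect_equal(get("lack of fit") + get("pure error"), get("residual"),
                   tolerance = 1e-9)
      expect_equal(an$df[an$source == "model"] + an$df[an$source == "residual"],
                   an$df[an$source == "total"])
      expect_true(all(an$sumsq > -1e-12))
    }
  })
})

test_that("noiseless quadratic data leave zero residual and zero lack of fit", {
  sim <- sim_bbd(c(1, 0.5, -0.2, 0.3, 0.1, 0, 0.2, -0.4, 0.6, -0.1), noise_sd = 0)
  an <- anova_rsm(fit_rsm(sim, "y"))
  expect_lt(an$sumsq[an$source == "residual"], 1e-18)
  expect_lt(an$sumsq[an$source == "lack of fit"], 1e-18)
})

test_that("designs without replicated runs omit the lack-of-fit split with a warning", {
  sim <- sim_bbd(rnorm(10), n_center = 1, noise_sd = 0.1, seed = 2)
  expect_warning(an <- anova_rsm(fit_rsm(sim, "y")), "replicated")
  expect_false(any(an$source %in% c("lack of fit", "pure error")))
  expect_true(all(c("model", "residual", "total") %in% an$source))
})

test_that("prediction evaluates the quadratic polynomial exactly", {
  fit <- fit_table2()
  expect_equal(predict(fit, c(0, 0, 0)), fit$intercept)
  pt <- c(0, 0.3, -0.5)
  expect_equal(predict(fit, pt), eval_quadratic(fit$coefficients, pt),
               tolerance = 1e-12)
  expect_error(predict(fit, c(0, 1)), class = "nanodoe_error_invalid_argument")
})

test_that("a pure concave bowl has its interior maximum at the origin", {
  sim <- sim_bbd(c(2, 0, 0, 0, 0, 0, 0, -1, -1, -1), noise_sd = 0)
  opt <- rsm_optimum(fit_rsm(sim, "y"))
  expect_equal(opt$classification, "interior maximum")
  expect_equal(unname(opt$coded), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(opt$predicted, 2, tolerance = 1e-9)
})

test_that("the study optimum matches an independent linear-solver oracle and rounds to the published recipe", {
  fit <- fit_table2()
  opt <- rsm_optimum(fit, factors = table2_factors, step = 0.1)
  expect_equal(opt$classification, "interior maximum")
  expect_equal(unname(opt$coded), stationary_oracle(fit$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(opt$natural_rounded), c(2.0, 2.3, 1.5))
  # the constrained optimum dominates every design point
  expect_true(opt$predicted >= max(fit$fitted) - 1e-9)
})

test_that("an indefinite surface falls back to a constrained search", {
  sim <- sim_bbd(c(0, 0, 0, 0, 0, 0, 0, 1, -1, 1), noise_sd = 0) # saddle
  opt <- rsm_optimum(fit_rsm(sim, "y"), grid_step = 0.05)
  expect_equal(opt$classification, "saddle-fallback")
  expect_true(all(abs(opt$coded) <= 1 + 1e-9))
  # maximum of x1^2 - x2^2 + x3^2 over the cube is 2 at (+/-1, 0, +/-1)
  expect_equal(opt$predicted, 2, tolerance = 1e-6)
})

test_that("degenerate designs raise classed errors", {
  sim <- sim_bbd(rnorm(10), noise_sd = 0.1, seed = 3)
  expect_error(fit_rsm(sim[1:9, ], "y"), class = "nanodoe_error_insufficient_runs")
  bad <- sim
  bad$X3 <- bad$X1
  expect_error(fit_rsm(bad, "y"), class = "nanodoe_error_singular_design")
})
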