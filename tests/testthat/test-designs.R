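test_that("12-run Plackett-Burman columns are balanced and mutually orthogonal for every width", {
  for (k in 1:11) {
    d <- design_pbd(k)
    expect_equal(nrow(d), 12)
    mat <- as.matrix(d[-1])
    expect_equal(ncol(mat), 11) # real + dummy columns always span the full design
    expect_true(all(colSums(mat == 1) == 6))
    expect_true(all(colSums(mat == -1) == 6))
    expect_equal(colSums(mat), rep(0, 11), ignore_attr = TRUE)
    gram <- crossprod(mat)
    expect_equal(gram - diag(12, 11), matrix(0, 11, 11), ignore_attr = TRUE)
    expect_equal(attr(d, "factor_cols"), colnames(mat)[seq_len(k)])
  }
})

test_that("Plackett-Burman argument checks and randomization behave", {
  expect_error(design_pbd(0), class = "nanodoe_error_invalid_argument")
  expect_error(design_pbd(12), class = "nanodoe_error_invalid_argument")
  d1 <- design_pbd(6, randomize = TRUE, seed = 1)
  d2 <- design_pbd(6, randomize = TRUE, seed = 1)
  expect_identical(d1, d2)
  expect_setequal(d1$run, 1:12)
})

test_that("uncoding a screening design yields only the two natural levels per factor", {
  lv <- doe_example("pbd_levels")
  specs <- doe_factors(lv$name, low = lv$low, high = lv$high, units = lv$units)
  d <- design_pbd(6, factors = specs)
  nat <- uncode_levels(d[c("run", specs$name)], specs)
  expect_setequal(unique(nat$A), c(2, 3))
  expect_setequal(unique(nat$B), c(1, 3))
  expect_setequal(unique(nat$F), c(1, 2))
})

test_that("Box-Behnken structure: 12 edge midpoints plus center replicates", {
  d <- design_bbd(5)
  expect_equal(nrow(d), 17)
  mat <- as.matrix(d[c("X1", "X2", "X3")])
  center <- rowSums(mat == 0) == 3
  expect_equal(sum(center), 5)
  edges <- mat[!center, , drop = FALSE]
  expect_true(all(rowSums(edges == 0) == 1))
  expect_true(all(abs(edges[edges != 0]) == 1))
  expect_equal(nrow(design_bbd(1)), 13)
  expect_error(design_bbd(0), class = "nanodoe_error_invalid_argument")
})

test_that("the 5-center Box-Behnken run order reproduces the packaged study rows exactly", {
  d <- design_bbd(5)
  expect_identical(as.matrix(d[c("X1", "X2", "X3")]),
                   as.matrix(table2[c("X1", "X2", "X3")]),
                   ignore_attr = TRUE)
  # and the edge runs form the same multiset for any other center count
  edge_key <- function(d) {
    m <- as.matrix(d[c("X1", "X2", "X3")])
    sort(apply(m[rowSums(m == 0) < 3, ], 1, paste, collapse = ","))
  }
  expect_identical(edge_key(design_bbd(3)), edge_key(table2))
})

test_that("coding maps natural levels to the expected coded values", {
  expect_equal(code_levels(data.frame(X1 = 2.0), table2_factors[1, ])$X1, 0)
  expect_equal(code_levels(data.frame(X2 = 2.3), table2_factors[2, ])$X2, 0.3)
  expect_equal(code_levels(data.frame(X3 = 1.455), table2_factors[3, ])$X3, -0.545)
})

test_that("coding and uncoding are mutual inverses on random natural values", {
  withr::with_seed(11, {
    for (i in 1:20) {
      nat <- tibble::tibble(
        X1 = runif(5, 1.5, 2.5), X2 = runif(5, 1, 3), X3 = runif(5, 1, 3)
      )
      back <- uncode_levels(code_levels(nat, table2_factors), table2_factors)
      expect_equal(back, nat, tolerance = 1e-12)
      coded <- code_levels(uncode_levels(
        tibble::tibble(X1 = runif(5, -1, 1), X2 = runif(5, -1, 1), X3 = runif(5, -1, 1)),
        table2_factors), table2_factors)
      expect_true(all(abs(coded$X1) <= 1 + 1e-12))
    }
  })
})

test_that("factor specification rejects degenerate or asymmetric level maps", {
  expect_error(doe_factors("A", low = 2, high = 2),
               class = "nanodoe_error_invalid_argument")
  expect_error(doe_factors("A", low = 1, center = 1.2, high = 3),
               class = "nanodoe_error_invalid_spec")
  expect_error(code_levels(data.frame(B = 1), doe_factors("A", low = 1, high = 3, center = 2)),
               class = "nanodoe_error_schema")
  expect_error(code_levels(data.frame(A = 1), doe_factors("A", low = 1, high = 3)),
               class = "nanodoe_error_invalid_spec")
})
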