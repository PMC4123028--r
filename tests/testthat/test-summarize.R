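# minimal hand-built fit objects so summaries are tested independently
# of the sampler
fake_fit <- function(draws, model = "model2", area_id = NULL,
                     modifiers = NULL) {
  structure(list(model = model, draws = draws,
                 chain = rep(1L, nrow(draws)),
                 rhat = rep(1, ncol(draws)), ess = rep(nrow(draws),
                                                       ncol(draws)),
                 meta = list(area_id = area_id, modifiers = modifiers)),
            class = "heat_fit")
}

test_that("percent change maps slopes to the reporting scale exactly", {
  expect_equal(percent_change(0)$estimate, 0)
  expect_equal(percent_change(log(2) / 10)$estimate, 100)
  # the inverse of the transform at the headline estimate
  expect_equal(percent_change(0.0069526)$estimate, 7.2, tolerance = 1e-3)
  # strict monotonicity in gamma
  g <- seq(-0.05, 0.05, length.out = 21)
  p <- vapply(g, function(x) percent_change(x)$estimate, 0)
  expect_true(all(diff(p) > 0))
  expect_error(percent_change(numeric(0)), "non-empty")
})

test_that("extra admissions reproduce the burden arithmetic", {
  expect_equal(extra_admissions(193, 7.2), 13.9)
  expect_equal(extra_admissions(100, 0), 0)
  expect_equal(extra_admissions(200, 10), 20)
  expect_error(extra_admissions(-1, 5), "mean_rate")
})

test_that("slope table classifies and orders areas by significance", {
  set.seed(1)
  n <- 800
  # three areas engineered to be positive / negative / null
  draws <- cbind(gamma_A = rnorm(n, 0.07, 0.01) / 10,
                 gamma_B = rnorm(n, -0.08, 0.012) / 10,
                 gamma_C = rnorm(n, 0, 0.02) / 10,
                 gamma_D = rnorm(n, 0.12, 0.01) / 10)
  fit <- fake_fit(draws, area_id = c("A", "B", "C", "D"))
  tab <- slope_table(fit)
  expect_equal(tab$signif[tab$area_id == "A"], "positive")
  expect_equal(tab$signif[tab$area_id == "B"], "negative")
  expect_equal(tab$signif[tab$area_id == "C"], "null")
  # layout: positives descending first, then negatives, then null
  expect_equal(tab$area_id[1:2], c("D", "A"))
  expect_equal(tab$area_id[3], "B")
  expect_true(all(tab$cri_low <= tab$pct_per_10C &
                    tab$pct_per_10C <= tab$cri_high))
  # significance counts equal a direct recount of intervals
  cnt <- attr(tab, "signif_counts")
  expect_equal(unname(cnt["positive"]), sum(tab$cri_low > 0))
  expect_equal(unname(cnt["negative"]), sum(tab$cri_high < 0))
  # published-table bounds imply the class
  expect_equal(tab$signif[tab$cri_low > 10][1], "positive")
  fit_bad <- fake_fit(draws[, 1:3], area_id = c("A", "B", "C", "D"))
  expect_error(slope_table(fit_bad), "inconsisten")
})

test_that("modifier table reports lambda per unit relative to the mean slope", {
  n <- 500
  gs <- rep(log(1.072) / 10, n)
  # lambda chosen so that +1000 units raises the slope by exactly 50%
  lam <- rep(0.5 * log(1.072) / 10 / 1000, n)
  draws <- cbind(gamma_star = gs, lambda_density = lam)
  fit <- fake_fit(draws, model = "model3", area_id = "A",
                  modifiers = "density")
  tab <- modifier_table(list(density = fit), c(density = 1000))
  expect_equal(tab$pct_change, 50, tolerance = 1e-10)
  zero <- fake_fit(cbind(gamma_star = gs, lambda_density = rep(0, n)),
                   model = "model3", modifiers = "density")
  tab0 <- modifier_table(list(z = zero), c(density = 1000))
  expect_equal(c(tab0$pct_change, tab0$cri_low, tab0$cri_high), c(0, 0, 0))
  expect_error(modifier_table(list(density = fit), c(elsewhere = 1)),
               "unit")
  expect_error(modifier_table(list(x = fake_fit(draws)), c(density = 1)),
               "modifier")
})

test_that("Moran's I equals the brute-force double sum and hand values", {
  # hand-evaluated 3-area case: z = (1, 0, -1), all-ones off-diagonal,
  # sum_ij w_ij z_i z_j = 2 * (1)(-1) = -2, S0 = 6, sum z^2 = 2:
  # I = (3/6) * (-2) / 2 = -0.5
  W <- matrix(1, 3, 3); diag(W) <- 0
  v <- c(2, 1, 0)
  res <- morans_i(v, W, n_perm = 99, seed = 1)
  expect_equal(res$I, -0.5)
  expect_equal(res$I, moran_brute(v, W))
  # brute-force equivalence on a synthetic city
  ar <- gen_area_frame(50, seed = 13)
  Wk <- knn_weights(ar, k = 5)
  set.seed(99)
  vals <- rnorm(50)
  rk <- morans_i(vals, Wk, n_perm = 99, seed = 2)
  expect_equal(rk$I, moran_brute(vals, Wk), tolerance = 1e-12)
  expect_gt(rk$p_value, 0)
  expect_lte(rk$p_value, 1)
  # cross-check against an independent library implementation
  if (requireNamespace("ape", quietly = TRUE)) {
    expect_equal(rk$I, unname(ape::Moran.I(vals, Wk)$observed),
                 tolerance = 1e-10)
  }
  expect_error(morans_i(rep(1, 50), Wk), "constant")
  expect_error(morans_i(vals[1:2], W[1:2, 1:2]), "3 areas")
})

test_that("Moran's I is invariant to shifting and positive scaling", {
  ar <- gen_area_frame(30, seed = 17)
  W <- knn_weights(ar, k = 5)
  set.seed(7)
  v <- rnorm(30)
  base <- morans_i(v, W, n_perm = 9, seed = 1)$I
  expect_equal(morans_i(v + 100, W, n_perm = 9, seed = 1)$I, base,
               tolerance = 1e-12)
  expect_equal(morans_i(v * 3.5, W, n_perm = 9, seed = 1)$I, base,
               tolerance = 1e-12)
})

test_that("knn weights are row-standardised with an empty diagonal", {
  ar <- gen_area_frame(12, seed = 19)
  W <- knn_weights(ar, k = 5)
  expect_equal(unname(rowSums(W)), rep(1, 12))
  expect_equal(diag(W), rep(0, 12))
  expect_true(all(W >= 0))
  expect_error(knn_weights(ar[1:4, ], k = 5), "at least")
})
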