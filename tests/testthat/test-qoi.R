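# Prediction map, quantities of interest, and distribution comparisons.

test_that("prediction over an empty window returns the initial state and composes", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule()
  m <- parameter_field(rep(log(0.3), n), rep(log(0.15), n))
  u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 50), 1)
  expect_equal(predict_state(dom, m, u0, 3, 3, sch), u0)
  # semigroup: predict to t1 then t2 equals predict to t2 directly
  u1 <- predict_state(dom, m, u0, 0, 4, sch)
  u2a <- predict_state(dom, m, u1, 4, 9, sch)
  u2b <- predict_state(dom, m, u0, 0, 9, sch)
  expect_equal(u2a, u2b, tolerance = 1e-9)
})

test_that("measurable region thresholds correctly", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  low <- measurable_region(rep(0.05, n), 0.1)
  expect_equal(max(low$u_hat), 0)
  expect_equal(sum(low$indicator), 0)
  high <- measurable_region(rep(0.5, n), 0.1)
  expect_equal(high$u_hat, rep(0.5, n))
  expect_error(measurable_region(rep(0.5, n), 1.2), "threshold")
})

test_that("cellularity and volume integrals match constants and a per-cell oracle", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  A <- sum(dom$fem$vol)
  expect_equal(total_tumor_cellularity(dom, rep(0.5, n)), 0.5 * A, tolerance = 1e-10)
  expect_equal(tumor_volume(dom, rep(0.5, n)), A, tolerance = 1e-10)
  expect_equal(total_tumor_cellularity(dom, rep(0.05, n)), 0)
  expect_equal(tumor_volume(dom, rep(0.05, n)), 0)
  # random field: lumped-mass quadrature equals the per-cell vertex-average
  # integration oracle
  set.seed(41)
  u <- runif(n)
  uh <- u * (u > 0.1)
  oracle <- sum(dom$fem$vol * rowMeans(matrix(uh[dom$cells], nrow(dom$cells))))
  expect_equal(total_tumor_cellularity(dom, u), oracle, tolerance = 1e-10)
  ind <- as.numeric(u > 0.1)
  oracle_v <- sum(dom$fem$vol * rowMeans(matrix(ind[dom$cells], nrow(dom$cells))))
  expect_equal(tumor_volume(dom, u), oracle_v, tolerance = 1e-10)
})

test_that("tumor volume is non-increasing in the threshold and TTC <= TV", {
  dom <- small_domain()
  set.seed(43)
  u <- runif(nrow(dom$vertices))
  th <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  tv <- vapply(th, function(t) tumor_volume(dom, u, t), numeric(1))
  expect_true(all(diff(tv) <= 0))
  for (t in th) {
    expect_lte(total_tumor_cellularity(dom, u, t), tumor_volume(dom, u, t))
  }
})

test_that("concordance correlation matches its closed form and penalizes offsets", {
  set.seed(47)
  x <- rnorm(200)
  expect_equal(ccc(x, x), 1)
  x0 <- x - mean(x)
  expect_equal(ccc(x0, -x0), -1)
  y <- x + 0.8
  direct <- 2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)
  expect_equal(ccc(x, y), direct)
  expect_lt(ccc(x, y), cor(x, y))
  expect_equal(ccc(x, y), ccc(y, x))
  expect_error(ccc(rep(1, 10), rep(2, 10)), "constant")
})

test_that("Dice coefficient counts overlaps and handles empty sets", {
  a <- c(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  b <- c(rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(dice(a, b), 0.5)  # |A|=|B|=100, 50 shared
  expect_equal(dice(logical(10), logical(10)), 1)
  expect_equal(dice(a, b), dice(b, a))
})

test_that("distribution comparisons detect shifts and scale changes", {
  set.seed(53)
  a <- rnorm(120)
  same <- compare_distributions(a, a + rnorm(120, sd = 1e-8))
  expect_gt(same[["location_p"]], 0.5)
  shifted <- compare_distributions(a, a + 10)
  expect_lt(shifted[["location_p"]], 1e-6)
  scaled <- compare_distributions(a, 10 * (a - mean(a)) + mean(a))
  expect_lt(scaled[["variance_p"]], 1e-6)
  expect_error(compare_distributions(rep(1, 30), rep(1, 30)), "identical")
  expect_error(compare_distributions(a[1:5], a), "at least 20")
})

test_that("pushforward from a point mass at truth has zero volume error", {
  dom <- small_domain()
  n <- nrow(dom$vertices)
  sch <- treatment_schedule()
  grid <- make_voxel_grid(dom, 4)
  m_true_v <- c(rep(log(0.3), n), rep(log(0.15), n))
  u0 <- pmin(0.8 * exp(-rowSums(dom$vertices^2) / 50), 1)
  u_true <- predict_state(dom, pf_split(m_true_v), u0, 0, 6, sch)
  truth <- list(tumor_volume = tumor_volume(dom, u_true),
                total_cellularity = total_tumor_cellularity(dom, u_true),
                voxel_values = observe(u_true, grid), grid = grid)
  # a Laplace posterior with a tiny prior spread is numerically a point mass
  tight <- block_prior(list(mD = matern_prior(dom, log(0.3), 1e-12, 10),
                            mkappa = matern_prior(dom, log(0.15), 1e-12, 10)))
  post <- laplace_posterior(m_true_v, NULL, tight)
  rec <- pushforward_qoi(post, n = 1, seed = 3, domain = dom, u0 = u0,
                         t0 = 0, t_pred = 6, schedule = sch,
                         qois = c("rel_error_volume", "ccc", "dice"), truth = truth)
  expect_equal(rec$value[rec$qoi == "rel_error_volume"], 0, tolerance = 1e-6)
  expect_equal(rec$value[rec$qoi == "ccc"], 1, tolerance = 1e-6)
  expect_equal(rec$value[rec$qoi == "dice"], 1)
  expect_identical(rec$provenance, rep("laplace", 3))
})
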