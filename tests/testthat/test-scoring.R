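test_that("monotonic repair sorts and preserves the value multiset", {
  expect_equal(repair_monotonic(c(3, 1, 2)), c(1, 2, 3))
  v <- sort(rnorm(99))
  expect_identical(repair_monotonic(v), v)
  w <- rnorm(50)
  expect_setequal(repair_monotonic(w), w)
})

test_that("the predicted CDF interpolates its knots and reaches 0/1", {
  taus <- as.numeric(quantile_grid())
  qv <- qnorm(taus, 100, 2)
  expect_equal(quantile_cdf(qv, taus, qv[50]), 0.50)
  mid <- (qv[40] + qv[41]) / 2
  expect_equal(quantile_cdf(qv, taus, mid), 0.405, tolerance = 1e-9)
  expect_equal(quantile_cdf(qv, taus, -1e6), 0)
  expect_equal(quantile_cdf(qv, taus, 1e6), 1)
  xs <- seq(90, 110, length.out = 400)
  expect_true(all(diff(quantile_cdf(qv, taus, xs)) >= 0))
  expect_error(quantile_cdf(rev(qv), taus, 100), "repaired")
  # clamped tails freeze at the outer grid levels
  expect_equal(quantile_cdf(qv, taus, -1e6, tails = "clamp"), 0.01)
  expect_equal(quantile_cdf(qv, taus, 1e6, tails = "clamp"), 0.99)
})

test_that("error score matches the Gaussian closed form on exact knots", {
  taus <- as.numeric(quantile_grid())
  qv <- qnorm(taus, 100, 2)
  es <- error_score(qv, taus, y = 102)      # y = mu + sigma
  expect_equal(es$P, 2 * pnorm(1) - 1, tolerance = 0.01)
  expect_equal(error_score(qv, taus, y = 100)$P, 0)
  expect_equal(error_score(qv, taus, y = 100)$dp5q, 1)
  expect_equal(error_score(qv, taus, y = 300)$P, 1)
})

test_that("error score equals the density-integration oracle", {
  taus <- as.numeric(quantile_grid())
  set.seed(33)
  for (k in 1:100) {
    # random location/scale families: smooth implied density, so the
    # 1e4-point trapezoid oracle is itself accurate beyond 1e-3
    mu <- runif(1, 0, 200); s <- runif(1, 0.5, 6)
    vec <- mu + s * qnorm(taus) * runif(1, 0.8, 1.2)
    y <- mu + runif(1, -4, 4) * s
    P <- error_score(vec, taus, y)$P
    expect_equal(P, trapezoid_error_score(vec, taus, y), tolerance = 1e-3)
  }
})

test_that("error score grows monotonically with the observed error", {
  taus <- as.numeric(quantile_grid())
  vec <- sort(qnorm(taus, 55, 1.5))
  ys <- seq(55, 75, by = 0.25)
  Ps <- vapply(ys, function(y) error_score(vec, taus, y)$P, 0)
  expect_true(all(diff(Ps) >= -1e-12))
  expect_true(all(Ps >= 0 & Ps <= 1))
})

test_that("degenerate distributions give the step-CDF scores", {
  taus <- as.numeric(quantile_grid())
  vec <- rep(120, 99)
  expect_equal(error_score(vec, taus, 120)$P, 0)
  expect_equal(error_score(vec, taus, 121)$P, 1)
})

test_that("molecular score is the geometric mean with zero propagation", {
  expect_equal(molecule_dp5q(c(1, 1, 1)), 1)
  expect_equal(molecule_dp5q(c(1, 0.25)), 0.5)
  expect_equal(molecule_dp5q(c(0.8, 0, 0.9)), 0)
  set.seed(2)
  for (k in 1:50) {
    x <- runif(sample(2:12, 1), 0.01, 1)
    expect_equal(molecule_dp5q(x), prod(x)^(1 / length(x)), tolerance = 1e-12)
    expect_gte(molecule_dp5q(x), min(x))
    expect_lte(molecule_dp5q(x), max(x))
  }
  expect_error(molecule_dp5q(numeric(0)), "no atomic scores")
})

test_that("molecular MAE averages assigned peak errors, order-free", {
  med <- c(20, 80, 140)
  sp <- shift_spectrum(c(21, 83, 140), assignment = c(1, 2, 3))
  expect_equal(molecule_mae(med, sp), (1 + 3 + 0) / 3)
  sp2 <- shift_spectrum(c(140, 21, 83), assignment = c(3, 1, 2))
  expect_equal(molecule_mae(med, sp2), molecule_mae(med, sp))
  expect_equal(molecule_mae(med, shift_spectrum(c(20, 80), c(1, 2))), 0)
  expect_error(molecule_mae(med, shift_spectrum(c(5, 6))), "assigned")
})

test_that("dp5q_score runs the full pipeline on a perfect prediction", {
  mol <- generate_conformers(parse_smiles("CCO"), 1, 42)
  sm0 <- surrogate_model(seed = 4, sigma_scale = 0)
  sim <- simulate_spectrum(mol, sm0)
  # a model stub whose predictions equal the true class quantiles exactly:
  # feed the scoring layer directly instead
  taus <- as.numeric(quantile_grid())
  class_vecs <- lapply(seq_along(mol$carbon_classes), function(ci)
    sim$class_mean[ci] + 2 * qnorm(taus))
  meds <- vapply(class_vecs, function(v) v[50], 0)
  a <- assign_peaks(meds, sim$spectrum$shifts)
  expect_equal(a$cost, 0)
  scores <- vapply(seq_along(sim$spectrum$shifts), function(p)
    error_score(class_vecs[[a$assignment[p]]], taus,
                sim$spectrum$shifts[p])$dp5q, 0)
  expect_equal(molecule_dp5q(scores), 1)
})
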