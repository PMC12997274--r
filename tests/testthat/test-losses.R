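test_that("modified Huber loss matches its closed forms and is C1", {
  expect_equal(huber(0, 1e-4), 0)
  expect_equal(huber(0.5, 1e-4), 0.49995)            # |r| - delta/2
  expect_equal(huber(5e-5, 1e-4), 1.25e-5)           # r^2 / (2 delta)
  # continuity and smoothness at the transition
  d <- 1e-4
  expect_equal(huber(d, d), huber(d + 1e-12, d), tolerance = 1e-6)
  g <- function(r, h = 1e-9) (huber(r + h, d) - huber(r - h, d)) / (2 * h)
  expect_equal(g(d), 1, tolerance = 1e-3)
  expect_equal(g(-d), -1, tolerance = 1e-3)
  expect_equal(g(0), 0, tolerance = 1e-3)
})

test_that("tau weights the asymmetry: 3x at 0.75, symmetric at 0.5", {
  under <- quantile_loss(y = 1, yhat = 0, tau = 0.75)   # yhat < y
  over <- quantile_loss(y = 0, yhat = 1, tau = 0.75)    # yhat > y
  expect_equal(under / over, 3)
  expect_equal(quantile_loss(1, 0, 0.5), quantile_loss(0, 1, 0.5))
  expect_equal(quantile_loss(5, 5, 0.3), 0)
  expect_error(quantile_loss(1, 0, 1.2), "tau")
})

test_that("quantile loss converges to pinball within delta/2 everywhere", {
  taus <- as.numeric(quantile_grid())
  res <- seq(-100, 100, by = 0.5)
  delta <- 1e-4
  for (tau in taus) {
    ql <- quantile_loss(res, 0, tau, delta)
    pb <- pinball(res, 0, tau)
    expect_lte(max(abs(ql - pb)), delta / 2)
  }
})

test_that("multi-quantile loss equals the term-by-term sum", {
  cfg <- loss_config()
  set.seed(42)
  y <- 57.3
  vec <- sort(rnorm(99, 57, 4))
  manual <- sum(vapply(seq_along(vec), function(k)
    quantile_loss(y, vec[k], as.numeric(cfg$grid)[k], cfg$delta), 0))
  expect_equal(multi_quantile_loss(y, vec, cfg), manual)
  expect_equal(multi_quantile_loss(y, rep(y, 99), cfg), 0)
  expect_error(multi_quantile_loss(y, vec[1:10], cfg), "grid length")
})

test_that("single-median grid reduces to symmetric pinball (half of MAE)", {
  cfg <- loss_config(grid = quantile_grid(0.5))
  set.seed(7)
  for (r in runif(20, -30, 30)) {
    expect_equal(multi_quantile_loss(r, 0, cfg), abs(r) / 2,
                 tolerance = cfg$delta)
  }
})

test_that("monotonicity penalty matches the hinge closed form", {
  expect_equal(monotonicity_penalty(c(1, 1.01, 1.02), 1e-6), 0)
  expect_equal(monotonicity_penalty(c(5.0, 4.0), 1e-6), 1.000001)
  expect_equal(monotonicity_penalty(rep(3.2, 99), 1e-6), 98e-6)
  expect_gte(monotonicity_penalty(rnorm(50), 1e-6), 0)
})

test_that("total loss composes the two terms and has finite gradients", {
  set.seed(1)
  y <- c(10, 120)
  yh <- rbind(sort(rnorm(99, 10, 2)), sort(rnorm(99, 118, 2)))
  l0 <- total_loss(y, yh, loss_config(mono_weight = 0))
  expect_equal(l0, mean(vapply(1:2, function(a)
    multi_quantile_loss(y[a], yh[a, ], loss_config()), 0)))
  # all quantiles equal to y cannot be jointly lossless when epsilon > 0
  flat <- matrix(y, 2, 99)   # row a constant at y[a]
  expect_gt(total_loss(y, flat, loss_config()), 0)
  expect_error(total_loss(numeric(0), yh), "empty batch")
  # finite gradients over a residual grid including 0 and +/- delta
  cfg <- loss_config()
  res <- c(-100, -1, -cfg$delta, 0, cfg$delta, 1, 100)
  for (r in res) {
    lg <- dp5q:::total_loss_grad(50 + r, matrix(rep(50, 99), 1), cfg)
    expect_true(all(is.finite(lg$grad)))
    expect_true(is.finite(lg$loss))
  }
})

test_that("loss scales linearly with residual scale far from delta", {
  cfg <- loss_config()
  y <- 0
  vec <- seq(2, 6, length.out = 99)
  l1 <- multi_quantile_loss(y, vec, cfg)
  l3 <- multi_quantile_loss(y, 3 * vec, cfg)
  expect_equal(l3 / l1, 3, tolerance = 0.01)
})

test_that("loss and grid configs validate their domains", {
  expect_error(loss_config(delta = 0), "delta")
  expect_error(quantile_grid(c(0.5, 0.4)), "increasing")
  expect_error(quantile_grid(c(0, 0.5)), "increasing|\\(0, 1\\)")
  expect_length(as.numeric(quantile_grid()), 99)
})
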