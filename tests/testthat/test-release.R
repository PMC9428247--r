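test_that("early- and late-time branches evaluate to their closed forms", {
  # frozen direct evaluations at K = 0.033 /h, no lag
  expect_equal(round(as.numeric(release_early(1, 0.033)), 3), 0.516)
  expect_equal(round(as.numeric(release_late(2, 0.033)), 3), 0.683)
  expect_equal(as.numeric(release_late(0, 0.033)), 1 - 6 / pi^2,
               tolerance = 1e-12)
  expect_equal(as.numeric(release_early(0.2, K = 0.033, t_lag = 0.2)), 0)
  expect_equal(release_fraction(1e4, 0.033), 1, tolerance = 1e-9)
})

test_that("validity flags fire outside each branch's range", {
  f <- release_early(c(0.1, 1, 5), 0.033)
  expect_equal(attr(f, "valid"), c(TRUE, FALSE, FALSE))
  # the early branch is flagged invalid well before its maximum at 3/(4K)
  K <- 0.08
  t_max <- 3 / (4 * K)
  t_invalid <- min(which(!attr(release_early(seq(0.01, t_max, 0.01), K),
                               "valid"))) * 0.01
  expect_lt(t_invalid, t_max / 2)
  l <- release_late(c(0.5, 50), 0.033)
  expect_equal(attr(l, "valid"), c(FALSE, TRUE))
})

test_that("both branches are monotone increasing in time and in K", {
  tt <- seq(0, 20, 0.25)
  for (K in c(0.01, 0.033, 0.2)) {
    l <- as.numeric(release_late(tt, K))
    expect_true(all(diff(l) >= 0))
    expect_true(all(diff(l)[l[-1] < 1 - 1e-12] > 0))
    f <- release_fraction(tt, K, t_lag = 0.3)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
  }
  expect_true(all(release_late(5, 0.05) > release_late(5, 0.02)))
})

test_that("the joined model is continuous and honors both branch validity zones", {
  for (K in c(0.005, 0.01, 0.033, 0.1, 0.25, 0.5)) {
    tau <- seq(1e-4 / K, 2 / K, length.out = 500)
    f1 <- release_fraction(tau, K)
    f2 <- release_fraction(tau + 1e-6 / K, K)
    expect_lt(max(abs(f2 - f1)), 1e-3)    # no step anywhere (a hard branch
                                          # switch would jump by ~0.05)
    # independent window edges: reduced times where the rising early
    # branch passes 0.4 and 0.6
    x_lo <- uniroot(function(x) 6 * sqrt(x / pi) - 3 * x - 0.4,
                    c(1e-8, 1 / pi))$root
    x_hi <- uniroot(function(x) 6 * sqrt(x / pi) - 3 * x - 0.6,
                    c(1e-8, 1 / pi))$root
    x <- K * tau
    e <- as.numeric(release_early(tau, K))
    late <- as.numeric(release_late(tau, K))
    expect_equal(f1[x <= x_lo], e[x <= x_lo], tolerance = 1e-6)  # pure early
    expect_equal(f1[x >= x_hi], late[x >= x_hi], tolerance = 1e-6) # pure late
    # inside the blend window the curve lies between the two branches
    mid <- x > x_lo & x < x_hi
    expect_true(all(f1[mid] >= pmin(e, late)[mid] - 1e-6 &
                    f1[mid] <= pmax(e, late)[mid] + 1e-6))
  }
})

test_that("release curves validate their inputs", {
  expect_error(release_curve(c(1, 1, 2), c(0.1, 0.2, 0.3)), "increasing")
  expect_error(release_curve(c(1, 2), c(0.1, 1.2)), "\\[0, 1.05\\]")
  # percent input is auto-detected
  cv <- release_curve(c(1, 2, 4), c(30, 60, 90))
  expect_equal(cv$mean_fraction, c(0.3, 0.6, 0.9))
  expect_warning(release_curve(c(1, 2, 3), c(0.9, 0.5, 0.95)),
                 "decreases")
})

test_that("late-time linearization recovers K exactly from noise-free data", {
  cv <- sim_release_curve(K = 0.033, t_lag = 0, noise_sd = 0, n_rep = 1)
  expect_equal(fit_release_late(cv), 0.033, tolerance = 1e-6)
  # equals a brute-force 1-D grid minimization of the late-time SSE
  fbar <- cv$mean_fraction
  sel <- fbar >= 0.6 & fbar < 1
  grid_K <- seq(0.001, 0.2, 1e-5)
  # oracle: weighted SSE of the linearized model, intercept profiled out
  w <- (1 - fbar[sel])^2
  sse2 <- vapply(grid_K, function(K) {
    r <- log(1 - fbar[sel]) + pi^2 * K * cv$times[sel]
    sum(w * (r - weighted.mean(r, w))^2)
  }, 0)
  expect_equal(fit_release_late(cv), grid_K[which.min(sse2)],
               tolerance = 2e-5)
})

test_that("curves that never reach the threshold raise an error", {
  cv <- release_curve(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_error(fit_release_late(cv), "insufficient data")
  expect_error(fit_release(cv), "insufficient data")
})

test_that("the two-stage fit recovers K and lag from noise-free curves", {
  cv <- sim_release_curve(K = 0.033, t_lag = 0.2, noise_sd = 0, n_rep = 1)
  fit <- fit_release(cv)
  expect_equal(fit$model$K, 0.033, tolerance = 1e-3)
  expect_equal(fit$model$t_lag, 0.2, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(fit$mse, 1e-6)
  # joint refinement stays at the optimum
  fitj <- fit_release(cv, joint = TRUE)
  expect_equal(fitj$model$K, 0.033, tolerance = 1e-3)
  expect_equal(fitj$model$t_lag, 0.2, tolerance = 5e-3)
})

test_that("a true zero lag is estimated as (near) zero", {
  cv <- sim_release_curve(K = 0.05, t_lag = 0, noise_sd = 0, n_rep = 1)
  expect_lte(fit_release(cv)$model$t_lag, 0.05)
  cvn <- sim_release_curve(K = 0.05, t_lag = 0, noise_sd = 0.02,
                           n_rep = 6, seed = 11)
  expect_lte(fit_release(cvn)$model$t_lag, 0.05)
})

test_that("parameter bias vanishes as noise goes to zero", {
  for (sd in c(0.02, 0.01, 0)) {
    set.seed(5)
    Ks <- replicate(30, fit_release(sim_release_curve(noise_sd = sd))$model$K)
    err <- abs(mean(Ks) - 0.033)
    if (sd == 0) expect_lt(err, 1e-3)
    assign(paste0("err_", sd * 100), err)
  }
  expect_lte(err_0, err_1 + 1e-9)
})

test_that("profile differences behave as release comparisons", {
  cv <- sim_release_curve(noise_sd = 0, n_rep = 1)
  pd <- profile_difference(cv, cv)
  expect_equal(pd$table$difference_pct, rep(0, nrow(pd$table)))
  slow <- sim_release_curve(K = 0.033, t_lag = 0, noise_sd = 0, n_rep = 1)
  fast <- sim_release_curve(K = 0.33, t_lag = 0, noise_sd = 0, n_rep = 1)
  pd2 <- profile_difference(slow, fast)
  early <- pd2$table$time_h <= 3
  expect_true(all(pd2$table$difference_pct[early] > 0))
  expect_error(profile_difference(
    release_curve(1:3, c(0.1, 0.2, 0.3)),
    release_curve(10:12, c(0.1, 0.2, 0.3))), "overlap")
})

test_that("fractional release is independent of the initial drug mass", {
  a <- sim_release_curve(noise_sd = 0, n_rep = 1, initial_mass = 12.5)
  b <- sim_release_curve(noise_sd = 0, n_rep = 1, initial_mass = 7.5)
  expect_equal(a$fractions, b$fractions)
  expect_equal(fit_release(a)$model$K, fit_release(b)$model$K)
})
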