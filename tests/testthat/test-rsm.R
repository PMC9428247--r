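# independent oracle: coefficients by the normal equations
normal_eq_oracle <- function(data, response, terms) {
  X <- stats::model.matrix(stats::reformulate(terms), data)
  drop(solve(crossprod(X), crossprod(X, data[[response]])))
}

test_that("surface coefficients match the normal-equations oracle", {
  tab <- qbd_ccd_table()
  for (cl in rsm_model_classes) {
    s <- fit_surface(tab, "size_nm", cl)
    orc <- normal_eq_oracle(tab, "size_nm", rsm_terms(cl, c("x1", "x2")))
    expect_equal(unname(s$coefficients), unname(orc), tolerance = 1e-8)
  }
})

test_that("coded fits of the study CCD reproduce the reported fits", {
  tab <- qbd_ccd_table()
  expect_equal(round(fit_surface(tab, "size_nm", "second_order")$r_squared,
                     2), 0.80)
  expect_equal(round(fit_surface(tab, "pdi", "pure_quadratic")$r_squared,
                     2), 0.97)
  # Z-potential pure-quadratic: frozen value from this table (0.6434)
  expect_equal(fit_surface(tab, "zeta_mv", "pure_quadratic")$r_squared,
               0.6434, tolerance = 1e-3)
})

test_that("nested model classes have monotone R-squared", {
  tab <- qbd_ccd_table()
  for (resp in c("size_nm", "pdi", "zeta_mv")) {
    r2 <- vapply(rsm_model_classes, function(cl)
      fit_surface(tab, resp, cl)$r_squared, 0)
    expect_true(r2["second_order"] >= r2["pure_quadratic"] - 1e-12)
    expect_true(r2["second_order"] >= r2["first_order_interactions"] - 1e-12)
    expect_true(r2["pure_quadratic"] >= r2["first_order"] - 1e-12)
    expect_true(r2["first_order_interactions"] >= r2["first_order"] - 1e-12)
  }
})

test_that("a noise-free quadratic surface is interpolated exactly", {
  d <- ccd_design(list(factor_spec("a", center = 0, step = 1),
                       factor_spec("b", center = 0, step = 1)))
  beta <- c("(Intercept)" = 150, x1 = 20, x2 = -8, "x1:x2" = 5,
            "I(x1^2)" = 12, "I(x2^2)" = -3)
  dat <- sim_doe_responses(d, beta, noise_sd = 0)
  s <- fit_surface(dat, "y", "second_order")
  expect_equal(s$r_squared, 1, tolerance = 1e-10)
  expect_equal(s$coefficients[names(beta)], beta, tolerance = 1e-8)
  expect_equal(s$residual_sd, 0, tolerance = 1e-8)
})

test_that("model selection reproduces the study's classes and honors parsimony", {
  tab <- qbd_ccd_table()
  expect_equal(select_model(tab, "size_nm")$model_class, "second_order")
  expect_equal(select_model(tab, "pdi")$model_class, "pure_quadratic")
  expect_equal(select_model(tab, "zeta_mv")$model_class, "pure_quadratic")

  # a response exactly linear in x1: every class fits perfectly, the
  # tie must break to the smallest class
  d <- ccd_design(list(factor_spec("a", center = 0, step = 1),
                       factor_spec("b", center = 0, step = 1)))
  dat <- sim_doe_responses(d, c("(Intercept)" = 10, x1 = 3), noise_sd = 0)
  expect_equal(select_model(dat, "y")$model_class, "first_order")
})

test_that("coefficient estimates are unbiased on noisy synthetic CCDs", {
  d <- ccd_design(list(factor_spec("a", center = 0, step = 1),
                       factor_spec("b", center = 0, step = 1)))
  beta <- c("(Intercept)" = 160, x1 = 15, x2 = -5, "x1:x2" = 4,
            "I(x1^2)" = 8, "I(x2^2)" = 6)
  set.seed(99)
  n_sim <- 500
  est <- matrix(NA_real_, n_sim, length(beta))
  for (i in seq_len(n_sim)) {
    dat <- sim_doe_responses(d, beta, noise_sd = 5)
    est[i, ] <- fit_surface(dat, "y", "second_order")$coefficients[names(beta)]
  }
  bias <- colMeans(est) - beta
  mc_se <- apply(est, 2, sd) / sqrt(n_sim)
  expect_true(all(abs(bias) < 4 * mc_se + 1e-8))
})

test_that("prediction error includes the new-observation term", {
  tab <- qbd_ccd_table()
  s <- fit_surface(tab, "size_nm", "second_order")
  p <- predict(s, c(x1 = 0, x2 = 0), se = TRUE)
  expect_gt(p$s_pred, s$residual_sd)
  expect_equal(p$rsd_pred_pct, 100 * p$s_pred / abs(p$fit))
  # exact-fit surface predicts with zero error
  d <- ccd_design(list(factor_spec("a", center = 0, step = 1),
                       factor_spec("b", center = 0, step = 1)))
  dat <- sim_doe_responses(d, c("(Intercept)" = 10, x1 = 2), noise_sd = 0)
  s0 <- fit_surface(dat, "y", "second_order")
  expect_equal(predict(s0, c(0.3, -0.2), se = TRUE)$s_pred, 0,
               tolerance = 1e-7)
})

test_that("extrapolation warns instead of failing", {
  tab <- qbd_ccd_table()
  s <- fit_surface(tab, "size_nm", "second_order")
  expect_warning(predict(s, c(x1 = 2, x2 = 2)), "outside")
  expect_silent(predict(s, c(x1 = 1, x2 = 0)))
})

test_that("the surface prediction at the desirability optimum is consistent with the measured replicates", {
  tab <- qbd_ccd_table()
  sel <- lapply(c(size_nm = "size_nm", pdi = "pdi", zeta_mv = "zeta_mv"),
                function(r) select_model(tab, r)$surface)
  opt <- maximize_desirability(sel, specs_from_data(tab, names(sel)),
                               seed = 1)
  pred_size <- predict(sel$size_nm, opt$optimum_coded)
  measured <- replicate_summary(c(180.1, 175.0, 180.6))$mean
  # consistency, not exactness: within the model's residual scale
  expect_lt(abs(pred_size - measured), 3 * sel$size_nm$residual_sd)
})
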