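sim_grouped <- function(n_per_group, seed = 1, delta = 5, sd_sub = 2, sd_eps = 1) {
  set.seed(seed)
  nsub <- 2 * n_per_group
  sub <- rep(sprintf("s%02d", seq_len(nsub)), each = 12)
  grp <- rep(rep(c("a", "b"), each = n_per_group), each = 12)
  tt <- rep(seq(0.5, 11.5, 1), nsub)
  y <- ifelse(grp == "b", delta, 0) + sin(tt / 2) +
    rep(rnorm(nsub, 0, sd_sub), each = 12) + rnorm(12 * nsub, 0, sd_eps)
  data.frame(sub = sub, grp = grp, tt = tt, y = y)
}

test_that("a cubic polynomial with tiny noise is recovered almost exactly", {
  set.seed(11)
  n <- 80
  t <- seq(0, 1, length.out = n)
  f <- 3 * t^3 - 2 * t^2 + t
  d <- data.frame(t = t, y = f + rnorm(n, 0, 1e-3))
  fit <- fit_ssanova(d, "y", ssanova_design("t"))
  expect_lt(max(abs(fit$fitted_values - f)) / diff(range(f)), 0.01)
  expect_gt(model_r_squared(fit), 0.999)
})

test_that("an infinite penalty collapses the fit onto the kernel null space", {
  set.seed(12)
  n <- 60
  t <- seq(0, 1, length.out = n)
  d <- data.frame(t = t, y = sin(4 * t) + rnorm(n, 0, 0.1))
  fit <- fit_ssanova(d, "y", ssanova_design("t"), lambda = c(smooth = 1e12))
  lm_fit <- lm(y ~ t, d)
  expect_lt(max(abs(fit$fitted_values - fitted(lm_fit))), 1e-6)
  # 2D: an exact plane is reproduced with zero residual at any penalty
  xy <- expand.grid(x = seq(0, 32, 8), y = seq(4, 92, 8))
  z <- 2 + 3 * xy$x - 0.5 * xy$y
  d2 <- data.frame(xy, z = z)
  for (lam in c(1e-3, 1, 1e6)) {
    fit2 <- fit_ssanova(d2, "z", ssanova_design(c("x", "y")),
                        lambda = c(smooth = lam))
    expect_lt(max(abs(fit2$fitted_values - z)), 1e-8)
  }
})

test_that("fixed-penalty fits equal a dense normal-equations solve", {
  d <- sim_grouped(2, seed = 13)              # 4 subjects x 12 epochs
  d <- d[d$tt %in% seq(0.5, 8.5, 2), ]        # 20 rows: small instance
  des <- ssanova_design("tt", factors = "grp", subject = "sub")
  lam <- c(smooth = 0.37, interaction = 2.1, subject = 5)
  fit <- fit_ssanova(d, "y", des, lambda = lam)
  # oracle: rebuild the penalised normal equations and solve densely
  mats <- fit$mats
  L <- frpmap:::.penalty_matrix(mats, as.list(lam))
  beta_o <- qr.solve(crossprod(mats$X) + L, crossprod(mats$X, mats$y))
  fitted_o <- as.vector(mats$X %*% beta_o)
  expect_lt(max(abs(fit$fitted_values - fitted_o)) /
              max(abs(fitted_o)), 1e-8)
})

test_that("GCV returns the grid argmin and reacts to noise structure", {
  grid <- 10^seq(-6, 8, by = 1)
  # argmin contract on one draw
  set.seed(14)
  n <- 60
  t <- seq(0, 1, length.out = n)
  d <- data.frame(t = t, y = sin(6 * t) + rnorm(n, 0, 0.3))
  des <- ssanova_design("t")
  sel <- gcv_select(d, "y", des, lambda_grid = grid)
  scores <- vapply(grid, function(l)
    fit_ssanova(d, "y", des, lambda = c(smooth = l))$gcv_score, numeric(1))
  expect_lte(sel$gcv, min(scores) + 1e-9)
  # GCV reacts to the noise structure: pure noise selects heavy smoothing
  # (occasional mild undersmoothing is a documented GCV property), a
  # noiseless smooth signal selects a tiny penalty, and the two separate by
  # orders of magnitude in every paired draw
  lam_noise <- lam_smooth <- numeric(25)
  for (i in 1:25) {
    set.seed(1000 + i)
    dn <- data.frame(t = t, y = rnorm(n))
    lam_noise[i] <- gcv_select(dn, "y", des, lambda_grid = grid,
                               refine = FALSE)$lambda[["smooth"]]
    ds <- data.frame(t = t, y = sin(6 * t) + rnorm(n, 0, 1e-4))
    lam_smooth[i] <- gcv_select(ds, "y", des, lambda_grid = grid,
                                refine = FALSE)$lambda[["smooth"]]
  }
  expect_gte(median(lam_noise), 1)
  expect_gte(mean(lam_smooth <= 1e-2), 0.9)
  expect_gte(mean(lam_noise / lam_smooth >= 1e2), 0.9)
})

test_that("row order of the input data does not change the fit", {
  d <- sim_grouped(4, seed = 15)
  des <- ssanova_design("tt", factors = "grp", subject = "sub")
  fit1 <- fit_ssanova(d, "y", des)
  set.seed(16)
  perm <- sample.int(nrow(d))
  fit2 <- fit_ssanova(d[perm, ], "y", des)
  expect_equal(unlist(fit2$smoothing_parameters),
               unlist(fit1$smoothing_parameters), tolerance = 1e-6)
  expect_equal(fit2$fitted_values, fit1$fitted_values[perm], tolerance = 1e-6)
  expect_equal(fit2$r_squared, fit1$r_squared, tolerance = 1e-8)
})

test_that("contrasts recover injected group differences; self-contrast is null", {
  d <- sim_grouped(8, seed = 17, delta = 5)
  des <- ssanova_design("tt", factors = "grp", subject = "sub")
  fit <- fit_ssanova(d, "y", des)
  ct <- contrast_difference(fit, "b", "a")
  expect_true(ct$mean_ci[1] < 5 && 5 < ct$mean_ci[2])
  expect_true(ct$significant)
  expect_true(all(ct$ci_lower <= ct$difference & ct$difference <= ct$ci_upper))
  ct0 <- contrast_difference(fit, "a", "a")
  expect_equal(max(abs(ct0$difference)), 0)
  expect_equal(ct0$mean_difference, 0)
  expect_false(ct0$significant)
  expect_error(contrast_difference(fit, "a", "zz"), "levels")
})

test_that("contrast intervals narrow as the group size doubles", {
  widths <- vapply(c(5, 10, 20), function(ng) {
    d <- sim_grouped(ng, seed = 18)
    fit <- fit_ssanova(d, "y",
                       ssanova_design("tt", factors = "grp", subject = "sub"))
    ct <- contrast_difference(fit, "b", "a")
    diff(ct$mean_ci)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("single-group smooth fits agree with an independent GAM fit", {
  skip_if_not_installed("mgcv")
  set.seed(19)
  n <- 120
  t <- seq(0, 1, length.out = n)
  f <- sin(2 * pi * t) + 0.5 * t
  d <- data.frame(t = t, y = f + rnorm(n, 0, 0.15))
  fit <- fit_ssanova(d, "y", ssanova_design("t"))
  gam_fit <- mgcv::gam(y ~ s(t, bs = "cr"), data = d)
  expect_lt(max(abs(fit$fitted_values - fitted(gam_fit))) / diff(range(f)),
            0.06)
})

test_that("degenerate designs raise errors", {
  d <- sim_grouped(3, seed = 20)
  expect_error(ssanova_design(c("a", "b", "c")), "one or two")
  expect_error(ssanova_design("t", kernel = "thin_plate"), "match")
  d1 <- d; d1$grp <- "a"
  expect_error(fit_ssanova(d1, "y", ssanova_design("tt", factors = "grp")),
               "single level")
  d2 <- d; d2$y[1] <- NA
  expect_error(fit_ssanova(d2, "y", ssanova_design("tt")), "missing")
})
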