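test_that("residual dimensions and degrees of freedom match the formulas", {
  expect_equal(residual_dim(16, 3), 32 + 120 * 4)
  expect_equal(residual_dim(20, 5), 80 + 190 * 16)
  expect_equal(m2_df(16, 3, 4, "bifactor"), 448)
  expect_equal(m2_df(16, 3, 4, "secondorder"), 460)
  ## the index tibble enumerates exactly s residuals
  expect_equal(nrow(bifcop:::residual_index(5, 3)), residual_dim(5, 3))
})

## small fitted fixture shared by the gof tests
gof_fixture <- local({
  m <- bifactor_model(4, K = 3, common_family = "gumbel",
                      group_family = "gumbel",
                      tau_theta = c(0.45, 0.5, 0.55, 0.5),
                      tau_delta = c(0.3, 0.3, 0.35, 0.35))
  y <- simulate_responses(m, 500, seed = 18)
  fit <- fit_factor_copula(y, 4, families = "gumbel", se = FALSE)
  list(m = m, y = y, fit = fit)
})

test_that("IFM step-1 makes the univariate residual block vanish", {
  res <- residual_vector(gof_fixture$fit)
  uni <- dplyr::filter(res, block == "uni")
  expect_lt(max(abs(uni$residual)), 1e-4)   # quadrature-level zero
  expect_equal(nrow(res), residual_dim(4, 3))
})

test_that("Delta2 has the expected structure and matches Richardson derivatives", {
  fit <- gof_fixture$fit
  D <- bifcop:::compute_delta2(fit)
  expect_equal(dim(D), c(residual_dim(4, 3), fit$q))
  K <- 3; d <- 4
  ## univariate rows: d pi_{j,y} / d a_{j,k} is the +/-1 difference pattern
  ## (pi_{j,1} = a_2 - a_1 so the derivative wrt a_1 is -1, wrt a_2 is +1)
  expect_equal(D[1, 1], -1, tolerance = 1e-3)   # item 1, cat 1 wrt a_{1,1}
  expect_equal(D[1, 2], 1, tolerance = 1e-3)    # item 1, cat 1 wrt a_{1,2}
  expect_equal(D[2, 2], -1, tolerance = 1e-3)   # item 1, cat 2 wrt a_{1,2}
  expect_equal(D[1, 3], 0, tolerance = 1e-3)    # other item's cutpoint
  ## univariate margins do not depend on the copula parameters
  expect_lt(max(abs(D[seq_len(d * (K - 1)), (d * (K - 1) + 1):fit$q])), 1e-6)

  ## Richardson-extrapolated oracle for a few copula-parameter columns
  skip_if_not_installed("numDeriv")
  m_hat <- fit$model
  n1 <- length(m_hat$par1)
  f <- function(p) {
    mm <- m_hat
    mm$par1 <- p[seq_len(n1)]
    mm$par2 <- p[-seq_len(n1)]
    bifcop:::model_pi2(mm, n_q = fit$n_q)
  }
  p_hat <- c(m_hat$par1, m_hat$par2)
  J <- numDeriv::jacobian(f, p_hat, method = "Richardson")
  cop_cols <- (d * (K - 1) + 1):fit$q
  expect_equal(D[, cop_cols], J[, fit$free], tolerance = 1e-5)
})

test_that("Delta2 columns vanish for copula parameters at independence", {
  m0 <- bifactor_model(c(2, 2), K = 2, theta = rep(0, 4), delta = rep(0, 4))
  y0 <- simulate_responses(m0, 300, seed = 19)
  f0 <- fit_factor_copula(y0, c(2, 2), se = FALSE)
  ## force the fitted parameters exactly to independence; the whole copula
  ## block of Delta2 then vanishes, so skip the rank check
  f0$model$par1[] <- 0; f0$model$par2[] <- 0
  D <- bifcop:::compute_delta2(f0, check_rank = FALSE)
  uni_rows <- seq_len(4)
  cop_cols <- 5:f0$q
  expect_lt(max(abs(D[uni_rows, cop_cols])), 1e-6)
})

test_that("Xi2 matches binomial variances, independence factorisation and MC", {
  fit <- gof_fixture$fit
  Xi <- bifcop:::compute_xi2(fit)
  res <- residual_vector(fit)
  expect_equal(Xi, t(Xi))
  expect_true(all(eigen(Xi, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  ## diagonal of the univariate block: pi (1 - pi)
  uni <- dplyr::filter(res, block == "uni")
  expect_equal(diag(Xi)[seq_len(nrow(uni))], uni$pi * (1 - uni$pi),
               tolerance = 1e-8)

  ## independence model: cross-item covariance of univariate blocks is zero
  m0 <- bifactor_model(c(2, 2), K = 2, theta = rep(0, 4), delta = rep(0, 4))
  y0 <- simulate_responses(m0, 200, seed = 20)
  f0 <- fit_factor_copula(y0, c(2, 2), se = FALSE)
  f0$model$par1[] <- 0; f0$model$par2[] <- 0
  Xi0 <- bifcop:::compute_xi2(f0)
  expect_lt(abs(Xi0[1, 2]), 1e-6)   # item 1 vs item 2 univariate entries
  expect_lt(abs(Xi0[1, 4]), 1e-6)

  ## Monte-Carlo oracle: covariance of the per-observation indicators
  m3 <- secondorder_model(c(2, 1), K = 2, group_family = "gumbel",
                          top_family = "bvn", tau_theta = c(0.4, 0.5, 0.45),
                          delta = 0.6)
  y3 <- simulate_responses(m3, 400, seed = 21)
  f3 <- suppressMessages(
    fit_factor_copula(y3, c(2, 1), model = "secondorder",
                      families = list(group = "gumbel", top = "bvn"),
                      se = FALSE))
  Xi3 <- bifcop:::compute_xi2(f3)
  big <- as.matrix(simulate_responses(f3$model, 200000, seed = 22))
  ind <- cbind(big == 1L,
               (big[, 1] == 1L) * (big[, 2] == 1L),
               (big[, 1] == 1L) * (big[, 3] == 1L),
               (big[, 2] == 1L) * (big[, 3] == 1L))
  emp <- cov(ind)
  expect_lt(max(abs(emp - Xi3)), 3 * 0.5 / sqrt(200000) * 3)
})

test_that("M2 is nonnegative, chi-square calibrated in form, and C2-invariant", {
  fit <- gof_fixture$fit
  m2 <- m2_test(fit)
  expect_gte(m2$statistic, 0)
  expect_equal(m2$df, m2$s - m2$q)
  expect_equal(m2$rmsea2,
               sqrt(max((m2$statistic - m2$df) / (fit$n * m2$df), 0)))

  ## orthogonal-complement form of C2 gives the same statistic
  res <- residual_vector(fit)
  r <- res$residual
  D <- bifcop:::compute_delta2(fit)
  Xi <- bifcop:::compute_xi2(fit)
  Dc <- qr.Q(qr(D), complete = TRUE)[, (fit$q + 1):length(r), drop = FALSE]
  M <- crossprod(Dc, Xi %*% Dc)
  m2_alt <- fit$n * drop(crossprod(crossprod(Dc, r), solve(M, crossprod(Dc, r))))
  expect_equal(m2$statistic, m2_alt, tolerance = 1e-8)
})

test_that("maximum discrepancies match a direct computation", {
  fit <- gof_fixture$fit
  disc <- max_discrepancy(fit)
  K <- 3; n <- fit$n
  ## brute-force check of one pair
  obs <- table(factor(fit$data[, 1], levels = 0:2),
               factor(fit$data[, 3], levels = 0:2)) / n
  mod <- model_margin(fit$model, c(1, 3), n_q = fit$n_q)
  D13 <- n * max(abs(obs - mod))
  expect_equal(disc$pairs$D[disc$pairs$j1 == 1 & disc$pairs$j2 == 3], D13,
               tolerance = 1e-10)
  ## summary scopes: per-group (within-group pairs) and all pairs
  expect_setequal(disc$summary$scope, c("group1", "all"))
  expect_equal(disc$summary$D[disc$summary$scope == "all"],
               mean(disc$pairs$D))

  ## a saturated-by-construction table: uniform binary data fits an
  ## independence model exactly, so discrepancies are quadrature-level zero
  y_perf <- as.matrix(expand.grid(0:1, 0:1))[rep(1:4, 25), ]
  colnames(y_perf) <- c("i1", "i2")
  m0 <- bifactor_model(c(1, 1), K = 2, theta = c(0, 0), delta = c(0, 0),
                       cutpoints = matrix(0.5, 1, 2))
  f0 <- suppressMessages(fit_factor_copula(y_perf, c(1, 1), se = FALSE))
  f0$model$par1[] <- 0; f0$model$par2[] <- 0
  d0 <- max_discrepancy(f0)
  expect_lt(max(d0$pairs$D), 0.01)
})
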