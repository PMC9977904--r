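test_that("copula cdfs reproduce closed-form and independence values", {
  expect_equal(pbicop(0.3, 0.7, bicop("gumbel", par = 1)), 0.21, tolerance = 1e-9)
  expect_equal(pbicop(0.5, 0.5, bicop("bvn", par = 0)), 0.25, tolerance = 1e-9)
  expect_equal(pbicop(0.5, 0.5, bicop("gumbel", par = 2)), 0.5^(2^(1 / 2)),
               tolerance = 1e-9)
  ## uniform margins: C(u, 1) = u, C(1, u) = u
  for (spec in list(bicop("bvn", par = 0.6), bicop("t3", par = -0.4),
                    bicop("sgumbel", par = 1.7))) {
    expect_equal(pbicop(0.37, 1, spec), 0.37, tolerance = 1e-6)
    expect_equal(pbicop(1, 0.81, spec), 0.81, tolerance = 1e-6)
  }
})

test_that("parameters outside the family domain are rejected", {
  expect_error(bicop("gumbel", par = 0.8), "domain")
  expect_error(bicop("bvn", par = 1.5), "domain")
  expect_error(bicop("t", par = 0.5), "nu")
  expect_error(tau_to_par("gumbel", -0.2), "range")
  expect_error(tau_to_par("gumbel_r1", 0.3), "range")
})

test_that("Frechet bounds hold across families and parameters", {
  set.seed(42)
  specs <- list(
    function() bicop("bvn", par = runif(1, -0.99, 0.99)),
    function() bicop("t", par = runif(1, -0.95, 0.95), nu = runif(1, 2, 10)),
    function() bicop("gumbel", par = runif(1, 1, 8)),
    function() bicop("sgumbel", par = runif(1, 1, 8)),
    function() bicop("gumbel_r1", par = runif(1, 1, 8)),
    function() bicop("gumbel_r2", par = runif(1, 1, 8)))
  for (mk in specs) {
    for (i in 1:170) {
      spec <- mk()
      u <- runif(2)
      C <- pbicop(u[1], u[2], spec)
      expect_gte(C, max(u[1] + u[2] - 1, 0) - 1e-7)
      expect_lte(C, min(u) + 1e-7)
    }
  }
})

test_that("conditional cdf matches a finite difference of the cdf", {
  specs <- list(bicop("bvn", par = 0.5), bicop("t5", par = 0.5),
                bicop("t5", par = -0.6), bicop("gumbel", par = 2.2),
                bicop("sgumbel", par = 1.6), bicop("gumbel_r1", par = 2),
                bicop("gumbel_r2", par = 1.4))
  grid <- expand.grid(u = c(0.15, 0.4, 0.75), v = c(0.2, 0.5, 0.85))
  h <- 1e-5
  for (spec in specs) {
    fd <- (pbicop(grid$u, grid$v + h, spec) - pbicop(grid$u, grid$v - h, spec)) /
      (2 * h)
    expect_equal(hbicop(grid$u, grid$v, spec), fd, tolerance = 1e-5)
  }
})

test_that("copula density matches a mixed finite difference of the cdf", {
  specs <- list(bicop("bvn", par = 0.5), bicop("t4", par = -0.4),
                bicop("gumbel", par = 2), bicop("sgumbel", par = 1.5))
  h <- 1e-4
  grid <- expand.grid(u = c(0.25, 0.5, 0.8), v = c(0.3, 0.6))
  for (spec in specs) {
    fd <- (pbicop(grid$u + h, grid$v + h, spec) -
             pbicop(grid$u - h, grid$v + h, spec) -
             pbicop(grid$u + h, grid$v - h, spec) +
             pbicop(grid$u - h, grid$v - h, spec)) / (4 * h^2)
    expect_equal(dbicop(grid$u, grid$v, spec), fd, tolerance = 1e-3)
  }
  ## closed-form check at the medians
  expect_equal(dbicop(0.5, 0.5, bicop("bvn", par = 0.5)), 1 / sqrt(0.75),
               tolerance = 1e-9)
  ## independence density is 1
  expect_equal(dbicop(c(0.2, 0.7), c(0.4, 0.9), bicop("bvn", par = 0)),
               c(1, 1), tolerance = 1e-12)
})

test_that("margin consistency: integrating the conditional cdf recovers u", {
  gl <- legendre_rule(200)
  for (spec in list(bicop("bvn", par = 0.7), bicop("t5", par = 0.6),
                    bicop("gumbel", par = 3), bicop("sgumbel", par = 2))) {
    for (u in c(0.2, 0.55, 0.9)) {
      val <- sum(gl$weights * hbicop(u, gl$nodes, spec))
      expect_equal(val, u, tolerance = 1e-6)
    }
  }
})

test_that("inverse conditional cdf inverts the conditional cdf", {
  specs <- list(bicop("bvn", par = 0.8), bicop("t3", par = 0.5),
                bicop("gumbel", par = 2.5), bicop("sgumbel", par = 1.8),
                bicop("gumbel_r1", par = 2), bicop("gumbel_r2", par = 3))
  for (spec in specs) {
    expect_equal(hinv_bicop(hbicop(0.37, 0.7, spec), 0.7, spec), 0.37,
                 tolerance = 1e-8)
    p <- hbicop(0.42, 0.15, spec)
    expect_equal(hbicop(hinv_bicop(p, 0.15, spec), 0.15, spec), p,
                 tolerance = 1e-8)
  }
  ## BVN conditional median is Phi(rho * qnorm(v))
  expect_equal(hinv_bicop(0.5, 0.5, bicop("bvn", par = 0.8)), 0.5,
               tolerance = 1e-10)
  ## independence: identity in p
  expect_equal(hinv_bicop(0.42, 0.7, bicop("gumbel", par = 1)), 0.42,
               tolerance = 1e-8)
})

test_that("Kendall's tau conversions are mutually inverse and match theory", {
  expect_equal(tau_to_par("bvn", 1 / 3), sin(pi / 6), tolerance = 1e-12)
  expect_equal(tau_to_par("gumbel", 0.5), 2, tolerance = 1e-12)
  expect_equal(par_to_tau(bicop("gumbel_r1", par = 2)), -0.5, tolerance = 1e-12)
  for (fam in c("bvn", "t3", "gumbel", "sgumbel", "gumbel_r1", "gumbel_r2")) {
    tau <- if (grepl("r[12]$", fam)) -0.37 else
      if (fam %in% c("gumbel", "sgumbel")) 0.37 else 0.37
    spec <- bicop(fam, tau = tau)
    expect_equal(par_to_tau(spec), tau, tolerance = 1e-12)
  }
})

test_that("parametric tau agrees with a Monte-Carlo sample tau", {
  set.seed(7)
  n <- 10000
  mc_se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  cases <- list(bicop("bvn", tau = 0.4), bicop("t5", tau = -0.3),
                bicop("gumbel", tau = 0.5), bicop("sgumbel", tau = 0.25),
                bicop("gumbel_r1", tau = -0.4), bicop("gumbel_r2", tau = -0.2))
  for (spec in cases) {
    uv <- r_bicop(n, spec)
    tau_hat <- stats::cor(uv[, 1], uv[, 2], method = "kendall")
    expect_lt(abs(tau_hat - par_to_tau(spec)), 3 * mc_se)
  }
})

test_that("reflections satisfy their distributional identities", {
  g <- bicop("gumbel", par = 2.5)
  grid <- expand.grid(u = c(0.2, 0.5, 0.8), v = c(0.3, 0.6, 0.9))
  ## survival: Chat(u1,u2) = u1 + u2 - 1 + C(1-u1, 1-u2)
  sg <- reflect_bicop(g, "survival")
  expect_identical(sg$family, "sgumbel")
  expect_equal(pbicop(grid$u, grid$v, sg),
               grid$u + grid$v - 1 + pbicop(1 - grid$u, 1 - grid$v, g),
               tolerance = 1e-12)
  ## 1-reflection: Chat1(u1,u2) = u2 - C(1-u1, u2)
  r1 <- reflect_bicop(g, "reflect1")
  expect_equal(pbicop(grid$u, grid$v, r1),
               grid$v - pbicop(1 - grid$u, grid$v, g), tolerance = 1e-12)
  ## 2-reflection: Chat2(u1,u2) = u1 - C(u1, 1-u2)
  r2 <- reflect_bicop(g, "reflect2")
  expect_equal(pbicop(grid$u, grid$v, r2),
               grid$u - pbicop(grid$u, 1 - grid$v, g), tolerance = 1e-12)
  ## involution and symmetry properties
  expect_identical(reflect_bicop(sg, "survival")$family, "gumbel")
  expect_identical(reflect_bicop(bicop("bvn", par = 0.4), "survival")$par, 0.4)
  expect_lt(par_to_tau(r1), 0)
  ## density reflection: sgumbel density at (u1,u2) = gumbel density at (1-u1,1-u2)
  expect_equal(dbicop(grid$u, grid$v, sg),
               dbicop(1 - grid$u, 1 - grid$v, g), tolerance = 1e-12)
})

test_that("t copulas accept non-integer degrees of freedom", {
  spec <- bicop("t", par = 0.5, nu = 3.7)
  h <- 1e-5
  fd <- unname((pbicop(0.3, 0.6 + h, spec) - pbicop(0.3, 0.6 - h, spec)) / (2 * h))
  expect_equal(hbicop(0.3, 0.6, spec), fd, tolerance = 1e-5)
  expect_equal(hinv_bicop(hbicop(0.3, 0.6, spec), 0.6, spec), 0.3,
               tolerance = 1e-8)
})
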