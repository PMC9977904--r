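test_that("quadrature rule and structures validate", {
  rule <- legendre_rule(25)
  expect_equal(sum(rule$weights), 1, tolerance = 1e-12)
  expect_true(all(diff(rule$nodes) > 0))
  expect_error(group_structure(c(2, 2), K = 1), "K")
  s <- group_structure(c("a", "a", "b"), K = 3)
  expect_equal(s$sizes, c(2L, 1L))
  expect_error(group_structure(c("a", "b", "a"), K = 3), "contiguous")
  expect_error(cutpoint_set(c(0.6, 0.4), group_structure(2, K = 3)),
               "increasing")
})

test_that("full independence factors the pmf into cutpoint gaps", {
  m <- bifactor_model(c(2, 2), K = 3, theta = rep(0, 4), delta = rep(0, 4),
                      cutpoints = matrix(c(0.2, 0.5), 2, 4))
  y <- c(0, 1, 2, 1)
  gaps <- c(0.2, 0.3, 0.5)
  expect_equal(model_pmf(m, y), prod(gaps[y + 1]), tolerance = 1e-9)
  ## second-order at independence everywhere
  m2 <- secondorder_model(c(2, 2), K = 3, theta = rep(0, 4), delta = rep(0, 2),
                          cutpoints = matrix(c(0.2, 0.5), 2, 4))
  expect_equal(model_pmf(m2, y), prod(gaps[y + 1]), tolerance = 1e-9)
})

test_that("joint pmfs normalise to one for mixed family models", {
  cells <- all_outcomes(4, 2)
  mixes <- list(
    bifactor_model(c(2, 2), K = 2, common_family = "gumbel",
                   group_family = c("sgumbel", "t3"),
                   tau_theta = c(0.4, 0.5, 0.6, 0.3),
                   tau_delta = c(0.3, 0.2, 0.4, 0.35)),
    bifactor_model(c(2, 2), K = 2, common_family = "t2", group_family = "bvn",
                   tau_theta = 0.5, tau_delta = c(0.2, 0.3, 0.1, 0.4)),
    secondorder_model(c(2, 2), K = 2, group_family = "gumbel",
                      top_family = "t5", tau_theta = c(0.4, 0.5, 0.6, 0.3),
                      tau_delta = c(0.3, 0.45)),
    secondorder_model(c(2, 2), K = 2, group_family = c("sgumbel", "bvn"),
                      top_family = "gumbel", tau_theta = 0.45,
                      tau_delta = c(0.25, 0.4)))
  for (m in mixes) {
    expect_equal(sum(model_pmf(m, cells)), 1, tolerance = 1e-8)
  }
  ## d = 5, K = 3, unbalanced groups
  m5 <- bifactor_model(c(3, 2), K = 3, common_family = "gumbel",
                       group_family = "gumbel", tau_theta = 0.5,
                       tau_delta = 0.3)
  expect_equal(sum(model_pmf(m5, all_outcomes(5, 3))), 1, tolerance = 1e-8)
})

test_that("all-BVN models equal the discretised-MVN models", {
  th <- c(0.6, 0.5, 0.7, 0.4); dl <- c(0.3, 0.3, 0.4, 0.4)
  grp <- c(1, 1, 2, 2)
  m <- bifactor_model(c(2, 2), K = 3, theta = th, delta = dl)
  cells <- all_outcomes(4, 3)
  oracle <- suppressWarnings(mvn_rectangle_oracle(cells, qnorm(unclass(m$cut)),
                                                  bifactor_corr(th, dl, grp)))
  expect_lt(max(abs(model_pmf(m, cells, n_q = 80) - oracle)), 1e-5)

  ## second-order: theta_jg = beta_jg * beta_g, gamma_jg = beta_jg sqrt(1-beta_g^2)
  bj <- c(0.8, 0.7, 0.6, 0.75); bg <- c(0.75, 0.6)
  m2 <- secondorder_model(c(2, 2), K = 3, theta = bj, delta = bg)
  R2 <- bifactor_corr(bj * bg[grp], bj * sqrt(1 - bg[grp]^2) /
                        sqrt(1 - (bj * bg[grp])^2), grp)
  oracle2 <- suppressWarnings(mvn_rectangle_oracle(cells, qnorm(unclass(m2$cut)), R2))
  expect_lt(max(abs(model_pmf(m2, cells, n_q = 80) - oracle2)), 1e-5)
})

test_that("with one group the models reduce to one/two-factor copula models", {
  acut <- matrix(c(0.3, 0.7), 2, 3)
  struct <- group_structure(3, K = 3)
  specs1 <- list(bicop("gumbel", par = 2), bicop("gumbel", par = 1.5),
                 bicop("gumbel", par = 3))
  specs2 <- list(bicop("t4", par = 0.5), bicop("t4", par = 0.3),
                 bicop("t4", par = 0.6))
  mb <- bifactor_model(struct, common_family = "gumbel", group_family = "t4",
                       theta = c(2, 1.5, 3), delta = c(0.5, 0.3, 0.6),
                       cutpoints = acut)
  ms <- secondorder_model(struct, group_family = "gumbel", top_family = "t4",
                          theta = c(2, 1.5, 3), delta = 0.5, cutpoints = acut)
  for (y in list(c(0, 1, 2), c(2, 2, 0), c(1, 1, 1))) {
    expect_equal(model_pmf(mb, y, n_q = 35),
                 twofactor_pmf_oracle(y, acut, specs1, specs2), tolerance = 1e-7)
    ## the second-order model integrates out V0 exactly: one-factor model
    ## (dependent-node quadrature differs from direct integration by O(1e-6))
    expect_equal(model_pmf(ms, y, n_q = 35),
                 onefactor_pmf_oracle(y, acut, specs1), tolerance = 1e-4)
  }
})

test_that("second-order groups decouple when the top copulas are independent", {
  m <- secondorder_model(c(2, 2), K = 2, group_family = "gumbel",
                         top_family = "bvn", tau_theta = c(0.4, 0.5, 0.6, 0.3),
                         delta = c(0, 0))
  cells <- all_outcomes(4, 2)
  p <- model_pmf(m, cells, n_q = 35)
  ## product of the two groups' one-factor pmfs
  acut <- unclass(m$cut)
  s1 <- lapply(1:2, function(j) bicop("gumbel", tau = c(0.4, 0.5)[j]))
  s2 <- lapply(3:4, function(j) bicop("gumbel", tau = c(0.6, 0.3)[j - 2]))
  for (r in seq_len(nrow(cells))) {
    p1 <- onefactor_pmf_oracle(cells[r, 1:2], acut[, 1:2, drop = FALSE], s1)
    p2 <- onefactor_pmf_oracle(cells[r, 3:4], acut[, 3:4, drop = FALSE], s2)
    expect_equal(p[r], p1 * p2, tolerance = 1e-7)
  }
})

test_that("marginal probabilities agree with brute-force marginalisation", {
  m <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
                      group_family = c("sgumbel", "t3"),
                      tau_theta = c(0.4, 0.5, 0.6, 0.3),
                      tau_delta = c(0.3, 0.2, 0.4, 0.35))
  cells <- all_outcomes(4, 3)
  p <- model_pmf(m, cells)
  mg <- model_margin(m, c(1, 3))
  brute <- matrix(0, 3, 3)
  for (y1 in 0:2) for (y3 in 0:2) {
    brute[y1 + 1, y3 + 1] <- sum(p[cells[, 1] == y1 & cells[, 3] == y3])
  }
  expect_lt(max(abs(mg - brute)), 1e-8)
  ## permuted item order permutes the table
  expect_lt(max(abs(model_margin(m, c(3, 1)) - t(brute))), 1e-8)
  ## univariate margins are the cutpoint gaps for any parameters
  expect_lt(max(abs(model_margin(m, 2) - rep(1 / 3, 3))), 2e-4)
  ## bivariate margin sums to one
  expect_equal(sum(mg), 1, tolerance = 1e-6)
  ## subset margin equals summed superset margin
  m123 <- model_margin(m, c(1, 2, 3))
  expect_lt(max(abs(apply(m123, c(1, 3), sum) - mg)), 1e-10)
  expect_error(model_margin(m, c(1, 1)), "distinct")
})

test_that("log-likelihood is additive and matches per-row pmf summation", {
  m <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
                      group_family = "gumbel", tau_theta = 0.5, tau_delta = 0.3)
  y <- as.matrix(simulate_responses(m, 20, seed = 9))
  ll1 <- model_loglik(m, y)
  slow <- sum(sapply(seq_len(nrow(y)), function(i) log(model_pmf(m, y[i, ]))))
  expect_equal(ll1, slow, tolerance = 1e-8)
  expect_equal(model_loglik(m, rbind(y, y)), 2 * ll1, tolerance = 1e-8)
  ## independence model: multinomial log-likelihood of the margins
  m0 <- bifactor_model(c(2, 2), K = 3, theta = rep(0, 4), delta = rep(0, 4))
  ll0 <- model_loglik(m0, y)
  gaps <- rep(1 / 3, 3)
  expect_equal(ll0, sum(log(gaps[y + 1])), tolerance = 1e-6)
})

test_that("pmf is stable between 25 and 50 quadrature points", {
  m <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
                      group_family = "t5", tau_theta = c(0.4, 0.5, 0.6, 0.3),
                      tau_delta = 0.3)
  set.seed(3)
  y <- all_outcomes(4, 3)[sample(81, 12), ]
  expect_lt(max(abs(model_pmf(m, y, n_q = 25) - model_pmf(m, y, n_q = 50))),
            1e-4)
})

test_that("gaussian_loadings implements the loading identities", {
  m <- bifactor_model(c(2, 2), K = 3, theta = rep(0.6, 4),
                      delta = c(0.5, 0, 0.5, 0))
  gl <- gaussian_loadings(m)
  expect_equal(gl$gamma, c(0.4, 0, 0.4, 0), tolerance = 1e-12)
  ms <- secondorder_model(c(2, 2), K = 3, theta = rep(0.8, 4),
                          delta = c(0.75, 0.75))
  gs <- gaussian_loadings(ms)
  expect_equal(gs$theta, rep(0.6, 4), tolerance = 1e-12)
  expect_equal(gs$gamma, rep(0.8 * sqrt(1 - 0.5625), 4), tolerance = 1e-12)
  mg <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
                       group_family = "gumbel", tau_theta = 0.5,
                       tau_delta = 0.3)
  expect_error(gaussian_loadings(mg), "BVN")
})
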