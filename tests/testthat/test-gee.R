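test_that("independence working correlation reproduces the GLM exactly", {
  for (fam in c("gaussian", "binomial", "poisson")) {
    sim <- sim_count_grid(n_side = 10, family = fam, seed = 3)
    m <- gee(count ~ pollution + exposure, fam, sim$data, sim$coords,
             corstr = "independence", compute_ac = FALSE)
    g <- glm(count ~ pollution + exposure,
             family = get(fam, mode = "function")(), data = sim$data)
    expect_equal(unname(coef(m)), unname(coef(g)), tolerance = 1e-8)
    expect_equal(unname(m$se), unname(summary(g)$coefficients[, 2]),
                 tolerance = 1e-8)
  }
})

test_that("a forced power base of zero reduces the fixed structure to a GLM", {
  sim <- sim_count_grid(n_side = 10, seed = 4, confounder_strength = 0.7)
  m <- gee(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
           corstr = "fixed", fixed_a = 0, compute_ac = FALSE)
  g <- glm(count ~ pollution + exposure, poisson, sim$data)
  expect_equal(unname(coef(m)), unname(coef(g)), tolerance = 1e-6)
})

test_that("gaussian estimates with a frozen correlation match closed-form GLS", {
  sim <- sim_count_grid(n_side = 10, family = "gaussian", seed = 5,
                        confounder_strength = 0.5)
  a <- 0.45
  m <- gee(count ~ pollution + exposure, "gaussian", sim$data, sim$coords,
           corstr = "fixed", fixed_a = a, compute_ac = FALSE)
  D <- as.matrix(dist(sim$coords))
  Ri <- solve(a^D)
  X <- model.matrix(~ pollution + exposure, sim$data)
  y <- sim$data$count
  b_gls <- solve(t(X) %*% Ri %*% X, t(X) %*% Ri %*% y)
  expect_equal(unname(coef(m)), unname(drop(b_gls)), tolerance = 1e-8)
})

test_that("normalised residuals are whitened under the true correlation", {
  set.seed(6)
  n_side <- 10; n <- n_side^2
  co <- full_grid(n_side)
  a <- 0.5
  L <- t(chol(a^as.matrix(dist(co))))
  x <- rnorm(n)
  i1 <- replicate(100, {
    y <- 1 + 0.5 * x + drop(L %*% rnorm(n))
    m <- gee(y ~ x, "gaussian", data.frame(y = y, x = x), co,
             corstr = "fixed", fixed_a = a, compute_ac = FALSE)
    moran_lag1(co, m$residuals$normalized)
  })
  se <- sd(i1) / sqrt(length(i1))
  expect_lt(abs(mean(i1) - (-1 / (n - 1))), 3 * se + 0.01)
})

test_that("independence sandwich equals the HC0 robust-covariance oracle", {
  set.seed(7)
  n <- 80
  x <- rnorm(n)
  y <- 1 + x + rnorm(n) * (1 + abs(x))  # heteroscedastic
  co <- ragged_grid(10, n, seed = 7)
  m <- gee(y ~ x, "gaussian", data.frame(y = y, x = x), co,
           corstr = "independence", compute_ac = FALSE)
  X <- model.matrix(~ x)
  r <- y - fitted(lm(y ~ x))
  hc0 <- solve(crossprod(X)) %*% crossprod(X * r) %*% solve(crossprod(X))
  expect_equal(unname(m$vcov_robust), unname(hc0), tolerance = 1e-8)
})

test_that("clustered structures estimate within-block correlation", {
  sim <- sim_count_grid(n_side = 15, seed = 8, confounder_strength = 0.5)
  me <- gee(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
            corstr = "exchangeable", cluster = 3, compute_ac = FALSE)
  expect_gt(me$corpars$alphas[["alpha"]], 0)
  expect_true(all(is.finite(coef(me))))
  mq <- gee(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
            corstr = "quadratic", cluster = 3, compute_ac = FALSE)
  al <- mq$corpars$alphas
  expect_true(length(al) > 2)          # one parameter per within-tile distance
  expect_gt(al[[1]], al[[length(al)]]) # nearest distance most correlated
  # 15 is not a multiple of 3 on purpose: trailing tiles form smaller blocks
  expect_equal(length(mq$residuals$normalized), nrow(sim$data))
})

test_that("the fixed structure adapts its power base to the residual correlogram", {
  sim <- sim_count_grid(n_side = 20, seed = 9, confounder_strength = 1)
  m <- gee(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
           corstr = "fixed")
  expect_gt(m$corpars$a, 0)
  expect_lt(m$corpars$a, 0.99)
  # the working correlation reduces the lag-1 autocorrelation of the
  # normalised residuals below the GLM's
  expect_lt(abs(moran_lag1(sim$coords, m$residuals$normalized)),
            abs(moran_lag1(sim$coords, m$glm_fit$residuals$pearson)))
})

test_that("prediction and summary methods behave", {
  sim <- sim_count_grid(n_side = 10, seed = 10)
  m <- gee(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
           corstr = "fixed", compute_ac = FALSE)
  expect_equal(predict(m, sim$data), m$fitted, tolerance = 1e-12)
  expect_error(predict(m, sim$data[, "count", drop = FALSE]), "missing")
  m0 <- gee(count ~ 1, "poisson", sim$data, sim$coords,
            corstr = "independence", compute_ac = FALSE)
  expect_equal(length(unique(round(predict(m0, sim$data), 12))), 1L)
  expect_output(print(summary(m, printAutoCorPars = TRUE)), "correlation")
  expect_output(print(summary(m0)), "QIC")
})
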