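test_that("gaussian WRM slopes equal OLS on the filtered quantities", {
  set.seed(4)
  sim <- sim_count_grid(n_side = 12, family = "gaussian", seed = 4)
  d <- sim$data; co <- sim$coords
  m <- wrm(count ~ pollution + exposure, "gaussian", d, co, level = 1,
           compute_ac = FALSE)
  yf <- filter_highpass(d$count, co, 1)
  x1f <- filter_highpass(d$pollution, co, 1)
  x2f <- filter_highpass(d$exposure, co, 1)
  ols <- coef(lm(yf ~ x1f + x2f))
  expect_equal(unname(coef(m)[2:3]), unname(ols[2:3]), tolerance = 1e-10)
  # intercept is re-anchored to the data's mean level
  expect_equal(coef(m)[["(Intercept)"]],
               mean(d$count - cbind(d$pollution, d$exposure) %*% ols[2:3]),
               tolerance = 1e-10)
})

test_that("level shifts in the response move only the intercept", {
  set.seed(5)
  sim <- sim_count_grid(n_side = 12, family = "gaussian", seed = 5)
  d <- sim$data; co <- sim$coords
  m1 <- wrm(count ~ pollution + exposure, "gaussian", d, co,
            compute_ac = FALSE)
  d2 <- d; d2$count <- d2$count + 10
  m2 <- wrm(count ~ pollution + exposure, "gaussian", d2, co,
            compute_ac = FALSE)
  expect_equal(coef(m1)[2:3], coef(m2)[2:3], tolerance = 1e-8)
  expect_equal(coef(m2)[[1]] - coef(m1)[[1]], 10, tolerance = 1e-8)
})

test_that("WRM at level 1 equals the scale-1 detail multiresolution fit", {
  sim <- sim_count_grid(n_side = 16, seed = 5, confounder_strength = 0.5)
  for (fam in c("poisson", "gaussian")) {
    a <- wrm(count ~ pollution + exposure, fam, sim$data, sim$coords,
             level = 1, compute_ac = FALSE)
    b <- scale_wmrr(count ~ pollution + exposure, fam, sim$data, sim$coords,
                    scale = 1, detail = TRUE, compute_ac = FALSE)
    expect_equal(coef(a), coef(b), tolerance = 1e-8)
    expect_equal(a$fitted, b$fitted, tolerance = 1e-8)
  }
})

test_that("a response living purely at level-2 detail is recovered at scale 2", {
  set.seed(6)
  co <- full_grid(16)
  x <- rnorm(256)
  x2d <- extract_component(x, co, scale = 2, detail = TRUE)
  d <- data.frame(y = 5 + 2 * x2d, x = x)
  m2 <- scale_wmrr(y ~ x, "gaussian", d, co, scale = 2, compute_ac = FALSE)
  expect_equal(coef(m2)[["x"]], 2, tolerance = 1e-6)
  m3 <- scale_wmrr(y ~ x, "gaussian", d, co, scale = 3, compute_ac = FALSE)
  expect_lt(abs(coef(m3)[["x"]]), 1e-6)
})

test_that("regressing smooths on smooths at full depth degenerates cleanly", {
  co <- full_grid(8)
  set.seed(7)
  d <- data.frame(y = rnorm(64), x = rnorm(64))
  expect_error(scale_wmrr(y ~ x, "gaussian", d, co, scale = 3,
                          detail = FALSE, compute_ac = FALSE),
               "rank deficient")
})

test_that("level-1 filtering removes the residual autocorrelation a GLM keeps", {
  hits <- 0L; tried <- 0L
  for (s in 1:10) {
    sim <- sim_count_grid(n_side = 20, confounder_strength = 1, seed = s)
    g <- glm_lattice(count ~ pollution + exposure, "poisson", sim$data,
                     coord = sim$coords)
    i_glm <- moran_lag1(sim$coords, g$residuals$pearson)
    if (i_glm < 0.15) next
    tried <- tried + 1L
    m <- wrm(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
             level = 1, compute_ac = FALSE)
    w <- m$residuals$whitened
    i_wrm <- moran_lag1(w$coord, w$values)
    if (abs(i_wrm) < abs(i_glm)) hits <- hits + 1L
  }
  expect_gt(tried, 2L)
  expect_equal(hits, tried)
})

test_that("predictions are coefficient-based and need all model columns", {
  sim <- sim_count_grid(n_side = 12, seed = 8)
  m <- wrm(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
           compute_ac = FALSE)
  expect_equal(predict(m, sim$data), m$fitted, tolerance = 1e-12)
  expect_error(predict(m, sim$data[, c("count", "pollution")]), "exposure")
  # intercept-only model predicts a constant
  m0 <- wrm(count ~ 1, "poisson", sim$data, sim$coords, compute_ac = FALSE)
  expect_equal(length(unique(round(predict(m0, sim$data), 12))), 1L)
})

test_that("summaries render the three display cases", {
  sim <- sim_count_grid(n_side = 12, seed = 9)
  m0 <- wrm(count ~ 1, "poisson", sim$data, sim$coords, compute_ac = FALSE)
  expect_output(print(summary(m0)), "Intercept")
  m2 <- wrm(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
            compute_ac = FALSE)
  expect_output(print(summary(m2)), "AICc")
  m2$converged <- FALSE
  expect_output(print(summary(m2)), "NOT converge")
})

test_that("filtered rank deficiency is reported with column names", {
  sim <- sim_count_grid(n_side = 12, seed = 10)
  d <- sim$data
  d$dup <- d$pollution
  expect_error(wrm(count ~ pollution + dup, "poisson", d, sim$coords,
                   compute_ac = FALSE), "dup")
})

test_that("whitened wavelet residuals are white under a correct model", {
  set.seed(55)
  i1 <- replicate(40, {
    n <- 256; co <- full_grid(16)
    d <- data.frame(y = rnorm(n), x = rnorm(n))
    m <- wrm(y ~ x, "gaussian", d, co, level = 1, compute_ac = FALSE)
    w <- m$residuals$whitened
    moran_lag1(w$coord, w$values)
  })
  m1 <- 3 * 64  # level-1 detail coefficients on a 16x16 grid
  se <- sd(i1) / sqrt(length(i1))
  expect_lt(abs(mean(i1) - (-1 / (m1 - 1))), 3 * se + 0.01)
})
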