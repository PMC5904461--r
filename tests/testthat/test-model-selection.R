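make_selection_fixture <- function(seed = 1, n_side = 8) {
  set.seed(seed)
  n <- n_side^2
  co <- full_grid(n_side)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 1 + 2 * x1 + rnorm(n)            # only x1 matters
  list(data = data.frame(y = y, x1 = x1, x2 = x2, x3 = x3), coords = co)
}

test_that("backward selection keeps the true predictor and drops noise", {
  dropped_noise <- 0L
  for (s in 1:10) {
    fx <- make_selection_fixture(s)
    m <- gee(y ~ x1 + x2, "gaussian", fx$data, fx$coords,
             corstr = "independence", compute_ac = FALSE)
    st <- step_spatial(m, fx$data)
    kept <- attr(terms(st$model), "term.labels")
    expect_true("x1" %in% kept)          # the strong effect always stays
    if (!"x2" %in% kept) dropped_noise <- dropped_noise + 1L
    # criterion never increases along the step log
    expect_true(all(diff(st$steps$criterion) <= 0))
  }
  # a pure-noise term survives only when its chance fit beats the
  # complexity penalty, which should be the minority of seeds
  expect_gte(dropped_noise, 6L)
})

test_that("main effects are never removed while their polynomial remains", {
  fx <- make_selection_fixture(2)
  d <- fx$data
  m <- gee(y ~ x2 + I(x2^2) + x3, "gaussian", d, fx$coords,
           corstr = "independence", compute_ac = FALSE)
  st <- step_spatial(m, d)
  # replay every deletion against the hierarchy rule: x2 may only
  # disappear after I(x2^2) has
  deleted <- st$steps$deleted[-1]
  labels <- c("x2", "I(x2^2)", "x3")
  violations <- 0L
  for (tm in deleted) {
    if (!tm %in% removable_set(labels)) violations <- violations + 1L
    labels <- setdiff(labels, tm)
  }
  expect_equal(violations, 0L)
  # and the full model is always logged as step 0
  expect_equal(st$steps$deleted[1], "<full>")
})

test_that("selection stops cleanly when no deletion improves the criterion", {
  fx <- make_selection_fixture(3)
  d <- fx$data
  d$y <- 1 + 2 * d$x1 + 1.5 * d$x2 + rnorm(nrow(d), sd = 0.2)
  m <- gee(y ~ x1 + x2, "gaussian", d, fx$coords,
           corstr = "independence", compute_ac = FALSE)
  st <- step_spatial(m, d)
  expect_equal(deparse(st$model[[3]]), deparse(m$formula[[3]]))
  expect_equal(nrow(st$steps), 1L)
})

test_that("hierarchy is respected across randomized formula runs", {
  set.seed(42)
  violations <- 0L
  for (r in 1:60) {
    n <- 49
    co <- full_grid(7)
    d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    forms <- list(y ~ a + b + a:b, y ~ a + I(a^2) + b,
                  y ~ a + b + c + a:c + I(b^2))
    f <- forms[[sample(3, 1)]]
    m <- suppressWarnings(gee(f, "gaussian", d, co,
                              corstr = "independence", compute_ac = FALSE))
    st <- step_spatial(m, d)
    # replay the deletions and check each was removable at its turn
    labels <- attr(terms(f), "term.labels")
    for (tm in st$steps$deleted[-1]) {
      if (!tm %in% removable_set(labels)) violations <- violations + 1L
      labels <- setdiff(labels, tm)
    }
  }
  expect_equal(violations, 0L)
})

test_that("all-subsets tables enumerate 2^p models with unit weight mass", {
  fx <- make_selection_fixture(5)
  m <- gee(y ~ x1 + x2 + x3, "gaussian", fx$data, fx$coords,
           corstr = "independence", compute_ac = FALSE)
  tab <- mmi_gee(m, fx$data)
  expect_equal(nrow(tab), 8L)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta[1], 0)
  expect_true("x1" %in% tab$terms[[1]])
  # p = 1: two rows, the strong predictor dominates the null model
  m1 <- gee(y ~ x1, "gaussian", fx$data, fx$coords,
            corstr = "independence", compute_ac = FALSE)
  t1 <- mmi_gee(m1, fx$data)
  expect_equal(nrow(t1), 2L)
  expect_gt(t1$weight[1], t1$weight[2])
  expect_equal(t1$model[1], "x1")
})

test_that("wavelet-model tables support AICc and the guard on many terms", {
  sim <- sim_count_grid(n_side = 12, seed = 6)
  m <- wrm(count ~ pollution + exposure, "poisson", sim$data, sim$coords,
           compute_ac = FALSE)
  tab <- mmi_wmrr(m, sim$data, scale = 1, detail = TRUE, AICc = TRUE)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_identical(attr(tab, "criterion_name"), "AICc")
  big <- reformulate(paste0("x", 1:13), response = "count")
  m$formula <- big
  expect_error(spatglm:::mmi_core(m, sim$data), "12")
})

test_that("relative importance lies in [0,1] and exposes pure noise", {
  set.seed(9)
  n <- 256
  co <- full_grid(16)
  x1 <- rnorm(n); noise <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.8 * x1))
  d <- data.frame(y = y, x1 = x1, noise = noise)
  r <- rvi(y ~ x1 + noise, "poisson", d, co, maxlevel = 3)
  expect_true(all(r$rvi >= 0 & r$rvi <= 1))
  expect_true(all(r$rvi["noise", ] < 0.5))
  expect_true(all(r$rvi["x1", ] > 0.5))
  expect_length(r$tables, 3L)
})
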