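test_that("neighbourhood smoothing counts presences correctly", {
  co <- full_grid(5)
  a <- rep(0, 25); a[13] <- 1             # centre cell (3,3)
  s <- smooth_actuals(a, co)
  expect_equal(s[13], 1 / 9)              # isolated presence
  expect_equal(smooth_actuals(rep(1, 25), co), rep(1, 25))
  # 2x2 grid: every cell sees all four cells
  co2 <- full_grid(2)
  expect_equal(smooth_actuals(c(1, 0, 0, 0), co2), rep(0.25, 4))
})

test_that("classical kappa and AUC match textbook oracles", {
  set.seed(31)
  for (i in 1:20) {
    n <- 80
    a <- rbinom(n, 1, 0.4)
    if (length(unique(a)) < 2) next
    p <- round(runif(n), 2)               # ties on purpose
    co <- ragged_grid(10, n, seed = i)
    td <- th_dep(a, p, co, threshold = 0.5, spatial = FALSE)
    expect_equal(td$kappa, kappa_oracle(a, p, 0.5), tolerance = 1e-10)
    ti <- th_indep(a, p, co, spatial = FALSE)
    expect_equal(ti$AUC, auc_oracle(a, p), tolerance = 1e-10)
  }
})

test_that("classical AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  a <- rbinom(120, 1, 0.35); p <- runif(120)
  co <- ragged_grid(12, 120, seed = 8)
  ours <- th_indep(a, p, co, spatial = FALSE)$AUC
  ref <- as.numeric(pROC::auc(pROC::roc(a, p, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("perfect predictions score perfectly under both modes", {
  h <- sim_presence_preds(n_side = 12, seed = 3)
  a <- h$data$actuals; co <- h$coords
  p <- pmin(pmax(a, 0.01), 0.99)
  for (sp in c(TRUE, FALSE)) {
    td <- th_dep(a, p, co, spatial = sp)
    expect_equal(td$kappa, 1)
    expect_equal(td$sensitivity, 1)
    expect_equal(td$specificity, 1)
    ti <- th_indep(a, p, co, spatial = sp)
    expect_equal(ti$AUC, 1)
    expect_equal(ti$TSS, 1)
  }
})

test_that("shuffled predictions give chance-level classical kappa", {
  set.seed(12)
  co <- full_grid(20)
  kap <- replicate(100, {
    a <- rbinom(400, 1, 0.3)
    th_dep(a, sample(a), co, spatial = FALSE)$kappa
  })
  se <- sd(kap) / sqrt(length(kap))
  expect_lt(abs(mean(kap)), 3 * se + 0.005)
})

test_that("near-miss predictions beat their classical scores spatially", {
  for (s in 1:5) {
    h <- sim_presence_preds(n_side = 20, shift_cells = 1, seed = s)
    d <- h$data; co <- h$coords
    expect_gt(th_indep(d$actuals, d$predictions, co, spatial = TRUE)$AUC,
              th_indep(d$actuals, d$predictions, co, spatial = FALSE)$AUC)
    expect_gt(th_dep(d$actuals, d$predictions, co, spatial = TRUE)$kappa,
              th_dep(d$actuals, d$predictions, co, spatial = FALSE)$kappa)
  }
})

test_that("spatial metrics are invariant to translation and rotation", {
  h <- sim_presence_preds(n_side = 12, shift_cells = 1, seed = 6)
  d <- h$data; co <- h$coords
  base_k <- th_dep(d$actuals, d$predictions, co)$kappa
  base_a <- th_indep(d$actuals, d$predictions, co)$AUC
  co_t <- co + 50L
  expect_equal(th_dep(d$actuals, d$predictions, co_t)$kappa, base_k)
  expect_equal(th_indep(d$actuals, d$predictions, co_t)$AUC, base_a)
  co_r <- cbind(co[, 2], max(co[, 1]) - co[, 1] + 1L)  # 90 degree rotation
  expect_equal(th_dep(d$actuals, d$predictions, co_r)$kappa, base_k)
  expect_equal(th_indep(d$actuals, d$predictions, co_r)$AUC, base_a)
})

test_that("invalid accuracy inputs are rejected", {
  co <- full_grid(4)
  a <- rep(c(0, 1), 8); p <- runif(16)
  expect_error(th_dep(a, p, co, threshold = 1.2), "threshold")
  expect_error(th_dep(a, p + 2, co), "probabilities")
  expect_error(th_indep(rep(1, 16), p, co), "one class")
  expect_error(smooth_actuals(c(a[-1], 2), co), "0/1")
})
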