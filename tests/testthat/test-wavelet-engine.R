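test_that("perfect reconstruction and telescoping hold for all transforms", {
  for (wav in c("haar", "d4")) for (tr in c("dwt", "modwt")) for (s in 1:2) {
    set.seed(s)
    m <- matrix(rnorm(256), 16, 16)
    L <- 3L
    de <- decompose2d(m, wav, tr, max_level = L)
    rec <- de$smooths[[L]]
    for (j in 1:L) rec <- rec + de$details[[j]]$total
    expect_lt(max(abs(rec - m)), 1e-8)
    for (j in 2:L)
      expect_lt(max(abs(de$smooths[[j - 1]] -
                        (de$smooths[[j]] + de$details[[j]]$total))), 1e-8)
    # orientation sub-bands add up to the total detail
    expect_lt(max(abs(de$details[[1]]$lh + de$details[[1]]$hl +
                      de$details[[1]]$hh - de$details[[1]]$total)), 1e-10)
  }
})

test_that("constant frames have exactly zero detail components", {
  m <- matrix(4.2, 16, 16)
  for (wav in c("haar", "d4")) for (tr in c("dwt", "modwt")) {
    de <- decompose2d(m, wav, tr, max_level = 2)
    expect_lt(max(abs(de$details[[1]]$total)), 1e-12)
    expect_lt(max(abs(de$details[[2]]$total)), 1e-12)
  }
})

test_that("haar dwt smooth components equal nested block averages", {
  set.seed(8)
  m <- matrix(rnorm(64), 8, 8)
  de <- decompose2d(m, "haar", "dwt", max_level = 3)
  for (s in 1:3)
    expect_lt(max(abs(de$smooths[[s]] - block_average(m, s))), 1e-10)
  expect_lt(max(abs(de$smooths[[3]] - mean(m))), 1e-10)
})

test_that("levels too deep for the grid are refused", {
  m <- matrix(rnorm(64), 8, 8)
  expect_error(decompose2d(m, "haar", "dwt", max_level = 4), "too deep")
  expect_error(decompose2d(m, "d4", "dwt", max_level = 3), "too deep")
})

test_that("high-pass filtering removes constants and preserves identities", {
  set.seed(21)
  co <- ragged_grid(8, 50, seed = 3)
  expect_lt(max(abs(filter_highpass(rep(5, 50), co, level = 2))), 1e-8)
  v <- rnorm(50)
  for (L in 1:2) {
    hp <- filter_highpass(v, co, level = L)
    sm <- extract_component(v, co, scale = L, detail = FALSE)
    expect_lt(max(abs(hp + sm - v)), 1e-8)
  }
  # checkerboard is pure level-1 detail under haar on a full dyadic grid
  co8 <- full_grid(8)
  f <- (-1)^(co8[, 1] + co8[, 2])
  expect_lt(max(abs(filter_highpass(f, co8, level = 1) - f)), 1e-10)
})

test_that("single-scale components telescope back to the data", {
  set.seed(31)
  co <- full_grid(16)
  v <- rnorm(256)
  L <- 3
  acc <- extract_component(v, co, scale = L, detail = FALSE)
  for (s in 1:L) acc <- acc + extract_component(v, co, scale = s)
  expect_lt(max(abs(acc - v)), 1e-8)
  expect_lt(max(abs(extract_component(rep(2, 256), co, scale = 2))), 1e-10)
  expect_equal(extract_component(v, co, scale = 1, detail = TRUE),
               filter_highpass(v, co, level = 1), tolerance = 1e-10)
})

test_that("modwt components are translation equivariant", {
  set.seed(17)
  m <- matrix(rnorm(256), 16, 16)
  ms <- m[c(16, 1:15), ]  # circular shift by one row
  d1 <- decompose2d(m, "d4", "modwt", max_level = 2)
  d2 <- decompose2d(ms, "d4", "modwt", max_level = 2)
  expect_lt(max(abs(d2$details[[2]]$total -
                    d1$details[[2]]$total[c(16, 1:15), ])), 1e-8)
  expect_lt(max(abs(d2$smooths[[2]] - d1$smooths[[2]][c(16, 1:15), ])), 1e-8)
})

test_that("d4 details annihilate linear ramps away from the wrap boundary", {
  co <- full_grid(16)
  ramp <- outer(1:16, 1:16, function(r, c) 0.7 * r + 0.2 * c)
  de <- decompose2d(ramp, "d4", "dwt", max_level = 1)
  interior <- de$details[[1]]$total[5:12, 5:12]
  expect_lt(max(abs(interior)), 1e-8)
})

test_that("wavelet variance satisfies the modwt energy decomposition", {
  set.seed(23)
  co <- full_grid(16)
  x <- rnorm(256); y <- 2 * x + rnorm(256)
  d <- data.frame(y = y, x = x)
  vc <- wavelet_varcov(y ~ x - 1, d, co, wavelet = "d4", wtrafo = "modwt")
  # covariance of a variable with an identical copy is its variance
  dd <- data.frame(y2 = x, x = x)
  vcx <- wavelet_varcov(y2 ~ x - 1, dd, co)
  expect_equal(unname(vcx$covariance[, 1]), unname(vcx$variance[, 1]),
               tolerance = 1e-10)
  # energies add up to the total variance of each (centred) field
  for (j in 1:2)
    expect_equal(unname(sum(vc$variance[, j]) + vc$smooth_energy[j]),
                 mean((d[[j]] - mean(d[[j]]))^2), tolerance = 1e-8)
})

test_that("wavelet covariance of independent noise is centred on zero", {
  set.seed(77)
  co <- full_grid(16)
  cov1 <- replicate(60, {
    d <- data.frame(y = rnorm(256), x = rnorm(256))
    wavelet_varcov(y ~ x - 1, d, co)$covariance[1, 1]
  })
  se <- sd(cov1) / sqrt(length(cov1))
  expect_lt(abs(mean(cov1)), 3 * se + 1e-3)
})
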