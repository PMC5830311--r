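# BOLD synthesis and the amplitude-modulated GLM.

test_that("HRF-convolved single-event regressors peak near 6 s and superpose linearly", {
  d1 <- build_design_matrix(onsets = 0, modulators = cbind(m = 1),
                            TR = 2, n_volumes = 20)
  ev <- d1$X[, "event"]
  expect_equal(which.max(ev), 4)            # sample at t = 6 s
  # linearity: two events equal the sum of the single-event columns
  d2 <- build_design_matrix(onsets = 10, modulators = cbind(m = 1), TR = 2, n_volumes = 20)
  d12 <- build_design_matrix(onsets = c(0, 10), modulators = cbind(m = c(1, 1)),
                             TR = 2, n_volumes = 20)
  expect_equal(d12$X[, "event"], d1$X[, "event"] + d2$X[, "event"], tolerance = 1e-10)
  # AM weights are mean-centered before convolution
  d3 <- build_design_matrix(onsets = c(0, 8, 16, 24), modulators = cbind(m = c(1, 0, 1, 1)),
                            TR = 2, n_volumes = 30)
  expect_equal(sum(d3$am_weights), 0)
  expect_error(build_design_matrix(onsets = 100, modulators = cbind(m = 1),
                                   TR = 2, n_volumes = 20), "beyond scan end")
})

test_that("noiseless signals are recovered exactly and scale linearly", {
  set.seed(5)
  onsets <- seq(0, 150, by = 6) + runif(26, 0, 2)
  mod <- cbind(a = rbinom(26, 1, 0.5), b = rnorm(26))
  grid <- c(4, 4, 2); nv <- prod(grid)
  betas <- cbind(runif(nv, -1, 1), runif(nv, -1, 1))
  bold <- synthesize_bold(onsets, mod, betas, noise = list(sigma = 0, ar1 = 0),
                          TR = 2, grid = grid, seed = 1)
  glm <- fit_am_glm(bold)
  expect_equal(glm$beta[, c("a", "b")], betas, tolerance = 1e-8, ignore_attr = TRUE)
  # doubling a planted amplitude doubles the recovered coefficient
  bold2 <- synthesize_bold(onsets, mod, betas * 2, noise = list(sigma = 0, ar1 = 0),
                           TR = 2, grid = grid, seed = 1)
  glm2 <- fit_am_glm(bold2)
  expect_equal(glm2$beta[, "a"], 2 * glm$beta[, "a"], tolerance = 1e-8)
  # an uncorrelated extra modulator leaves other coefficients unchanged
  # (joint interpretability of AM regressors in the noiseless case)
  mod3 <- cbind(mod, c = rep(c(1, 0), 13))
  betas3 <- cbind(betas, 0)
  bold3 <- synthesize_bold(onsets, mod3, betas3, noise = list(sigma = 0, ar1 = 0),
                           TR = 2, grid = grid, seed = 1)
  glm3 <- fit_am_glm(bold3)
  expect_equal(glm3$beta[, c("a", "b")], glm$beta[, c("a", "b")], tolerance = 1e-6)
})

test_that("rank deficiency is reported with the offending columns", {
  onsets <- seq(0, 60, by = 4)
  mod <- cbind(a = seq_along(onsets), dup = seq_along(onsets))
  d <- build_design_matrix(onsets, mod, TR = 2, n_volumes = 45)
  y <- matrix(rnorm(2 * 45), 2, 45)
  expect_error(fit_am_glm(y, d), "collinear.*dup")
})

test_that("noise-only synthesis has the requested variance and null-calibrated t values", {
  onsets <- seq(0, 400, by = 5)
  mod <- cbind(a = rep(c(0, 1), length.out = length(onsets)))
  grid <- c(10, 10, 10); nv <- prod(grid)
  bold <- synthesize_bold(onsets, mod, matrix(0, nv, 1),
                          noise = list(sigma = 1, ar1 = 0), TR = 2,
                          grid = grid, seed = 8)
  v <- apply(bold$signal, 1, var)
  nt <- ncol(bold$signal)
  se <- sqrt(2 / (nt - 1))           # sampling SE of unit-variance estimates
  expect_lt(abs(mean(v) - 1), 3 * se / sqrt(nv))
  # voxelwise t statistics follow the Student null
  glm <- fit_am_glm(bold)
  u <- pt(glm$t[, "a"], glm$df)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(glm$t[, "a"] > qt(0.995, glm$df)) - 0.005), 0.01)
})

test_that("group test separates strong consistent effects and flips with sign", {
  set.seed(9)
  strong <- matrix(1 + rnorm(24 * 5, sd = 0.05), 24, 5)
  gt <- group_test(strong)
  expect_true(all(gt$p_pos < 1e-8))
  gneg <- group_test(-strong)
  expect_equal(gneg$p_neg, gt$p_pos, tolerance = 1e-12)
  expect_equal(gneg$p_pos, gt$p_neg, tolerance = 1e-12)
  expect_error(group_test(strong[1:2, ]), "at least 3")
})

test_that("cluster-extent thresholding applies the size rule per component", {
  grid <- c(8, 8, 8)
  p <- rep(1, prod(grid)); tmap <- rep(0, prod(grid))
  vox <- function(x, y, z) (z - 1) * 64 + (y - 1) * 8 + x
  blob30 <- c(outer(outer(1:5, (1:3 - 1) * 8, "+"), (1:2 - 1) * 64, "+"))  # 5x3x2
  p[blob30] <- 1e-4; tmap[blob30] <- 4
  cl <- cluster_threshold(tmap, p, grid, p_thresh = 0.005, k = 23)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 30)
  expect_equal(cl$sign, "+")
  # 22-voxel blob falls below k = 23
  p2 <- rep(1, prod(grid)); t2 <- rep(0, prod(grid))
  blob22 <- blob30[1:22]
  p2[blob22] <- 1e-4; t2[blob22] <- 4
  expect_equal(nrow(cluster_threshold(t2, p2, grid, 0.005, 23)), 0)
  # separated blobs of 25 and 10: only the large one survives
  p3 <- rep(1, prod(grid)); t3 <- rep(0, prod(grid))
  blob25 <- c(outer(outer(1:5, (1:5 - 1) * 8, "+"), 0, "+"))          # 5x5x1 at z=1
  blob10 <- vox(rep(1:5, 2), rep(7:8, each = 5), 8)
  p3[c(blob25, blob10)] <- 1e-4; t3[c(blob25, blob10)] <- -4
  cl3 <- cluster_threshold(t3, p3, grid, 0.005, 23)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$size, 25)
  expect_equal(cl3$sign, "-")
})
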