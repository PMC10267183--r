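test_that("PCA matches an independent eigendecomposition and reconstructs", {
  set.seed(41)
  X <- matrix(rnorm(200), 20, 10) %*% diag(sqrt(seq(10, 1)))
  p <- cm_pca(X)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-12)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$variance_fractions, (ev / sum(ev))[seq_along(p$variance_fractions)],
               tolerance = 1e-10)
  expect_lt(max(abs(crossprod(p$loadings) - diag(ncol(p$loadings)))), 1e-10)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - sweep(X, 2, colMeans(X)))), 1e-8)

  # data varying along a single direction loads PC1 with everything
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  X1 <- outer(rnorm(15), u)
  p1 <- cm_pca(X1)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-10)

  expect_error(cm_pca(matrix(1, 5, 3)), "constant")
})

test_that("multivariate regression reproduces scalar OLS and detects exact
           fits", {
  set.seed(43)
  x <- rnorm(25)
  y <- 2 + 3 * x + rnorm(25)
  r1 <- multivariate_regression(matrix(y, ncol = 1), x)
  expect_equal(r1$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  expect_equal(unname(r1$coefficients),
               unname(stats::coef(stats::lm(y ~ x))[2]), tolerance = 1e-10)

  B <- matrix(rnorm(8), 1, 8)
  Y <- outer(x, as.vector(B)) + matrix(5, 25, 8)
  r2 <- multivariate_regression(Y, x, n_perm = 99, seed = 1)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  expect_equal(r2$p_value, 1 / 100)

  expect_error(multivariate_regression(Y, rep(1, 25)), "constant")
  expect_error(multivariate_regression(Y[1:2, ], x[1:2]), "at least 3")
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  set.seed(44)
  n <- 30
  x <- rnorm(n)
  Y <- outer(x, rnorm(5)) + matrix(rnorm(n * 5), n, 5)
  p1 <- multivariate_regression(Y, x, n_perm = 199, seed = 7)$p_value
  p2 <- multivariate_regression(Y, x, n_perm = 199, seed = 7)$p_value
  expect_identical(p1, p2)
  ord <- sample(n)
  p3 <- multivariate_regression(Y[ord, ], x[ord], n_perm = 199, seed = 7)$p_value
  expect_identical(p1, p3)

  xB <- rnorm(n)
  YB <- outer(xB, rnorm(5)) + matrix(rnorm(n * 5), n, 5)
  t1 <- trajectory_angle_test(Y, x, YB, xB, n_perm = 99, seed = 5)
  oA <- sample(n); oB <- sample(n)
  t2 <- trajectory_angle_test(Y[oA, ], x[oA], YB[oB, ], xB[oB],
                              n_perm = 99, seed = 5)
  expect_identical(t1$p_value, t2$p_value)
  expect_equal(t1$angle_deg, t2$angle_deg, tolerance = 1e-12)
})

test_that("trajectory angles are exact on constructed geometries", {
  set.seed(45)
  x <- rnorm(20)
  u <- c(1, 0, 0, 0); w <- c(0, 1, 0, 0)
  Y_u <- outer(x, u)
  self <- trajectory_angle_test(Y_u, x, Y_u, x, n_perm = 49, seed = 1)
  expect_equal(self$angle_deg, 0, tolerance = 1e-8)

  x2 <- rnorm(20)
  orth <- trajectory_angle_test(Y_u, x, outer(x2, w), x2, n_perm = 49, seed = 1)
  expect_equal(orth$angle_deg, 90, tolerance = 1e-8)

  expect_error(trajectory_angle_test(Y_u, x, matrix(0, 20, 4), x2,
                                     n_perm = 9), "zero-length")
})

test_that("two-block PLS matches a brute-force covariance maximisation", {
  set.seed(46)
  # noise-free coupling: block2 is a projection of a whitened block1, so
  # the covariance-maximal axis is the projection direction itself
  raw <- matrix(rnorm(60), 20, 3)
  cr <- sweep(raw, 2, colMeans(raw))
  b1 <- cr %*% solve(chol(stats::cov(cr)))
  dir <- c(0.5, -0.7, 0.2)
  b2 <- cbind(b1 %*% dir, b1 %*% dir * 2)
  pls <- two_block_pls(b1, b2, n_perm = 99, seed = 2)
  expect_equal(abs(pls$r[1]), 1, tolerance = 1e-10)
  expect_equal(sum(pls$pct_covariance), 100, tolerance = 1e-9)
  expect_equal(pls$p_value, 1 / 100)

  # brute force on a small noisy pair: search unit vectors maximising the
  # score covariance, polished by optim from many starts
  b1 <- matrix(rnorm(4 * 30), 30, 4)
  b2 <- b1[, 1:3] + matrix(rnorm(90), 30, 3) * 0.5
  pls2 <- two_block_pls(b1, b2, n_perm = 0)
  c1 <- sweep(b1, 2, colMeans(b1)); c2 <- sweep(b2, 2, colMeans(b2))
  covscore <- function(par) {
    u <- par[1:4]; v <- par[5:7]
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    -abs(stats::cov(c1 %*% u, c2 %*% v))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(400 + s)
    o <- stats::optim(rnorm(7), covscore, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-13))
    best <- min(best, o$value)
  }
  got <- abs(stats::cov(pls2$scores1[, 1], pls2$scores2[, 1]))
  expect_equal(got, -best, tolerance = 1e-6)

  expect_error(two_block_pls(b1, b2[1:10, ]), "equal row counts")
  expect_error(two_block_pls(matrix(1, 10, 2), matrix(1, 10, 2)),
               "rank-zero|constant")
})

test_that("age groups follow the half-open binning convention", {
  g <- assign_age_groups(c(0, 0.5, 1, 1.01, 44.62, 48))
  expect_equal(length(levels(g)), 9)
  expect_equal(as.character(g[1]), "[0,1]")
  expect_equal(as.character(g[3]), "[0,1]")    # edge goes to the lower bin
  expect_equal(as.character(g[4]), "(1,3]")
  expect_equal(as.character(g[5]), "(36,48]")  # 1357 days = 44.62 months
  expect_error(assign_age_groups(c(10, 50)), "outside")
  expect_error(assign_age_groups(5, edges = c(0, 3, 3, 10)), "increasing")

  set.seed(47)
  scores <- matrix(rnorm(40), 20, 2)
  labs <- assign_age_groups(stats::runif(20, 0, 48))
  sexes <- factor(sample(c("F", "M"), 20, TRUE))
  gm <- group_means(scores, labs, sexes)
  expect_true(all(c("group", "sex") %in% names(gm)))
})

test_that("regression warps restore shape and size along the trajectory", {
  g <- fix_gpa()
  reg <- multivariate_regression(g$shape_matrix, g$ln_cs)
  xbar <- mean(g$ln_cs)
  at_mean <- warp_along_regression(reg, xbar)
  want <- matrix(colMeans(g$shape_matrix), ncol = 3, byrow = TRUE) * exp(xbar)
  expect_lt(max(abs(at_mean - want)), 1e-9)

  # affine in the covariate: midpoint equals the average of the endpoints
  lo <- min(g$ln_cs); hi <- max(g$ln_cs)
  mid_shape <- warp_along_regression(reg, (lo + hi) / 2, ln_cs = 0)
  end_avg <- (warp_along_regression(reg, lo, ln_cs = 0) +
                warp_along_regression(reg, hi, ln_cs = 0)) / 2
  expect_lt(max(abs(mid_shape - end_avg)), 1e-9)

  expect_warning(warp_along_regression(reg, hi + 1), "extrapolat")

  # generator oracle: on a noise-free cohort the warp at a target size
  # reproduces the generator's noise-free specimen up to Procrustes error
  tpl <- fix_template2()
  coh0 <- generate_cohort(40, params = growth_params(landmark_noise_sd = 0),
                          seed = 77, with_mesh = FALSE, template = tpl)
  g0 <- gpa(lapply(coh0$specimens, `[[`, "landmarks"))
  reg0 <- multivariate_regression(g0$shape_matrix, g0$ln_cs)
  sp_t <- grow_skull(tpl, 900, "F", noise_sd = 0, with_mesh = FALSE)
  truth <- sp_t$landmarks$coords[g0$names, ]
  # covariate on the same 86-point roster the regression was fitted on
  x_t <- log(centroid_size(truth))
  pred <- warp_along_regression(reg0, x_t)
  expect_equal(centroid_size(pred), centroid_size(truth), tolerance = 0.01)
  expect_lt(procrustes_distance(pred, truth), 0.01)
})

test_that("the form matrix appends Ln(CS) with tagged column roles", {
  g <- fix_gpa()
  fm <- form_matrix(g)
  expect_equal(ncol(fm), ncol(g$shape_matrix) + 1)
  expect_equal(unname(fm[, ncol(fm)]), unname(g$ln_cs))
  roles <- attr(fm, "column_roles")
  expect_equal(sum(roles == "ln_cs"), 1)
  expect_equal(which(roles == "ln_cs"), ncol(fm))
})

test_that("similarity components are projected out of displacement fields", {
  set.seed(48)
  shape <- matrix(rnorm(30), 10, 3)
  shape <- sweep(shape, 2, colMeans(shape))
  shape <- shape / sqrt(sum(shape^2))
  # a pure similarity field (translation + scaling + rotation) projects to 0
  W <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))
  sim_field <- matrix(1, 10, 1) %*% c(1, 2, 3) + 0.3 * shape + shape %*% W
  expect_lt(sqrt(sum(project_out_similarity(sim_field, shape)^2)), 1e-10)
  rand <- matrix(rnorm(30), 10, 3)
  kept <- project_out_similarity(rand, shape)
  expect_gt(sqrt(sum(kept^2)), 0.1)
})
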