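test_that("centroid size follows its defining formula and scales linearly", {
  set.seed(21)
  x <- matrix(rnorm(15), 5, 3) * 12
  brute <- sqrt(sum(sweep(x, 2, colMeans(x))^2))
  expect_equal(centroid_size(x), brute, tolerance = 1e-12)
  expect_equal(centroid_size(x * 3.7), 3.7 * centroid_size(x),
               tolerance = 1e-12)
  expect_equal(centroid_size(matrix(5, 4, 3)), 0)
  expect_error(centroid_size(matrix(numeric(0), 0, 3)), "empty")
})

test_that("ordinary Procrustes removes similarity transforms and flags
           reflections", {
  set.seed(22)
  x <- matrix(rnorm(24), 8, 3) * 10
  R <- random_rotation(5)
  y <- 2.3 * x %*% R + matrix(c(4, 5, 6), 8, 3, byrow = TRUE)
  fit <- ordinary_procrustes(x, y)
  expect_lt(fit$distance, 1e-10)

  mirror <- x %*% diag(c(-1, 1, 1))
  expect_gt(ordinary_procrustes(mirror, x)$distance, 0.1)
  expect_lt(ordinary_procrustes(mirror, x, allow_reflection = TRUE)$distance,
            1e-10)
  expect_error(ordinary_procrustes(x, x[1:5, ]), "point counts")
})

test_that("ordinary Procrustes matches a numeric optimiser over rotations", {
  # oracle: minimise the residual over an Euler-angle parameterisation
  euler <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  for (seed in 1:8) {
    set.seed(seed)
    a <- matrix(rnorm(21), 7, 3)
    b <- matrix(rnorm(21), 7, 3)
    fit <- ordinary_procrustes(a, b)
    au <- a - matrix(colMeans(a), 7, 3, byrow = TRUE)
    au <- au / sqrt(sum(au^2))
    bu <- b - matrix(colMeans(b), 7, 3, byrow = TRUE)
    bu <- bu / sqrt(sum(bu^2))
    obj <- function(ang) sum((au %*% euler(ang) - bu)^2)
    best <- Inf
    for (s in 1:6) {
      set.seed(100 * seed + s)
      o <- stats::optim(runif(3, -pi, pi), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_equal(fit$distance, sqrt(best), tolerance = 1e-6)
  }
})

test_that("GPA is invariant to similarity transforms and honours the
           flagged-landmark exclusion", {
  tpl <- fix_template2()
  specs <- lapply(c(100, 600, 1200), function(d)
    grow_skull(tpl, d, "F", rng_seed = d, noise_sd = 1))
  lms <- lapply(specs, `[[`, "landmarks")
  names(lms) <- paste0("s", 1:3)
  res <- gpa(lms, exclude_flagged = TRUE)
  expect_equal(dim(res$shapes)[1], 86)
  expect_identical(res$excluded_names, c("Euryon_L", "Euryon_R"))
  expect_equal(ncol(res$shape_matrix), 86 * 3)

  # every aligned configuration is centred with unit centroid size
  for (i in 1:3) {
    expect_lt(max(abs(colMeans(res$shapes[, , i]))), 1e-12)
    expect_equal(sum(res$shapes[, , i]^2), 1, tolerance = 1e-12)
  }
  expect_equal(sum(res$mean_shape^2), 1, tolerance = 1e-12)

  # similarity-transformed inputs give identical shape coordinates
  lms2 <- lms
  for (i in seq_along(lms2)) {
    R <- random_rotation(40 + i)
    lms2[[i]]$coords <- 1.5 * lms2[[i]]$coords %*% R +
      matrix(c(10 * i, -3, 7), nrow(lms2[[i]]$coords), 3, byrow = TRUE)
  }
  res2 <- gpa(lms2, exclude_flagged = TRUE)
  expect_lt(max(abs(res2$shape_matrix - res$shape_matrix)), 1e-8)
  # centroid sizes pick up the scale factor
  expect_equal(res2$centroid_sizes, 1.5 * res$centroid_sizes,
               tolerance = 1e-9)

  # identical configurations: zero pairwise distances, mean equals shape
  same <- list(a = lms[[1]], b = lms[[1]], c = lms[[1]])
  res3 <- gpa(same)
  expect_lt(procrustes_distance(res3$shapes[, , 1], res3$shapes[, , 2]), 1e-12)
  expect_lt(max(abs(res3$mean_shape - res3$shapes[, , 1])), 1e-10)

  # roster mismatch is reported with the missing names
  bad <- lms
  bad[[2]] <- lm_subset(bad[[2]], 1:80)
  expect_error(gpa(bad), "roster")
})

test_that("the GPA mean is a fixed point and centring holds", {
  res <- fix_gpa()
  n <- dim(res$shapes)[3]
  # centring identity: the mean shape is the renormalised average of the
  # aligned shapes, so the column means point exactly along it
  avg <- matrix(colMeans(res$shape_matrix), ncol = 3, byrow = TRUE)
  avg_unit <- avg / sqrt(sum(avg^2))
  expect_lt(max(abs(avg_unit - res$mean_shape)), 1e-8)

  # re-aligning every shape to the converged mean changes nothing
  realigned <- vapply(seq_len(n), function(i)
    max(abs(ordinary_procrustes(res$shapes[, , i], res$mean_shape)$aligned -
              res$shapes[, , i])), numeric(1))
  expect_lt(max(realigned), 1e-7)
})

test_that("Procrustes distance behaves as a metric on unit-size shapes", {
  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    c <- matrix(rnorm(18), 6, 3)
    dab <- procrustes_distance(a, b)
    dba <- procrustes_distance(b, a)
    expect_equal(dab, dba, tolerance = 1e-8)
    expect_lte(procrustes_distance(a, c),
               dab + procrustes_distance(b, c) + 1e-8)
  }
})
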