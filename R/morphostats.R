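#' Form matrix: shape variables plus Ln(CS)
#'
#' Binds the flattened Procrustes shape coordinates with an appended column
#' of log centroid size, so that a PCA of the result is a form-space
#' analysis capturing size and shape jointly.
#'
#' @param gpa_result a `cm_gpa`.
#' @return numeric matrix with an `ln_cs` final column; the column role is
#'   recorded in `attr(, "column_roles")`.
#' @export
form_matrix <- function(gpa_result) {
  fm <- cbind(gpa_result$shape_matrix, ln_cs = gpa_result$ln_cs)
  attr(fm, "column_roles") <- c(rep("shape", ncol(gpa_result$shape_matrix)),
                                "ln_cs")
  fm
}

#' Covariance-based principal component analysis
#'
#' Thin wrapper around the singular value decomposition of the centred data
#' matrix: returns scores, orthonormal loadings and the fractions of total
#' variance per component (summing to 1).
#'
#' @param x numeric matrix, observations in rows.
#' @param center centre columns first.
#' @return list of class `cm_pca`: `scores`, `loadings`,
#'   `variance_fractions`, `center`.
#' @export
cm_pca <- function(x, center = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, ctr)
  if (all(abs(xc) < 1e-14)) stop("constant matrix: no variance to analyse")
  s <- svd(xc)
  keep <- s$d > max(s$d) * 1e-12
  lambda <- s$d[keep]^2
  structure(list(scores = s$u[, keep, drop = FALSE] %*% diag(s$d[keep],
                                                             sum(keep)),
                 loadings = s$v[, keep, drop = FALSE],
                 variance_fractions = lambda / sum(lambda),
                 center = ctr),
            class = "cm_pca")
}

#' Multivariate regression of a response matrix on one covariate
#'
#' Ordinary least squares per column. The single R-squared follows the
#' trace convention for multivariate responses:
#' `R2 = 1 - trace(residual SSQ) / trace(total centred SSQ)`. The
#' permutation p-value shuffles the covariate across rows and uses the
#' add-one smoothing `(1 + #{R2_perm >= R2_obs}) / (1 + n_perm)` so finite
#' permutation counts never report a zero p.
#'
#' @param Y numeric matrix (rows = specimens), no missing values.
#' @param x numeric covariate vector.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed for the permutations.
#' @return object of class `cm_mvregression`: `coefficients` (per column),
#'   `intercept`, `r_squared`, `p_value`, `n_perm`, `fitted_range`.
#' @export
multivariate_regression <- function(Y, x, n_perm = 0, seed = NULL) {
  Y <- as.matrix(Y)
  x <- as.numeric(x)
  n <- nrow(Y)
  if (length(x) != n) stop("covariate length mismatch")
  if (n < 3) stop("need at least 3 specimens")
  if (anyNA(Y) || anyNA(x)) stop("missing values are not allowed")
  ord <- order(x)  # canonical row order: permutation p-values do not depend
  Y <- Y[ord, , drop = FALSE]   # on the order specimens are supplied in
  x <- x[ord]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx < 1e-24) stop("constant covariate")
  Yc <- sweep(Y, 2, colMeans(Y))
  b <- as.vector(crossprod(Yc, xc)) / sxx
  tot <- sum(Yc^2)
  expl <- sum(b^2) * sxx
  r2 <- expl / tot
  p <- NA_real_
  if (n_perm > 0) {
    perm_r2 <- with_local_seed(seed, function() {
      vapply(seq_len(n_perm), function(i) {
        xp <- xc[sample.int(n)]
        sum(as.vector(crossprod(Yc, xp))^2) / sum(xp^2) / tot
      }, numeric(1))
    })
    p <- (1 + sum(perm_r2 >= r2)) / (1 + n_perm)
  }
  structure(list(coefficients = b,
                 intercept = colMeans(Y) - b * mean(x),
                 r_squared = r2, p_value = p, n_perm = n_perm,
                 fitted_range = range(x),
                 x_mean = mean(x)),
            class = "cm_mvregression")
}

#' @export
print.cm_mvregression <- function(x, ...) {
  cat(sprintf("multivariate regression: R2 = %.4f", x$r_squared))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Angle in degrees between two vectors
#' @param a,b numeric vectors.
#' @export
vector_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length vector")
  acos(pmin(1, pmax(-1, sum(a * b) / na / nb))) * 180 / pi
}

#' Permutation test for the angle between two ontogenetic trajectories
#'
#' Fits the regression of each group's response matrix on its covariate and
#' takes the angle (arc-cosine of the dot product of the unit coefficient
#' vectors). Two permutation schemes build the null of a shared trajectory:
#'
#' * `"stratified_labels"` (default): specimens are pooled, ranked by the
#'   covariate and split into `n_strata` rank strata; group labels are
#'   reshuffled within each stratum, preserving group sizes per stratum.
#'   Specimens of similar size are exchangeable under the null even when
#'   the groups differ in covariate distribution (e.g. one sex larger for
#'   age) or when residual scatter varies with size, so the test stays
#'   calibrated where plain label reshuffling does not.
#' * `"labels"`: specimens are pooled and group labels reassigned fully at
#'   random, preserving overall group sizes.
#'
#' @param Y_A,Y_B response matrices sharing columns.
#' @param x_A,x_B covariates.
#' @param n_perm permutations (the standard battery uses 1000).
#' @param seed integer.
#' @param labels group labels for reporting.
#' @param method permutation scheme (see above).
#' @param n_strata covariate strata for the default scheme.
#' @return object of class `cm_trajectory_comparison`: `angle_deg`,
#'   `p_value`, `n_perm`, per-group regressions.
#' @export
trajectory_angle_test <- function(Y_A, x_A, Y_B, x_B, n_perm = 1000,
                                  seed = NULL, labels = c("A", "B"),
                                  method = c("stratified_labels", "labels"),
                                  n_strata = 8) {
  method <- match.arg(method)
  Y_A <- as.matrix(Y_A); Y_B <- as.matrix(Y_B)
  if (ncol(Y_A) != ncol(Y_B)) stop("response blocks must share columns")
  oA <- order(x_A); oB <- order(x_B)  # canonical order (see above)
  Y_A <- Y_A[oA, , drop = FALSE]; x_A <- x_A[oA]
  Y_B <- Y_B[oB, , drop = FALSE]; x_B <- x_B[oB]
  coef_of <- function(Y, x) {
    xc <- x - mean(x)
    as.vector(crossprod(sweep(Y, 2, colMeans(Y)), xc)) / sum(xc^2)
  }
  angle_of <- function(bA, bB) {
    na <- sqrt(sum(bA^2)); nb <- sqrt(sum(bB^2))
    if (na < 1e-15 || nb < 1e-15) stop("zero-length coefficient vector")
    acos(pmin(1, pmax(-1, sum(bA * bB) / na / nb))) * 180 / pi
  }
  regA <- multivariate_regression(Y_A, x_A)
  regB <- multivariate_regression(Y_B, x_B)
  obs <- angle_of(regA$coefficients, regB$coefficients)
  nA <- nrow(Y_A)
  Y <- rbind(Y_A, Y_B)
  x <- c(x_A, x_B)
  n <- nrow(Y)
  ia0 <- seq_len(nA)
  grp <- rep(c(1L, 2L), c(nA, n - nA))
  perm_angles <- with_local_seed(seed, function() {
    if (method == "labels") {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        ia <- idx[ia0]; ib <- idx[-ia0]
        angle_of(coef_of(Y[ia, , drop = FALSE], x[ia]),
                 coef_of(Y[ib, , drop = FALSE], x[ib]))
      }, numeric(1))
    } else {
      nb <- max(1L, min(n_strata, floor(n / 4)))
      bins <- cut(rank(x, ties.method = "first"), breaks = nb, labels = FALSE)
      vapply(seq_len(n_perm), function(i) {
        gp <- grp
        for (b in unique(bins)) {
          idx <- which(bins == b)
          gp[idx] <- grp[idx][sample.int(length(idx))]
        }
        angle_of(coef_of(Y[gp == 1L, , drop = FALSE], x[gp == 1L]),
                 coef_of(Y[gp == 2L, , drop = FALSE], x[gp == 2L]))
      }, numeric(1))
    }
  })
  p <- (1 + sum(perm_angles >= obs)) / (1 + n_perm)
  structure(list(angle_deg = obs, p_value = p, n_perm = n_perm,
                 labels = labels,
                 regression_A = regA, regression_B = regB),
            class = "cm_trajectory_comparison")
}

#' @export
print.cm_trajectory_comparison <- function(x, ...) {
  cat(sprintf("trajectory angle %s vs %s: %.2f deg, p = %.4g (%d permutations)\n",
              x$labels[1], x$labels[2], x$angle_deg, x$p_value, x$n_perm))
  invisible(x)
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-covariance matrix of the two
#' centred blocks. Per axis: paired singular vectors, the correlation `r`
#' of the paired scores, and the percent of total squared cross-covariance.
#' `pct_var_block1` is the percent of Block 1's total variance explained by
#' its own first-axis scores (`mode = "own_scores"`), or by prediction from
#' Block 2's first-axis scores (`mode = "predicted"`). The permutation test
#' shuffles the rows of Block 2 and compares the first-axis score
#' correlation.
#'
#' @param block1,block2 numeric matrices with equal row counts (n >= 3).
#' @param n_perm permutations (the standard battery uses 1000).
#' @param seed integer.
#' @param mode convention for `pct_var_block1` (see above).
#' @return object of class `cm_pls`: `u`, `v` (singular vectors),
#'   `singular_values`, `scores1`, `scores2`, `r` (per axis),
#'   `pct_covariance`, `pct_var_block1`, `p_value`, `n_perm`.
#' @export
two_block_pls <- function(block1, block2, n_perm = 1000, seed = NULL,
                          mode = c("own_scores", "predicted")) {
  mode <- match.arg(mode)
  b1 <- as.matrix(block1); b2 <- as.matrix(block2)
  n <- nrow(b1)
  if (nrow(b2) != n) stop("blocks must have equal row counts")
  if (n < 3) stop("need at least 3 specimens")
  c1 <- sweep(b1, 2, colMeans(b1))
  c2 <- sweep(b2, 2, colMeans(b2))
  C <- crossprod(c1, c2) / (n - 1)
  if (max(abs(C)) < 1e-15) stop("rank-zero cross-covariance")
  s <- svd(C)
  keep <- s$d > max(s$d) * 1e-12
  d <- s$d[keep]
  u <- s$u[, keep, drop = FALSE]
  v <- s$v[, keep, drop = FALSE]
  s1 <- c1 %*% u
  s2 <- c2 %*% v
  r <- vapply(seq_along(d), function(j) stats::cor(s1[, j], s2[, j]),
              numeric(1))
  pct_cov <- 100 * d^2 / sum(d^2)
  pct_var1 <- if (mode == "own_scores") {
    100 * sum(s1[, 1]^2) / sum(c1^2)
  } else {
    fit <- stats::lm.fit(cbind(1, s2[, 1]), c1)
    100 * (1 - sum(fit$residuals^2) / sum(c1^2))
  }
  p <- NA_real_
  if (n_perm > 0) {
    perm_r <- with_local_seed(seed, function() {
      vapply(seq_len(n_perm), function(i) {
        c2p <- c2[sample.int(n), , drop = FALSE]
        cp <- crossprod(c1, c2p) / (n - 1)
        sp <- svd(cp)
        abs(stats::cor(c1 %*% sp$u[, 1], c2p %*% sp$v[, 1]))
      }, numeric(1))
    })
    p <- (1 + sum(perm_r >= abs(r[1]))) / (1 + n_perm)
  }
  structure(list(u = u, v = v, singular_values = d,
                 scores1 = s1, scores2 = s2, r = r,
                 pct_covariance = pct_cov,
                 pct_var_block1 = pct_var1,
                 p_value = p, n_perm = n_perm, mode = mode),
            class = "cm_pls")
}

#' @export
print.cm_pls <- function(x, ...) {
  cat(sprintf("two-block PLS: axis-1 r = %.3f (%.1f%% of squared cross-covariance), %%Var Block1 = %.1f",
              x$r[1], x$pct_covariance[1], x$pct_var_block1))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' The default 9-bin age grouping (months)
#'
#' Bin edges 0, 1, 3, 6, 9, 12, 18, 24, 36, 48: one bin to 1 month, then
#' widening intervals tracking the deceleration of growth, with a single
#' 36-48 month bin.
#'
#' @export
default_age_groups <- function() c(0, 1, 3, 6, 9, 12, 18, 24, 36, 48)

#' Assign specimens to age groups
#'
#' Half-open bins `(lower, upper]`, with the first bin closed at 0, so an
#' age exactly on an edge goes to the lower-adjacent bin deterministically.
#'
#' @param ages_months numeric ages in months.
#' @param edges strictly increasing bin edges covering the ages.
#' @return factor of bin labels `"(a,b]"`.
#' @export
assign_age_groups <- function(ages_months, edges = default_age_groups()) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(ages_months < edges[1] | ages_months > edges[length(edges)]))
    stop("age outside the grouping scheme coverage")
  cut(ages_months, breaks = edges, include.lowest = TRUE, right = TRUE)
}

#' Mean rows per group (optionally split by sex)
#' @param scores numeric matrix.
#' @param labels group factor.
#' @param sex optional factor to split by.
#' @return data.frame of group means.
#' @export
group_means <- function(scores, labels, sex = NULL) {
  scores <- as.matrix(scores)
  key <- if (is.null(sex)) data.frame(group = labels)
         else data.frame(group = labels, sex = sex)
  agg <- stats::aggregate(scores, by = key, FUN = mean, drop = TRUE)
  agg
}

#' Warp the mean shape along a regression vector and restore size
#'
#' Evaluates the fitted shape at `covariate_value` (affine in the
#' covariate) and scales it by `exp(ln_cs)`, the Ln(CS) associated with
#' that score — by default the covariate itself, when the regression is of
#' shape on Ln(CS). Values outside the fitted covariate range warn about
#' extrapolation.
#'
#' @param regression a `cm_mvregression` of the flattened shape matrix.
#' @param covariate_value scalar covariate value.
#' @param ln_cs log centroid size used to restore size (defaults to
#'   `covariate_value`).
#' @return `m x 3` matrix of landmark coordinates (mm).
#' @export
warp_along_regression <- function(regression, covariate_value,
                                  ln_cs = covariate_value) {
  rng <- regression$fitted_range
  if (covariate_value < rng[1] || covariate_value > rng[2])
    warning("covariate value outside the fitted range: extrapolating")
  flat <- regression$intercept + regression$coefficients * covariate_value
  shape <- matrix(flat, ncol = 3, byrow = TRUE)
  shape * exp(ln_cs)
}

#' Remove similarity components from a shape-space displacement field
#'
#' Projects out the translation, scaling and rotation directions at a
#' reference shape, leaving the pure shape-change part of a displacement
#' field; used to compare estimated allometric vectors with the generator's
#' stored field on equal footing.
#'
#' @param v `m x 3` matrix (or flattened vector) displacement field.
#' @param shape `m x 3` reference (unit-size, centred) shape.
#' @return flattened projected field.
#' @export
project_out_similarity <- function(v, shape) {
  m <- nrow(shape)
  if (!is.matrix(v)) v <- matrix(v, ncol = 3, byrow = TRUE)
  basis <- cbind(
    as.vector(t(cbind(rep(1, m), 0, 0))),
    as.vector(t(cbind(0, rep(1, m), 0))),
    as.vector(t(cbind(0, 0, rep(1, m)))),
    as.vector(t(shape)),
    as.vector(t(shape %*% rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)))),
    as.vector(t(shape %*% rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)))),
    as.vector(t(shape %*% rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))))
  q <- qr.Q(qr(basis))
  vf <- as.vector(t(v))
  vf - q %*% crossprod(q, vf)
}
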