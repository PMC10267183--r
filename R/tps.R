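#' Fit a 3D thin-plate-spline interpolant
#'
#' Fits the triplet of thin plate splines mapping `source` exactly onto
#' `target`, with the kernel `U(r) = r` standard for 3D landmark data
#' (entered with the negative sign convention, which makes the bending
#' energy quadratic form positive semidefinite). The
#' affine part and the non-affine kernel weights are returned separately;
#' the weights satisfy the usual orthogonality side conditions (they sum to
#' zero and are orthogonal to the source coordinates per output dimension).
#'
#' A small Tikhonov jitter (default `1e-10`) is added to the kernel block so
#' near-degenerate configurations still solve; it is small enough that the
#' interpolation error stays below 1e-8 mm on mm-scale data.
#'
#' @param source,target `k x 3` matrices (or `cm_landmarks`) with `k >= 4`,
#'   source non-coplanar.
#' @param lambda Tikhonov jitter added to the kernel diagonal.
#' @return object of class `cm_tps` with elements `source`, `weights`
#'   (`k x 3`), `affine` (`4 x 3`, row 1 the translation).
#' @export
tps_fit <- function(source, target, lambda = 1e-10) {
  source <- lm_coords(source)
  target <- lm_coords(target)
  k <- nrow(source)
  if (nrow(target) != k) stop("source and target point counts differ")
  if (k < 4) stop("at least 4 points are required for a 3D TPS")
  sv <- svd(scale(source, scale = FALSE))$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("singular configuration: source points are (nearly) coplanar")
  K0 <- -as.matrix(stats::dist(source))
  P <- cbind(1, source)
  L0 <- rbind(cbind(K0, P), cbind(t(P), matrix(0, 4, 4)))
  L <- rbind(cbind(K0 - diag(lambda, k), P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  # one step of iterative refinement against the unjittered system removes
  # the O(lambda) interpolation bias of the regularised solve
  sol <- sol + solve(L, rhs - L0 %*% sol)
  structure(list(source = source,
                 weights = sol[1:k, , drop = FALSE],
                 affine = sol[(k + 1):(k + 4), , drop = FALSE],
                 lambda = lambda),
            class = "cm_tps")
}

#' Apply a fitted thin-plate spline to points
#' @param tps a `cm_tps` from [tps_fit()].
#' @param points `n x 3` matrix.
#' @return `n x 3` matrix of warped points.
#' @export
tps_apply <- function(tps, points) {
  points <- matrix(as.numeric(lm_coords(points)), ncol = 3)
  U <- -cross_dist(points, tps$source)
  U %*% tps$weights + cbind(1, points) %*% tps$affine
}

cross_dist <- function(a, b, chunk = 2048L) {
  # per-coordinate differences avoid the cancellation of the outer-product
  # formula near r = 0, where the kernel must vanish exactly
  n <- nrow(a)
  out <- matrix(NA_real_, n, nrow(b))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(a[s:e, 1], b[, 1], "-")
    dy <- outer(a[s:e, 2], b[, 2], "-")
    dz <- outer(a[s:e, 3], b[, 3], "-")
    out[s:e, ] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  out
}

#' Bending-energy matrix of a landmark configuration
#'
#' Returns the symmetric positive-semidefinite `k x k` matrix `B` such that
#' for any target configuration (or displacement field) `Y` over the
#' landmarks, the thin-plate-spline bending energy of the interpolating map
#' is `sum(diag(t(Y) %*% B %*% Y))`. Affine fields lie in its null space.
#'
#' @param landmarks `k x 3` matrix (or `cm_landmarks`), non-degenerate.
#' @param lambda Tikhonov jitter on the kernel block.
#' @export
bending_energy_matrix <- function(landmarks, lambda = 1e-10) {
  x <- lm_coords(landmarks)
  k <- nrow(x)
  if (k < 4) stop("at least 4 points required")
  sv <- svd(scale(x, scale = FALSE))$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("degenerate configuration: points are (nearly) coplanar")
  K <- -as.matrix(stats::dist(x))
  K <- K - diag(lambda, k)
  P <- cbind(1, x)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Linv <- solve(L)
  B <- Linv[1:k, 1:k, drop = FALSE]
  (B + t(B)) / 2
}

#' Thin-plate-spline bending energy of a map between two configurations
#' @param B bending-energy matrix of the reference (from
#'   [bending_energy_matrix()]).
#' @param target `k x 3` target configuration (or displacement field).
#' @export
bending_energy <- function(B, target) {
  y <- lm_coords(target)
  sum(y * (B %*% y))
}
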