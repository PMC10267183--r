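#' Centroid size of a configuration
#'
#' Square root of the summed squared deviations of the points from their
#' centroid, in mm; the size measure whose natural logarithm (Ln(CS))
#' augments the shape matrix to form the form matrix.
#'
#' @param config `k x 3` matrix or `cm_landmarks`.
#' @export
centroid_size <- function(config) {
  x <- lm_coords(config)
  if (nrow(x) < 1) stop("empty configuration")
  sqrt(sum(sweep(x, 2, colMeans(x))^2))
}

# center and scale to unit centroid size
unit_shape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs == 0) stop("degenerate configuration with zero centroid size")
  x / cs
}

# deterministic canonical orientation for a centred configuration: principal
# axes ordered by extent; each axis sign set so the lowest-index point with a
# dominant coordinate on that axis is positive (stable even for bilaterally
# near-symmetric configurations); proper rotation enforced last
canonical_orientation <- function(m) {
  R <- svd(m)$v
  for (j in 1:3) {
    cj <- m %*% R[, j]
    anchor <- which(abs(cj) >= 0.5 * max(abs(cj)))[1]
    if (cj[anchor] < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# optimal rotation of (centered) a onto b; proper rotation unless
# allow_reflection
optimal_rotation <- function(a, b, allow_reflection = FALSE) {
  s <- svd(crossprod(a, b))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Ordinary Procrustes superimposition of one configuration onto another
#'
#' Optimal translation, unit-centroid-size scaling and rotation of `moving`
#' onto `fixed`; the returned distance is the root summed squared residual
#' between the two unit-size shapes (partial Procrustes distance).
#'
#' @param moving,fixed `k x 3` matrices or `cm_landmarks` with equal counts,
#'   `k >= 3`.
#' @param allow_reflection permit improper rotations.
#' @return list: `aligned` (`k x 3`, the moved unit-size shape), `rotation`,
#'   `distance`.
#' @export
ordinary_procrustes <- function(moving, fixed, allow_reflection = FALSE) {
  m <- lm_coords(moving); fx <- lm_coords(fixed)
  if (nrow(m) != nrow(fx)) stop("configurations have different point counts")
  if (nrow(m) < 3) stop("need at least 3 points")
  mu <- unit_shape(m); fu <- unit_shape(fx)
  R <- optimal_rotation(mu, fu, allow_reflection)
  aligned <- mu %*% R
  list(aligned = aligned, rotation = R,
       distance = sqrt(sum((aligned - fu)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a sample of configurations: each is
#' translated to the origin, scaled to unit centroid size (full Procrustes;
#' size is re-attached downstream as the Ln(CS) column of the form matrix)
#' and rotated to the current mean; the mean is renormalised and the loop
#' repeats until its relative change falls below `tol` (default `1e-10`) or
#' `max_iter` iterations. Rotations are proper: reflections are never used,
#' as mirrored crania would be anatomically invalid.
#'
#' Points flagged `gpa_excluded` (the Euryon pair on the standard roster)
#' are left out of the superimposition when `exclude_flagged = TRUE`, but
#' are carried along under each specimen's fitted transform so dimensions
#' using them remain computable.
#'
#' @param configs list of `cm_landmarks` (sharing one roster) or a
#'   `k x 3 x n` array.
#' @param exclude_flagged drop `gpa_excluded` points from the fit.
#' @param tol relative mean-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `cm_gpa`: `shapes` (`m x 3 x n` aligned unit-size
#'   shapes), `shape_matrix` (`n x 3m`), `mean_shape` (`m x 3`, unit CS),
#'   `centroid_sizes`, `ln_cs`, `names` (point names used), `excluded`
#'   (aligned coordinates of flagged points, or NULL), `iterations`.
#' @export
gpa <- function(configs, exclude_flagged = TRUE, tol = 1e-10, max_iter = 100) {
  if (is.array(configs) && length(dim(configs)) == 3) {
    configs <- lapply(seq_len(dim(configs)[3]), function(i)
      landmark_set(configs[, , i]))
  }
  n <- length(configs)
  if (n < 2) stop("GPA needs at least 2 configurations")
  roster <- rownames(configs[[1]]$coords)
  for (i in seq_along(configs)) {
    ri <- rownames(configs[[i]]$coords)
    if (!identical(ri, roster)) {
      miss <- setdiff(roster, ri)
      stop("configuration ", i, " does not share the roster",
           if (length(miss)) paste0("; missing: ",
                                    paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  flag <- configs[[1]]$gpa_excluded
  use <- if (exclude_flagged) which(!flag) else seq_along(flag)
  m <- length(use)
  cs <- numeric(n)
  shapes <- array(NA_real_, c(m, 3, n))
  aux <- NULL
  has_aux <- exclude_flagged && any(flag)
  if (has_aux) aux <- array(NA_real_, c(sum(flag), 3, n))
  centred <- vector("list", n)
  for (i in seq_len(n)) {
    x <- configs[[i]]$coords[use, , drop = FALSE]
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    cs[i] <- sqrt(sum(xc^2))
    shapes[, , i] <- xc / cs[i]
    if (has_aux)
      aux[, , i] <- sweep(configs[[i]]$coords[which(flag), , drop = FALSE],
                          2, ctr) / cs[i]
  }
  mean_shape <- unit_shape(shapes[, , 1])
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) {
      R <- optimal_rotation(shapes[, , i], mean_shape)
      shapes[, , i] <- shapes[, , i] %*% R
      if (has_aux) aux[, , i] <- aux[, , i] %*% R
    }
    new_mean <- unit_shape(apply(shapes, c(1, 2), mean))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || it >= max_iter) break
  }
  # canonicalise the arbitrary global orientation: principal axes of the
  # mean with a deterministic per-axis sign rule, so GPA output is
  # invariant to similarity transforms of the inputs
  Rc <- canonical_orientation(mean_shape)
  mean_shape <- mean_shape %*% Rc
  for (i in seq_len(n)) {
    shapes[, , i] <- shapes[, , i] %*% Rc
    if (has_aux) aux[, , i] <- aux[, , i] %*% Rc
  }
  shape_matrix <- t(apply(shapes, 3, function(s) as.vector(t(s))))
  colnames(shape_matrix) <- as.vector(t(outer(roster[use], c("x", "y", "z"),
                                              paste, sep = ".")))
  ids <- names(configs)
  if (!is.null(ids)) rownames(shape_matrix) <- ids
  structure(list(shapes = shapes, shape_matrix = shape_matrix,
                 mean_shape = mean_shape,
                 centroid_sizes = cs, ln_cs = log(cs),
                 names = roster[use],
                 excluded = aux,
                 excluded_names = roster[flag],
                 iterations = it),
            class = "cm_gpa")
}

#' @export
print.cm_gpa <- function(x, ...) {
  cat("cm_gpa:", dim(x$shapes)[3], "specimens,", dim(x$shapes)[1],
      "points superimposed,", length(x$excluded_names),
      "flagged points carried\n")
  invisible(x)
}

#' Procrustes distance between two unit-size shapes
#' @param a,b `k x 3` matrices or `cm_landmarks`.
#' @param allow_reflection permit improper rotations.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  ordinary_procrustes(a, b, allow_reflection)$distance
}
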