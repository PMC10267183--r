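#' Evenly sample points on a labelled surface patch
#'
#' Draws a dense candidate cloud on the faces carrying `patch_label`
#' (random barycentric points, area-weighted) and thins it to `count`
#' points by greedy farthest-point sampling, which yields an approximately
#' even distribution regardless of triangulation density.
#'
#' @param mesh a `cm_mesh` with `patch_labels`.
#' @param patch_label the patch to sample.
#' @param count number of points (>= 1).
#' @param seed integer seed for the candidate cloud.
#' @param oversample candidate-cloud size multiplier.
#' @return `count x 3` matrix of surface points.
#' @export
sample_patch <- function(mesh, patch_label, count, seed = 1,
                         oversample = 12) {
  if (is.null(mesh$patch_labels)) stop("mesh has no patch labels")
  fidx <- which(!is.na(mesh$patch_labels) & mesh$patch_labels == patch_label)
  if (length(fidx) == 0) stop("patch not found: ", patch_label)
  areas <- face_areas(mesh)[fidx]
  if (sum(areas) <= 0) stop("patch has zero area")
  n_cand <- max(count * oversample, 500)
  if (count > n_cand) stop("count exceeds the candidate budget; refine the mesh")
  cand <- with_local_seed(seed, function() {
    pick <- sample(fidx, n_cand, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n_cand))
    r2 <- stats::runif(n_cand)
    a <- mesh$vertices[mesh$faces[pick, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[pick, 2], , drop = FALSE]
    c <- mesh$vertices[mesh$faces[pick, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
  })
  # greedy farthest-point thinning, started from the candidate nearest the
  # patch centroid for determinism
  ctr <- colMeans(cand)
  sel <- integer(count)
  d0 <- rowSums(sweep(cand, 2, ctr)^2)
  sel[1] <- which.min(d0)
  mind <- rowSums(sweep(cand, 2, cand[sel[1], ])^2)
  if (count > 1) {
    for (i in 2:count) {
      sel[i] <- which.max(mind)
      dd <- rowSums(sweep(cand, 2, cand[sel[i], ])^2)
      mind <- pmin(mind, dd)
    }
  }
  cand[sel, , drop = FALSE]
}

#' Build the surface semilandmark template
#'
#' Samples each labelled patch on one side of the reference skull
#' (midfacial, calvarial, lower occipital), mirrors the sample across the
#' midsagittal plane, projects the mirrored points back onto the surface
#' and concatenates both sides in a fixed order (per patch: left block then
#' right block). With the standard counts (100 / 1000 / 52 per side) this
#' yields 2304 semilandmarks: 200 over the mid-face and 2104 over the
#' neurocranium (calvarial + lower occipital).
#'
#' @param reference a template `cm_specimen` (or any object with `$shell`
#'   and `$landmarks`).
#' @param counts named one-side counts per patch.
#' @param seed integer.
#' @return object of class `cm_slm_template`: `points` (`s x 3`), `patch`,
#'   `side`, `counts`, `anchor_landmarks` (the reference `cm_landmarks`),
#'   `reference_mesh`, `seed`.
#' @export
build_slm_template <- function(reference,
                               counts = c(midfacial = 100, calvarial = 1000,
                                          lower_occipital = 52),
                               seed = 1) {
  mesh <- reference$shell
  lms <- reference$landmarks
  plane <- midsagittal_plane(lms)
  pts <- NULL; patch <- character(0); side <- character(0)
  for (pn in names(counts)) {
    p_l <- sample_patch(mesh, pn, counts[[pn]],
                        seed = seed + match(pn, names(counts)))
    p_r_raw <- mirror_points(p_l, plane)
    p_r <- closest_point_on_mesh(mesh, p_r_raw)$points
    pts <- rbind(pts, p_l, p_r)
    patch <- c(patch, rep(pn, 2 * counts[[pn]]))
    side <- c(side, rep("L", counts[[pn]]), rep("R", counts[[pn]]))
  }
  total <- sum(counts) * 2
  stopifnot(nrow(pts) == total)
  structure(list(points = pts, patch = patch, side = side,
                 counts = counts, anchor_landmarks = lms,
                 reference_mesh = mesh, seed = seed),
            class = "cm_slm_template")
}

#' @export
print.cm_slm_template <- function(x, ...) {
  tab <- table(x$patch)
  cat("cm_slm_template:", nrow(x$points), "semilandmarks (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Semilandmark counts by region
#' @param template a `cm_slm_template`.
#' @return named vector: total, midface, neurocranium.
#' @export
slm_region_counts <- function(template) {
  c(total = nrow(template$points),
    midface = sum(template$patch == "midfacial"),
    neurocranium = sum(template$patch %in% c("calvarial", "lower_occipital")))
}

#' Project the semilandmark template onto a target specimen
#'
#' A thin-plate spline anchored on the landmark roster warps the template
#' semilandmarks toward the target, and the warped points are then
#' projected to the target surface by closest-point search.
#'
#' @param template a `cm_slm_template`.
#' @param target_mesh the target's outer-shell `cm_mesh`.
#' @param target_lms the target's `cm_landmarks` covering the anchor
#'   roster.
#' @return `s x 3` matrix of initial semilandmark positions on the target.
#' @export
project_slm_template <- function(template, target_mesh, target_lms) {
  anchor <- template$anchor_landmarks
  miss <- setdiff(rownames(anchor$coords), rownames(target_lms$coords))
  if (length(miss))
    stop("target is missing anchor landmarks: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tgt <- target_lms$coords[rownames(anchor$coords), , drop = FALSE]
  tps <- tps_fit(anchor$coords, tgt)
  warped <- tps_apply(tps, template$points)
  closest_point_on_mesh(target_mesh, warped)$points
}

# orthonormal tangent basis at surface points: barycentric-interpolated
# area-weighted vertex normals at the closest surface location
surface_tangent_basis <- function(mesh, points) {
  vn <- vertex_normals(mesh)
  cp <- closest_point_on_mesh(mesh, points)
  f <- mesh$faces[cp$face, , drop = FALSE]
  # barycentric coordinates of the projected points in their faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  v0 <- b - a; v1 <- c - a; v2 <- cp$points - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01^2
  wb <- (d11 * d20 - d01 * d21) / den
  wc <- (d00 * d21 - d01 * d20) / den
  wa <- 1 - wb - wc
  nrm <- wa * vn[f[, 1], , drop = FALSE] + wb * vn[f[, 2], , drop = FALSE] +
    wc * vn[f[, 3], , drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # stable tangent pair per point
  ref <- matrix(rep(c(1, 0, 0), each = nrow(nrm)), ncol = 3)
  swap <- abs(nrm[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  t1 <- cbind(nrm[, 2] * ref[, 3] - nrm[, 3] * ref[, 2],
              nrm[, 3] * ref[, 1] - nrm[, 1] * ref[, 3],
              nrm[, 1] * ref[, 2] - nrm[, 2] * ref[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  list(t1 = t1, t2 = t2, normal = nrm, projected = cp$points)
}

#' Slide semilandmarks by bending-energy minimisation
#'
#' Minimises the thin-plate-spline bending energy of the map from the
#' reference configuration (anchor landmarks plus template semilandmarks)
#' to the target configuration, by letting each semilandmark move within
#' its local tangent plane (closed-form solve against the bending-energy
#' matrix restricted to the tangent directions) and re-projecting to the
#' surface after each iteration; anchor landmarks stay fixed throughout.
#' Iterations that would raise the energy are rejected and sliding stops.
#'
#' @param slm_init `s x 3` initial semilandmarks on the target surface.
#' @param target_mesh the target's outer-shell `cm_mesh`.
#' @param target_lms the target's anchor `cm_landmarks`.
#' @param reference a `cm_slm_template` (or list with `anchor_landmarks`
#'   and `points`) defining the reference configuration.
#' @param max_iter iteration cap.
#' @param tol relative energy-change stopping tolerance.
#' @param ridge small diagonal regulariser for the tangent solve.
#' @return list: `slm` (slid points), `energy_trace`, `iterations`.
#' @export
slide_semilandmarks <- function(slm_init, target_mesh, target_lms,
                                reference, max_iter = 3, tol = 1e-6,
                                ridge = 1e-10) {
  ref_all <- rbind(reference$anchor_landmarks$coords, reference$points)
  k_lm <- nrow(reference$anchor_landmarks$coords)
  s <- nrow(reference$points)
  if (nrow(slm_init) != s) stop("semilandmark count mismatch with reference")
  B <- bending_energy_matrix(ref_all)
  if (any(!is.finite(B))) stop("degenerate reference: non-finite bending energy")
  tgt_lm <- target_lms$coords[rownames(reference$anchor_landmarks$coords), ,
                              drop = FALSE]
  slm <- as.matrix(slm_init)
  Y <- rbind(tgt_lm, slm)
  energy <- bending_energy(B, Y)
  trace <- energy
  idx_s <- (k_lm + 1):(k_lm + s)
  B_ss <- B[idx_s, idx_s, drop = FALSE]
  for (it in seq_len(max_iter)) {
    basis <- surface_tangent_basis(target_mesh, slm)
    # 2s x 3 stacked tangent vectors: rows (2i-1, 2i) are t1_i, t2_i
    Tall <- matrix(0, 2 * s, 3)
    Tall[seq(1, 2 * s, 2), ] <- basis$t1
    Tall[seq(2, 2 * s, 2), ] <- basis$t2
    M <- Tall %*% t(Tall)
    Bk <- B_ss[rep(seq_len(s), each = 2), rep(seq_len(s), each = 2)]
    A <- Bk * M
    G <- (B %*% Y)[idx_s, , drop = FALSE]
    g <- -as.vector(t(cbind(rowSums(basis$t1 * G), rowSums(basis$t2 * G))))
    tcoef <- tryCatch(solve(A + diag(ridge * max(diag(A)), 2 * s), g),
                      error = function(e) stop("tangent solve failed: ",
                                               conditionMessage(e)))
    step1 <- tcoef[seq(1, 2 * s, 2)]
    step2 <- tcoef[seq(2, 2 * s, 2)]
    slm_new <- slm + step1 * basis$t1 + step2 * basis$t2
    slm_new <- closest_point_on_mesh(target_mesh, slm_new)$points
    Y_new <- rbind(tgt_lm, slm_new)
    e_new <- bending_energy(B, Y_new)
    if (!is.finite(e_new)) stop("non-finite bending energy during sliding")
    if (e_new > energy * (1 + 1e-9)) break  # reject energy increase
    slm <- slm_new
    Y <- Y_new
    rel <- if (energy > 0) abs(energy - e_new) / energy else 0
    energy <- e_new
    trace <- c(trace, e_new)
    if (rel < tol) break
  }
  list(slm = slm, energy_trace = trace, iterations = length(trace) - 1L)
}

#' Project and slide the template over every specimen of a cohort
#'
#' Convenience wrapper: for each specimen, [project_slm_template()] then
#' [slide_semilandmarks()], returning combined landmark + semilandmark
#' configurations ready for GPA.
#'
#' @param cohort a `cm_cohort` with meshes.
#' @param template a `cm_slm_template`.
#' @param max_iter,tol sliding controls.
#' @return named list of `cm_landmarks` (88 LMs + semilandmarks each).
#' @export
slide_cohort <- function(cohort, template, max_iter = 3, tol = 1e-6) {
  out <- vector("list", length(cohort$specimens))
  names(out) <- names(cohort$specimens)
  slm_names <- sprintf("SLM%04d", seq_len(nrow(template$points)))
  for (id in names(cohort$specimens)) {
    sp <- cohort$specimens[[id]]
    if (is.null(sp$shell)) stop("specimen ", id, " has no mesh")
    init <- project_slm_template(template, sp$shell, sp$landmarks)
    slid <- slide_semilandmarks(init, sp$shell, sp$landmarks, template,
                                max_iter = max_iter, tol = tol)
    lm <- sp$landmarks
    all_coords <- rbind(lm$coords, slid$slm)
    out[[id]] <- landmark_set(
      all_coords,
      names = c(rownames(lm$coords), slm_names),
      role = c(lm$role, rep("SLM", nrow(slid$slm))),
      side = c(lm$side, template$side),
      gpa_excluded = c(lm$gpa_excluded, rep(FALSE, nrow(slid$slm))))
  }
  out
}
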