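#' Construct a triangulated surface mesh
#'
#' A mesh is a list of `vertices` (numeric `v x 3` matrix, mm) and `faces`
#' (integer `f x 3` matrix of vertex indices, counter-clockwise when seen
#' from outside). An optional character vector `patch_labels` tags each face
#' with a named surface patch (e.g. `"midfacial"`); untagged faces carry
#' `NA`.
#'
#' @param vertices numeric matrix, one 3D point per row (mm).
#' @param faces integer matrix, one triangle per row (1-based vertex indices).
#' @param patch_labels optional character vector, one label per face.
#' @param drop_degenerate drop zero-area faces instead of erroring.
#' @return an object of class `cm_mesh`.
#' @export
cm_mesh <- function(vertices, faces, patch_labels = NULL,
                    drop_degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("vertices must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a <- face_areas_internal(vertices, faces)
  if (any(a <= 0)) {
    if (drop_degenerate) {
      keep <- a > 0
      faces <- faces[keep, , drop = FALSE]
      if (!is.null(patch_labels)) patch_labels <- patch_labels[keep]
    } else {
      stop("mesh has ", sum(a <= 0), " degenerate (zero-area) faces")
    }
  }
  if (!is.null(patch_labels) && length(patch_labels) != nrow(faces))
    stop("patch_labels must have one entry per face")
  structure(list(vertices = vertices, faces = faces,
                 patch_labels = patch_labels),
            class = "cm_mesh")
}

#' @export
print.cm_mesh <- function(x, ...) {
  cat("cm_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (!is.null(x$patch_labels)) {
    tab <- table(x$patch_labels, useNA = "no")
    cat("patches:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

face_corner <- function(mesh, j) mesh$vertices[mesh$faces[, j], , drop = FALSE]

face_areas_internal <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-face triangle areas (mm^2)
#' @param mesh a `cm_mesh`.
#' @export
face_areas <- function(mesh) face_areas_internal(mesh$vertices, mesh$faces)

#' Per-face outward normals (unit vectors)
#' @param mesh a `cm_mesh`.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Area-weighted vertex normals
#' @param mesh a `cm_mesh`.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  fa <- face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    for (d in 1:3) {
      n[, d] <- n[, d] + unname(tapply2_sum(fn[, d] * fa, idx, nrow(n)))
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# fast grouped sum into a vector of length n
tapply2_sum <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

mesh_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

# undirected edge table: one row per half-edge (face, v1, v2)
half_edges <- function(faces) {
  f <- faces
  rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
}

edge_keys <- function(e) {
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  paste(lo, hi, sep = "-")
}

#' Watertightness report for a mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite orientation.
#'
#' @param mesh a `cm_mesh`.
#' @return list with `watertight` flag, `n_boundary_edges`, and
#'   `consistent_orientation`.
#' @export
mesh_watertight <- function(mesh) {
  he <- half_edges(mesh$faces)
  key <- edge_keys(he)
  cnt <- table(key)
  n_bad <- sum(cnt != 2L)
  # orientation: each undirected edge should appear once in each direction
  dir_key <- paste(he[, 1], he[, 2], sep = "-")
  consistent <- !any(duplicated(dir_key))
  list(watertight = (n_bad == 0L) && consistent,
       n_boundary_edges = sum(cnt == 1L),
       consistent_orientation = consistent)
}

#' Enclosed volume of a closed triangulated mesh (mm^3)
#'
#' Divergence-theorem signed volume, returned as an absolute value. A
#' reversed-orientation (inward-facing) mesh gives the same value with a
#' warning.
#'
#' @param mesh a watertight `cm_mesh`.
#' @export
closed_mesh_volume <- function(mesh) {
  wt <- mesh_watertight(mesh)
  if (!wt$watertight && wt$n_boundary_edges > 0)
    stop("mesh is not watertight: ", wt$n_boundary_edges, " open edges")
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  # signed tetra volumes against the origin
  sv <- (p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
         p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
         p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  vol <- sum(sv)
  if (vol < 0)
    warning("mesh orientation is inward-facing; returning absolute volume")
  abs(vol)
}

#' Connected components of a mesh (by shared vertices)
#' @param mesh a `cm_mesh`.
#' @return integer vector of component ids, one per face.
#' @export
mesh_components <- function(mesh) {
  # union-find over vertices
  parent <- seq_len(nrow(mesh$vertices))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a; parent[find(c)] <- a
  }
  roots <- vapply(f[, 1], find, integer(1))
  match(roots, unique(roots))
}

subset_mesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  cm_mesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[f], ncol = 3L),
          patch_labels = if (!is.null(mesh$patch_labels))
            mesh$patch_labels[face_idx] else NULL)
}

#' Boundary loops of an open mesh
#' @param mesh a `cm_mesh`.
#' @return list of integer vectors, each an ordered cycle of vertex indices.
#' @export
boundary_loops <- function(mesh) {
  he <- half_edges(mesh$faces)
  key <- edge_keys(he)
  cnt <- table(key)
  open_key <- names(cnt)[cnt == 1L]
  if (length(open_key) == 0) return(list())
  open <- he[key %in% open_key, , drop = FALSE]
  # boundary half-edges run opposite to interior winding; chain v2 -> v1
  nxt <- stats::setNames(open[, 1], as.character(open[, 2]))
  loops <- list()
  todo <- stats::setNames(rep(TRUE, nrow(open)), as.character(open[, 2]))
  for (start in as.character(open[, 2])) {
    if (!todo[[start]]) next
    loop <- integer(0)
    cur <- start
    repeat {
      todo[[cur]] <- FALSE
      loop <- c(loop, as.integer(cur))
      nx <- as.character(nxt[[cur]])
      if (identical(nx, start)) break
      if (is.null(nxt[[nx]])) stop("non-closable boundary loop")
      cur <- nx
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Cap all boundary loops of a mesh with triangle fans
#'
#' Each open loop is closed with a fan of triangles about the loop centroid,
#' wound so the cap continues the surface orientation.
#'
#' @param mesh a `cm_mesh` with one or more boundary loops.
#' @return a watertight `cm_mesh`.
#' @export
cap_boundary_loops <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  labs <- mesh$patch_labels
  for (loop in loops) {
    centroid <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    k <- length(loop)
    new_f <- cbind(loop, c(loop[-1], loop[1]), rep(ci, k))
    f <- rbind(f, new_f)
    if (!is.null(labs)) labs <- c(labs, rep("cap", k))
  }
  out <- cm_mesh(v, f, patch_labels = labs)
  wt <- mesh_watertight(out)
  if (!wt$watertight)
    stop("capping failed to produce a watertight mesh (",
         wt$n_boundary_edges, " open edges remain)")
  out
}

#' Test whether a point lies inside a closed mesh
#'
#' Ray-crossing parity along three fixed pseudo-random directions, by
#' majority vote, so points near a face plane are still classified robustly.
#'
#' @param mesh a watertight `cm_mesh`.
#' @param point numeric length-3.
#' @export
point_in_mesh <- function(mesh, point) {
  dirs <- rbind(c(0.2870, 0.5253, 0.8011),
                c(-0.6551, 0.7224, 0.2215),
                c(0.5917, -0.3712, 0.7157))
  votes <- vapply(seq_len(nrow(dirs)), function(i) {
    n_hit <- ray_mesh_crossings(mesh, point, dirs[i, ])
    (n_hit %% 2L) == 1L
  }, logical(1))
  sum(votes) >= 2
}

# Moller-Trumbore, vectorised over faces; counts crossings with t > 0
ray_mesh_crossings <- function(mesh, origin, dir) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(-p1, 2, origin, "+")   # origin - p1
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
  tt <- rowSums(e2 * q) / a
  hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
  sum(hit)
}

#' Perimeter of a planar cross-section of a mesh
#'
#' Cuts the mesh with the plane through `p1` and `p2` perpendicular to the
#' midsagittal plane (given by its unit normal), chains the intersection
#' segments into closed polylines and returns the perimeter of the longest
#' one. This is the construction used for the cranial-circumference
#' dimension.
#'
#' @param mesh a `cm_mesh`.
#' @param p1,p2 numeric length-3 points the plane passes through (mm).
#' @param midsagittal_normal unit normal of the midsagittal plane.
#' @return perimeter in mm.
#' @export
plane_circumference <- function(mesh, p1, p2, midsagittal_normal) {
  d12 <- p2 - p1
  n <- c(d12[2] * midsagittal_normal[3] - d12[3] * midsagittal_normal[2],
         d12[3] * midsagittal_normal[1] - d12[1] * midsagittal_normal[3],
         d12[1] * midsagittal_normal[2] - d12[2] * midsagittal_normal[1])
  ln <- sqrt(sum(n^2))
  if (ln < 1e-9 * sqrt(sum(d12^2)))
    stop("ambiguous plane: p1-p2 direction is parallel to the midsagittal normal")
  n <- n / ln
  v <- mesh$vertices
  dist <- as.vector(v %*% n) - sum(n * p1)
  # nudge exact-zero vertices off the plane for a clean parity of crossings
  dist[abs(dist) < 1e-12] <- 1e-12
  f <- mesh$faces
  s1 <- dist[f[, 1]]; s2 <- dist[f[, 2]]; s3 <- dist[f[, 3]]
  cut <- !(sign(s1) == sign(s2) & sign(s2) == sign(s3))
  if (!any(cut)) stop("plane does not intersect the mesh")
  fc <- f[cut, , drop = FALSE]
  segs_from <- character(0); segs_to <- character(0)
  pts <- list()
  edge_point <- function(i, j) {
    di <- dist[i]; dj <- dist[j]
    w <- di / (di - dj)
    v[i, ] + w * (v[j, ] - v[i, ])
  }
  seg_a <- list(); seg_b <- list(); key_a <- character(0); key_b <- character(0)
  for (r in seq_len(nrow(fc))) {
    tri <- fc[r, ]
    dd <- dist[tri]
    crossing <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tri[e[1]]; j <- tri[e[2]]
      if (sign(dist[i]) != sign(dist[j])) {
        k <- paste(min(i, j), max(i, j), sep = "-")
        crossing[[length(crossing) + 1L]] <- list(key = k, p = edge_point(i, j))
      }
    }
    if (length(crossing) == 2L) {
      seg_a[[length(seg_a) + 1L]] <- crossing[[1]]$p
      seg_b[[length(seg_b) + 1L]] <- crossing[[2]]$p
      key_a <- c(key_a, crossing[[1]]$key)
      key_b <- c(key_b, crossing[[2]]$key)
    }
  }
  if (length(seg_a) == 0) stop("plane does not intersect the mesh")
  # chain segments into loops via shared mesh-edge keys
  nseg <- length(seg_a)
  used <- rep(FALSE, nseg)
  best <- 0
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    # walk from segment s0
    perim <- 0
    cur <- s0
    enter_key <- key_a[s0]
    start_key <- enter_key
    closed <- FALSE
    repeat {
      used[cur] <- TRUE
      pa <- seg_a[[cur]]; pb <- seg_b[[cur]]
      perim <- perim + sqrt(sum((pa - pb)^2))
      exit_key <- if (identical(enter_key, key_a[cur])) key_b[cur] else key_a[cur]
      if (identical(exit_key, start_key)) { closed <- TRUE; break }
      nxt <- which(!used & (key_a == exit_key | key_b == exit_key))
      if (length(nxt) == 0) break
      cur <- nxt[1]
      enter_key <- exit_key
    }
    if (closed && perim > best) best <- perim
  }
  if (best == 0) stop("no closed intersection polyline found")
  best
}

#' Per-face percent area change between two topology-identical meshes
#'
#' For each corresponding face the percent change
#' `(area_target - area_reference) / area_reference * 100` is reported.
#' Correspondence is by face index: both meshes must derive from a common
#' template.
#'
#' @param reference,target `cm_mesh` objects with identical face matrices.
#' @return list of class `cm_area_change`: `percent` per face, `range`.
#' @export
area_change_map <- function(reference, target) {
  if (!identical(dim(reference$faces), dim(target$faces)) ||
      !identical(reference$faces, target$faces))
    stop("meshes do not share face topology")
  ar <- face_areas(reference)
  at <- face_areas(target)
  pct <- (at - ar) / ar * 100
  structure(list(percent = pct, range = range(pct)),
            class = "cm_area_change")
}

#' @export
print.cm_area_change <- function(x, ...) {
  cat(sprintf("area change over %d faces: min %.2f%%, max %.2f%%\n",
              length(x$percent), x$range[1], x$range[2]))
  invisible(x)
}

#' Export a per-face scalar field as CSV (face_index, value)
#' @param map a `cm_area_change` (or numeric vector).
#' @param path output path.
#' @export
write_face_scalar_csv <- function(map, path) {
  val <- if (inherits(map, "cm_area_change")) map$percent else map
  utils::write.csv(data.frame(face_index = seq_along(val), percent = val),
                   path, row.names = FALSE)
}

# ---- sphere / ellipsoid primitives -----------------------------------------

#' Subdivided icosahedral sphere mesh
#'
#' @param subdiv number of midpoint-subdivision rounds (0 = icosahedron).
#' @return unit-radius `cm_mesh`, symmetric about all coordinate planes.
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j), sep = "-")
      got <- edge_id[[key]]
      if (!is.null(got)) return(got)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(r - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  cm_mesh(v, f)
}

#' Triaxial ellipsoid mesh from an icosphere
#'
#' Unit-sphere vertices are scaled anisotropically, so vertices lie exactly
#' on the ellipsoid.
#'
#' @param semi_axes numeric length-3 (mm).
#' @param center numeric length-3 (mm).
#' @param subdiv subdivision level passed to [icosphere()].
#' @export
ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), subdiv = 3) {
  s <- icosphere(subdiv)
  v <- sweep(sweep(s$vertices, 2, semi_axes, "*"), 2, center, "+")
  cm_mesh(v, s$faces)
}

#' Cut an aperture into a closed mesh
#'
#' Removes the faces whose centroid direction (from `center`) lies within
#' `half_angle_deg` of `direction`, leaving an open rim.
#'
#' @param mesh a closed `cm_mesh`.
#' @param center reference point for directions.
#' @param direction aperture axis (need not be unit).
#' @param half_angle_deg angular radius of the removed cap.
#' @export
open_aperture <- function(mesh, center, direction, half_angle_deg) {
  d <- direction / sqrt(sum(direction^2))
  cen <- mesh_centroids(mesh)
  u <- sweep(cen, 2, center, "-")
  u <- u / sqrt(rowSums(u^2))
  ang <- acos(pmin(1, pmax(-1, as.vector(u %*% d)))) * 180 / pi
  keep <- ang > half_angle_deg
  if (all(keep)) stop("aperture removed no faces; increase half_angle_deg")
  subset_mesh(mesh, which(keep))
}

#' Merge meshes into one multi-component mesh
#' @param ... `cm_mesh` objects.
#' @export
merge_meshes <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "cm_mesh"))
    parts <- parts[[1]]
  v <- NULL; f <- NULL; labs <- character(0)
  any_lab <- any(vapply(parts, function(m) !is.null(m$patch_labels), logical(1)))
  for (m in parts) {
    off <- if (is.null(v)) 0L else nrow(v)
    v <- rbind(v, m$vertices)
    f <- rbind(f, m$faces + off)
    if (any_lab) {
      l <- m$patch_labels
      if (is.null(l)) l <- rep(NA_character_, nrow(m$faces))
      labs <- c(labs, l)
    }
  }
  cm_mesh(v, f, patch_labels = if (any_lab) labs else NULL)
}

# ---- closest point on mesh --------------------------------------------------

# closest point on each of a set of triangles (Ericson), vectorised over pairs
closest_point_on_triangles <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  out <- matrix(NA_real_, nrow(p), 3)
  done <- rep(FALSE, nrow(p))
  set <- function(idx, val) {
    out[idx, ] <<- val
    done[idx] <<- TRUE
  }
  r1 <- !done & d1 <= 0 & d2 <= 0
  if (any(r1)) set(r1, a[r1, , drop = FALSE])
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  r2 <- !done & d3 >= 0 & d4 <= d3
  if (any(r2)) set(r2, b[r2, , drop = FALSE])
  vc <- d1 * d4 - d3 * d2
  r3 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r3)) {
    w <- (d1 / (d1 - d3))[r3]
    set(r3, a[r3, , drop = FALSE] + w * ab[r3, , drop = FALSE])
  }
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  r4 <- !done & d6 >= 0 & d5 <= d6
  if (any(r4)) set(r4, c[r4, , drop = FALSE])
  vb <- d5 * d2 - d1 * d6
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r5)) {
    w <- (d2 / (d2 - d6))[r5]
    set(r5, a[r5, , drop = FALSE] + w * ac[r5, , drop = FALSE])
  }
  va <- d3 * d6 - d5 * d4
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r6)) {
    w <- ((d4 - d3) / ((d4 - d3) + (d5 - d6)))[r6]
    set(r6, b[r6, , drop = FALSE] + w * (c - b)[r6, , drop = FALSE])
  }
  rest <- !done
  if (any(rest)) {
    denom <- (va + vb + vc)[rest]
    v <- vb[rest] / denom; w <- vc[rest] / denom
    set(rest, a[rest, , drop = FALSE] + v * ab[rest, , drop = FALSE] +
          w * ac[rest, , drop = FALSE])
  }
  out
}

#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the triangulated surface is
#' found by screening the `k_candidates` nearest face centroids and solving
#' the exact point-triangle projection on those.
#'
#' @param mesh a `cm_mesh`.
#' @param points numeric `n x 3` matrix of query points.
#' @param k_candidates number of candidate faces per query.
#' @return list: `points` (projected `n x 3`), `face` (index), `distance`.
#' @export
closest_point_on_mesh <- function(mesh, points, k_candidates = 40) {
  points <- matrix(as.numeric(points), ncol = 3)
  cen <- mesh_centroids(mesh)
  nf <- nrow(cen)
  k <- min(k_candidates, nf)
  n <- nrow(points)
  proj <- matrix(NA_real_, n, 3)
  face <- integer(n)
  dist <- numeric(n)
  chunk <- 256L
  v <- mesh$vertices; f <- mesh$faces
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(cen^2), "+") - 2 * q %*% t(cen)
    ord <- apply(d2, 1, function(z) order(z)[seq_len(k)])
    # build pair arrays
    m <- e - s + 1L
    qi <- rep(seq_len(m), each = k)
    fi <- as.vector(ord)
    pp <- q[qi, , drop = FALSE]
    aa <- v[f[fi, 1], , drop = FALSE]
    bb <- v[f[fi, 2], , drop = FALSE]
    cc <- v[f[fi, 3], , drop = FALSE]
    cpt <- closest_point_on_triangles(pp, aa, bb, cc)
    dd <- rowSums((cpt - pp)^2)
    for (i in seq_len(m)) {
      sel <- which(qi == i)
      j <- sel[which.min(dd[sel])]
      proj[s + i - 1L, ] <- cpt[j, ]
      face[s + i - 1L] <- fi[j]
      dist[s + i - 1L] <- sqrt(dd[j])
    }
  }
  list(points = proj, face = face, distance = dist)
}
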