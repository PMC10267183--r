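#' Cranial volume set with cube-root and proportional views
#'
#' Holds the four cavity volumes — intracranial (ICV), left orbital (LOV),
#' nasal cavity (NCV) and upper intraoral (UIV) — in mm^3, their cube roots
#' (CVols, mm, the transform used to normalise the strongly right-skewed raw
#' volumes) and the proportional contributions of the cube roots to their
#' sum (CPVols, percent; they sum to 100).
#'
#' @param icv,lov,ncv,uiv positive volumes in mm^3.
#' @return object of class `cm_volume_set`.
#' @export
volume_set <- function(icv, lov, ncv, uiv) {
  v <- c(icv = icv, lov = lov, ncv = ncv, uiv = uiv)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all four volumes must be positive and finite")
  cv <- v^(1 / 3)
  names(cv) <- paste0("c", names(v))
  cp <- 100 * cv / sum(cv)
  names(cp) <- paste0("cp", names(v))
  structure(list(volumes = v, cvols = cv, cpvols = cp),
            class = "cm_volume_set")
}

#' @export
print.cm_volume_set <- function(x, ...) {
  cat(sprintf("volumes (mm^3): ICV %.0f, LOV %.0f, NCV %.0f, UIV %.0f\n",
              x$volumes[1], x$volumes[2], x$volumes[3], x$volumes[4]))
  cat(sprintf("CPVols (%%): %.2f / %.2f / %.2f / %.2f\n",
              x$cpvols[1], x$cpvols[2], x$cpvols[3], x$cpvols[4]))
  invisible(x)
}

#' The 47-entry linear dimension table
#'
#' Reads the dimension definitions shipped with the package
#' (`synthetic_dimension_table.csv`): index, name and the two endpoint
#' landmark names, except entry 3 (cranial circumference), which is the
#' perimeter of the section through landmarks Glabella and Opisthocranion
#' perpendicular to the midsagittal plane. The table is editable package
#' data: endpoints are a synthetic stand-in keyed to the classical
#' craniometric dimension names.
#'
#' @param path optional alternative CSV.
#' @return data.frame with columns index, name, endpoint_a, endpoint_b,
#'   special.
#' @export
dimension_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_dimension_table.csv",
                        package = "craniomorph", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df[order(df$index), ]
}

#' Compute the 47 linear cranial dimensions (mm)
#'
#' Euclidean distances between endpoint landmarks for 46 entries; the
#' cranial circumference (entry 3) is measured on the mesh in the plane
#' through its two landmarks perpendicular to the least-squares midsagittal
#' plane of the midline landmarks.
#'
#' @param landmarks a `cm_landmarks` covering the roster.
#' @param mesh the specimen's outer-shell `cm_mesh` (needed only for the
#'   circumference entry; may be NULL, which yields NA there).
#' @param table dimension table (see [dimension_table()]).
#' @return named numeric vector of length 47.
#' @export
linear_dimensions <- function(landmarks, mesh = NULL,
                              table = dimension_table()) {
  cc <- landmarks$coords
  need <- setdiff(unique(c(table$endpoint_a, table$endpoint_b)),
                  rownames(cc))
  if (length(need))
    stop("missing landmark(s): ", paste(need, collapse = ", "))
  out <- numeric(nrow(table))
  names(out) <- table$name
  for (i in seq_len(nrow(table))) {
    a <- cc[table$endpoint_a[i], ]
    b <- cc[table$endpoint_b[i], ]
    if (identical(table$special[i], "circumference")) {
      if (is.null(mesh)) { out[i] <- NA_real_; next }
      pl <- midsagittal_plane(landmarks)
      out[i] <- plane_circumference(mesh, a, b, pl$normal)
    } else {
      out[i] <- sqrt(sum((a - b)^2))
    }
  }
  out
}

#' Cranial module and the seven cranial indices
#'
#' * CM  = (max cranial length + max cranial breadth + basion-bregma height) / 3 (mm)
#' * CI  = max cranial breadth / max cranial length x 100
#' * CFI = bizygomatic breadth / max cranial breadth x 100
#' * UFI = upper facial height / bizygomatic breadth x 100
#' * LOI = left orbital height / left orbital breadth x 100
#' * NI  = nasal breadth / nasal height x 100
#' * PI  = internal palatal width / maximum palatal length x 100
#' * FMI = foramen magnum breadth / foramen magnum length x 100
#'
#' @param dims named vector from [linear_dimensions()].
#' @return named numeric vector (CM, CI, CFI, UFI, LOI, NI, PI, FMI).
#' @export
index_panel <- function(dims) {
  g <- function(nm) {
    if (!nm %in% names(dims)) stop("dimension not found: ", nm)
    dims[[nm]]
  }
  ratio <- function(a, b) {
    bv <- g(b)
    if (bv == 0) stop("zero denominator for index: ", b)
    100 * g(a) / bv
  }
  c(CM = (g("max_cranial_length") + g("max_cranial_breadth") +
            g("basion_bregma_height")) / 3,
    CI = ratio("max_cranial_breadth", "max_cranial_length"),
    CFI = ratio("bizygomatic_breadth", "max_cranial_breadth"),
    UFI = ratio("upper_facial_height", "bizygomatic_breadth"),
    LOI = ratio("orbital_height_left", "orbital_breadth_left"),
    NI = ratio("nasal_breadth", "nasal_height"),
    PI = ratio("internal_palatal_width", "max_palatal_length"),
    FMI = ratio("foramen_magnum_breadth", "foramen_magnum_length"))
}

#' Cavity specification for volume extraction
#' @param name cavity name.
#' @param seed_point a point strictly inside the cavity (mm).
#' @export
cavity_spec <- function(name, seed_point) {
  structure(list(name = name, seed_point = as.numeric(seed_point)),
            class = "cm_cavity_spec")
}

#' Measure a cavity volume from a multi-component skull mesh
#'
#' The mesh may contain the outer shell plus several internal cavity
#' surfaces, each left open at its anatomical aperture. Every connected
#' component has its boundary loops capped with triangle fans about the loop
#' centroids; the cavity enclosing the seed point is identified by
#' ray-parity point-in-mesh tests and, among enclosing components, the one
#' with the smallest enclosed volume (the innermost) is reported.
#'
#' @param mesh a `cm_mesh` (multi-component).
#' @param spec a `cm_cavity_spec`.
#' @return volume in mm^3.
#' @export
cavity_volume <- function(mesh, spec) {
  comp <- mesh_components(mesh)
  seed <- spec$seed_point
  best <- Inf
  found <- FALSE
  for (ci in unique(comp)) {
    sub <- subset_mesh(mesh, which(comp == ci))
    sub <- cap_boundary_loops(sub)
    if (!point_in_mesh(sub, seed)) next
    vol <- suppressWarnings(closed_mesh_volume(sub))
    found <- TRUE
    if (vol < best) best <- vol
  }
  if (!found)
    stop("seed point for cavity '", spec$name,
         "' is not inside any closed component")
  best
}

#' Measure all cavity volumes of a synthetic specimen
#'
#' Runs [cavity_volume()] with seeds at the generator's cavity centres and
#' returns a [volume_set()] (ICV, LOV, NCV, UIV). With `include_right_orbit`
#' the right orbital volume is additionally reported for symmetry checks;
#' the standard panel measures only the left orbit.
#'
#' @param specimen a `cm_specimen` with meshes.
#' @param include_right_orbit also measure the right orbit.
#' @return list: `volumes` (a `cm_volume_set`), optionally `rov` (mm^3).
#' @export
measure_cavity_volumes <- function(specimen, include_right_orbit = FALSE) {
  if (is.null(specimen$mesh)) stop("specimen has no mesh")
  gv <- function(nm) cavity_volume(specimen$mesh,
                                   cavity_spec(nm, specimen$cavity_geometry[[nm]]$center))
  vs <- volume_set(gv("icv"), gv("lov"), gv("ncv"), gv("uiv"))
  out <- list(volumes = vs)
  if (include_right_orbit) out$rov <- gv("rov")
  out
}

#' Full measurement panel for one specimen
#'
#' 47 linear dimensions, cranial module and indices, and the four cavity
#' volumes with their cube-root and proportional views.
#'
#' @param specimen a `cm_specimen`.
#' @param table dimension table.
#' @param measure_volumes measure cavity volumes from the mesh (otherwise
#'   the generator's true volumes are reported).
#' @return one-row data.frame.
#' @export
measurement_panel <- function(specimen, table = dimension_table(),
                              measure_volumes = TRUE) {
  dims <- linear_dimensions(specimen$landmarks, specimen$shell, table)
  idx <- index_panel(dims)
  vs <- if (measure_volumes && !is.null(specimen$mesh))
    measure_cavity_volumes(specimen)$volumes else specimen$true_volumes
  df <- as.data.frame(c(as.list(dims), as.list(idx),
                        as.list(vs$volumes), as.list(vs$cvols),
                        as.list(vs$cpvols)))
  df$age_days <- specimen$age_days
  df$age_months <- specimen$age_months
  df$sex <- specimen$sex
  df
}
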