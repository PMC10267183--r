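#' Construct a named landmark set
#'
#' An ordered set of named 3D points in mm for one specimen, with per-point
#' role (`"LM"` for anatomical landmarks, `"SLM"` for surface semilandmarks),
#' side (`"L"`, `"R"` or `"midline"`) and a `gpa_excluded` flag marking
#' points (the Euryon pair on the standard roster) that are carried through
#' the pipeline but left out of superimposition.
#'
#' @param coords `k x 3` numeric matrix (mm).
#' @param names character vector of unique point names.
#' @param role character vector (`"LM"`/`"SLM"`), recycled.
#' @param side character vector (`"L"`/`"R"`/`"midline"`), recycled.
#' @param gpa_excluded logical vector, recycled.
#' @return object of class `cm_landmarks`.
#' @export
landmark_set <- function(coords, names = NULL, role = "LM",
                         side = "midline", gpa_excluded = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must be k x 3")
  if (nrow(coords) == 0) stop("empty landmark set")
  if (anyNA(coords) || any(!is.finite(coords))) stop("coords must be finite")
  k <- nrow(coords)
  if (is.null(names)) names <- rownames(coords)
  if (is.null(names)) names <- sprintf("pt%03d", seq_len(k))
  if (anyDuplicated(names)) stop("landmark names must be unique")
  dimnames(coords) <- list(names, NULL)
  structure(list(coords = coords,
                 role = rep_len(role, k),
                 side = rep_len(side, k),
                 gpa_excluded = rep_len(gpa_excluded, k)),
            class = "cm_landmarks")
}

#' @export
print.cm_landmarks <- function(x, ...) {
  cat("cm_landmarks:", nrow(x$coords), "points (",
      sum(x$role == "LM"), "LM /", sum(x$role == "SLM"), "SLM ),",
      sum(x$gpa_excluded), "flagged gpa_excluded\n")
  invisible(x)
}

# coordinates from either a matrix or a cm_landmarks
lm_coords <- function(x) {
  if (inherits(x, "cm_landmarks")) x$coords else as.matrix(x)
}

#' Subset a landmark set by name or index
#' @param x a `cm_landmarks`.
#' @param idx integer or character index.
#' @export
lm_subset <- function(x, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, rownames(x$coords))
    if (length(miss)) stop("missing landmarks: ", paste(miss, collapse = ", "))
    idx <- match(idx, rownames(x$coords))
  }
  landmark_set(x$coords[idx, , drop = FALSE],
               names = rownames(x$coords)[idx],
               role = x$role[idx], side = x$side[idx],
               gpa_excluded = x$gpa_excluded[idx])
}

#' Write landmarks as CSV (name, x, y, z)
#' @param lms a `cm_landmarks`.
#' @param path output path.
#' @export
write_landmarks_csv <- function(lms, path) {
  df <- data.frame(name = rownames(lms$coords),
                   x = lms$coords[, 1], y = lms$coords[, 2],
                   z = lms$coords[, 3],
                   role = lms$role, side = lms$side,
                   gpa_excluded = lms$gpa_excluded)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read landmarks from CSV (name, x, y, z [, role, side, gpa_excluded])
#' @param path file path.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name, x, y, z")
  landmark_set(as.matrix(df[, c("x", "y", "z")]), names = df$name,
               role = if ("role" %in% names(df)) df$role else "LM",
               side = if ("side" %in% names(df)) df$side else "midline",
               gpa_excluded = if ("gpa_excluded" %in% names(df))
                 as.logical(df$gpa_excluded) else FALSE)
}

#' Write configurations in TPS format (`LM3=k` blocks)
#' @param configs list of `cm_landmarks` (or one).
#' @param path output path.
#' @param ids specimen identifiers for the `ID=` lines.
#' @export
write_landmarks_tps <- function(configs, path, ids = NULL) {
  if (inherits(configs, "cm_landmarks")) configs <- list(configs)
  if (is.null(ids)) ids <- sprintf("specimen_%03d", seq_along(configs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(configs)) {
    x <- lm_coords(configs[[i]])
    writeLines(sprintf("LM3=%d", nrow(x)), con)
    writeLines(sprintf("%.10g %.10g %.10g", x[, 1], x[, 2], x[, 3]), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
  }
  invisible(path)
}

#' Read configurations from a TPS-format file
#' @param path file path.
#' @return named list of coordinate matrices.
#' @export
read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM3?=", lines[i])) stop("malformed TPS file at line ", i)
    k <- as.integer(sub("^LM3?=", "", lines[i]))
    coords <- do.call(rbind, lapply(lines[(i + 1):(i + k)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
    i <- i + k + 1L
    id <- sprintf("specimen_%03d", length(out) + 1L)
    if (i <= length(lines) && grepl("^ID=", lines[i])) {
      id <- sub("^ID=", "", lines[i])
      i <- i + 1L
    }
    out[[id]] <- coords[, 1:3, drop = FALSE]
  }
  out
}

#' The 88-point landmark roster
#'
#' Reads the roster definition shipped with the package
#' (`synthetic_landmark_roster.csv`): number, name, side, role and the
#' `gpa_excluded` flag. The two Euryon points are flagged, leaving 86 points
#' for superimposition. The roster is a synthetic stand-in built from
#' classical craniometric point names; it is editable package data.
#'
#' @param path optional path to an alternative roster CSV.
#' @return data.frame with columns number, name, side, gpa_excluded.
#' @export
landmark_roster <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_landmark_roster.csv",
                        package = "craniomorph", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$gpa_excluded <- as.logical(df$gpa_excluded)
  df[order(df$number), ]
}

#' Least-squares midsagittal plane from midline landmarks
#'
#' Fits a plane through the midline-tagged points; the normal is the
#' direction of least variance of those points.
#'
#' @param lms a `cm_landmarks`.
#' @return list with `point` (on the plane) and `normal` (unit).
#' @export
midsagittal_plane <- function(lms) {
  mid <- lms$coords[lms$side == "midline", , drop = FALSE]
  if (nrow(mid) < 3) stop("need at least 3 midline landmarks")
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2, ctr))
  n <- sv$v[, 3]
  list(point = ctr, normal = n / sqrt(sum(n^2)))
}

#' Reflect points across a plane
#'
#' @param points `n x 3` matrix or `cm_landmarks`; for a landmark set, side
#'   tags are flipped (`L` to `R` and back).
#' @param plane list with `point` and `normal` (see [midsagittal_plane()]).
#' @return same type as `points`.
#' @export
mirror_points <- function(points, plane) {
  n <- plane$normal
  if (sqrt(sum(n^2)) < 1e-12) stop("zero plane normal")
  n <- n / sqrt(sum(n^2))
  refl <- function(x) {
    d <- as.vector(sweep(x, 2, plane$point) %*% n)
    x - 2 * outer(d, n)
  }
  if (inherits(points, "cm_landmarks")) {
    out <- points
    out$coords[] <- refl(points$coords)
    out$side <- ifelse(points$side == "L", "R",
                       ifelse(points$side == "R", "L", points$side))
    out
  } else {
    refl(as.matrix(points))
  }
}
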