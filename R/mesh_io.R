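#' Write a mesh as ASCII PLY
#'
#' Optionally attaches a per-face scalar as a `quality` face property and the
#' patch label as a face `comment`-free integer code (codes listed in the
#' header comments).
#'
#' @param mesh a `cm_mesh`.
#' @param path output file.
#' @param face_scalar optional numeric vector, one value per face.
#' @export
write_ply <- function(mesh, path, face_scalar = NULL) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment craniomorph mesh"), con)
  labs <- mesh$patch_labels
  has_lab <- !is.null(labs)
  if (has_lab) {
    lev <- sort(unique(labs[!is.na(labs)]))
    writeLines(sprintf("comment patch %d %s", seq_along(lev), lev), con)
    code <- match(labs, lev)
    code[is.na(code)] <- 0L
  }
  writeLines(c(sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices"), con)
  if (has_lab) writeLines("property int patch", con)
  if (!is.null(face_scalar)) writeLines("property double quality", con)
  writeLines("end_header", con)
  writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  face_txt <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  if (has_lab) face_txt <- paste(face_txt, code)
  if (!is.null(face_scalar))
    face_txt <- paste(face_txt, sprintf("%.10g", face_scalar))
  writeLines(face_txt, con)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()] (or any ASCII PLY with
#' x/y/z vertex properties and triangular faces)
#' @param path file path.
#' @return a `cm_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  patch_lines <- grep("^comment patch ", hdr, value = TRUE)
  lev <- if (length(patch_lines))
    sub("^comment patch \\d+ ", "", patch_lines) else NULL
  vtx <- utils::read.table(text = lines[(hdr_end + 1):(hdr_end + nv)])[, 1:3]
  face_rows <- utils::read.table(text = lines[(hdr_end + nv + 1):(hdr_end + nv + nf)])
  if (any(face_rows[, 1] != 3)) stop("non-triangular face in PLY")
  faces <- as.matrix(face_rows[, 2:4]) + 1L
  # face property columns follow the index list
  has_patch <- any(grepl("^property int patch", hdr))
  labs <- NULL
  if (has_patch && !is.null(lev)) {
    code <- face_rows[, 5]
    labs <- ifelse(code == 0, NA_character_, lev[pmax(code, 1)])
  }
  cm_mesh(as.matrix(vtx), faces, patch_labels = labs)
}

#' Write a mesh in OFF format
#' @param mesh a `cm_mesh`.
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  v <- mesh$vertices
  writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read an OFF mesh
#' @param path file path.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vtx <- utils::read.table(text = lines[3:(2 + nv)])[, 1:3]
  face_rows <- utils::read.table(text = lines[(3 + nv):(2 + nv + nf)])
  if (any(face_rows[, 1] != 3)) stop("non-triangular face in OFF")
  cm_mesh(as.matrix(vtx), as.matrix(face_rows[, 2:4]) + 1L)
}

#' Write a mesh as ASCII STL
#'
#' STL stores independent triangles; vertex sharing is lost on write and
#' restored on read by welding coincident vertices.
#'
#' @param mesh a `cm_mesh`.
#' @param path output file.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  writeLines("solid craniomorph", con)
  for (r in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.10g %.10g %.10g", n[r, 1], n[r, 2], n[r, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("      vertex %.10g %.10g %.10g",
                         v[f[r, j], 1], v[f[r, j], 2], v[f[r, j], 3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid craniomorph", con)
  invisible(path)
}

#' Read an ASCII STL mesh (welds coincident vertices)
#' @param path file path.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(round(m, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- m[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  cm_mesh(verts, faces)
}
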