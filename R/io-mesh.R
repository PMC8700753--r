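#' Labeled triangle mesh
#'
#' Triangle mesh in world mm coordinates with rendering metadata: a tissue
#' label, an RGB color, a transparency in [0, 1] (0 = opaque here means
#' `transparency` stores alpha; 1 = fully opaque) and a visibility flag.
#' Meshes are the unit the fusion scene and surgical simulation operate
#' on.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label one of `"humerus_ct"`, `"humerus_mri"`, `"cartilage"`,
#'   `"ssb"`, `"resection"`, `"graft"`.
#' @param color RGB triple in [0, 1].
#' @param transparency alpha in [0, 1]; 1 = opaque.
#' @param visible logical visibility flag.
#' @return An object of class `cf_mesh`.
#' @export
tri_mesh <- function(vertices, faces, label = c("humerus_ct", "humerus_mri",
                     "cartilage", "ssb", "resection", "graft"),
                     color = c(0.8, 0.8, 0.8), transparency = 1,
                     visible = TRUE) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(vertices) > 0 && !all(is.finite(vertices)))
    stop("mesh vertices must be finite")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (transparency < 0 || transparency > 1)
    stop("transparency must be in [0, 1]")
  structure(list(vertices = vertices, faces = faces, label = label,
                 color = as.numeric(color), transparency = transparency,
                 visible = isTRUE(visible)),
            class = "cf_mesh")
}

#' @export
print.cf_mesh <- function(x, ...) {
  cat(sprintf("<cf_mesh> '%s': %d vertices, %d faces, area %.2f mm^2%s\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              if (nrow(x$faces)) mesh_area(x) else 0,
              if (x$visible) "" else " (hidden)"))
  invisible(x)
}

#' Surface area of a triangle mesh
#' @param mesh a `cf_mesh`.
#' @return Total face area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed, consistently oriented mesh
#' @param mesh a `cf_mesh` (outward-oriented, watertight).
#' @return Signed enclosed volume in mm^3 (positive for outward normals).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

mesh_is_closed <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a mesh as binary STL or ASCII PLY
#'
#' PLY output carries per-vertex `red`/`green`/`blue` properties taken
#' from the mesh color (so e.g. the SSB overlay keeps its red color on
#' export). A non-manifold mesh is still written but flagged with a
#' message.
#'
#' @param mesh a `cf_mesh` with at least one face.
#' @param path output path.
#' @param format `"auto"` (by extension), `"stl"` or `"ply"`.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "cf_mesh"))
  if (nrow(mesh$faces) == 0) stop("cannot write an empty mesh")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  if (!mesh_is_closed(mesh))
    message("mesh '", mesh$label,
            "' is not 2-manifold/closed; writing anyway")
  if (format == "stl") write_mesh_stl(mesh, path) else
    write_mesh_ply(mesh, path)
  invisible(path)
}

write_mesh_stl <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("capfuse STL: %s", mesh$label))
  writeBin(c(hdr, raw(80 - length(hdr))), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  block <- t(cbind(nrm, V[F[, 1], ], V[F[, 2], ], V[F[, 3], ]))
  for (f in seq_len(nrow(F))) {
    writeBin(as.numeric(block[, f]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

write_mesh_ply <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  rgb <- pmax(0, pmin(255, round(mesh$color * 255)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment capfuse label %s", mesh$label),
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %d %d %d",
                     V[, 1], V[, 2], V[, 3], rgb[1], rgb[2], rgb[3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
             con)
}

#' Read a mesh written by [write_mesh()]
#'
#' Supports binary STL and the ASCII PLY layout the package writes.
#'
#' @param path file path.
#' @param label tissue label to assign (STL carries none; PLY uses its
#'   comment if present and `label` is missing).
#' @return A `cf_mesh`.
#' @export
read_mesh <- function(path, label = NULL) {
  if (grepl("\\.ply$", path, ignore.case = TRUE))
    read_mesh_ply(path, label)
  else read_mesh_stl(path, label)
}

read_mesh_stl <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, nf * 3, 3)
  for (f in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    tri[(3 * f - 2):(3 * f), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  key <- apply(round(tri, 7), 1, paste, collapse = "/")
  uid <- !duplicated(key)
  verts <- tri[uid, , drop = FALSE]
  index <- match(key, key[uid])
  faces <- matrix(index, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces, label = if (is.null(label)) "humerus_ct" else label)
}

read_mesh_ply <- function(path, label = NULL) {
  lines <- readLines(path)
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  cmt <- grep("^comment capfuse label", lines, value = TRUE)
  if (is.null(label) && length(cmt))
    label <- sub("comment capfuse label ", "", cmt[1])
  vl <- lines[(endh + 1):(endh + nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, " "))), nv, byrow = TRUE)
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- matrix(as.integer(unlist(strsplit(fl, " "))), nf, byrow = TRUE)
  color <- if (ncol(vm) >= 6) vm[1, 4:6] / 255 else c(0.8, 0.8, 0.8)
  tri_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L,
           label = if (is.null(label)) "humerus_ct" else label,
           color = color)
}

#' Rigidly transform a mesh
#' @param mesh a `cf_mesh`.
#' @param transform a `cf_transform`.
#' @return The transformed `cf_mesh` (metadata preserved).
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_transform(transform, mesh$vertices)
  mesh
}
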