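#' Read a 3D volume from NIfTI, NRRD, or a DICOM series directory
#'
#' NIfTI is read through RNifti; NRRD and DICOM use lightweight readers
#' shipped with the package (raw/gzip-encoded attached NRRD; explicit-VR
#' little-endian uncompressed single-frame DICOM series). DICOM geometry
#' (LPS) is converted to the package's right-handed RAS-style mm frame on
#' read.
#'
#' @param path file path (NIfTI/NRRD) or directory (DICOM series).
#' @param format `"auto"` (by extension / directory), `"nifti"`, `"nrrd"`
#'   or `"dicom"`.
#' @param modality `"MRI"` or `"CT"` tag for the returned volume.
#' @return A [image_volume()] object.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom"),
                        modality = c("MRI", "CT")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("cannot read volume: no such file or directory: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else "nifti"
  }
  switch(format,
         nifti = read_volume_nifti(path, modality),
         nrrd = read_volume_nrrd(path, modality),
         dicom = read_dicom_series(path, modality))
}

#' Write a volume as NIfTI (.nii / .nii.gz) or NRRD
#'
#' @param volume a `cf_volume`.
#' @param path output path; format chosen by extension unless given.
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "cf_volume"))
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else "nifti"
  if (format == "nifti") write_volume_nifti(volume, path)
  else write_volume_nrrd(volume, path)
  invisible(path)
}

volume_xform <- function(volume) {
  m <- diag(4)
  m[1:3, 1:3] <- volume$axes %*% diag(volume$spacing)
  m[1:3, 4] <- volume$origin
  m
}

read_volume_nifti <- function(path, modality) {
  img <- RNifti::readNifti(path)
  xfm <- RNifti::xform(img)
  sp <- sqrt(colSums(xfm[1:3, 1:3]^2))
  axes <- sweep(xfm[1:3, 1:3], 2, sp, `/`)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-4)
    stop("non-orthonormal direction matrix in NIfTI header: ", path)
  image_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp,
               origin = xfm[1:3, 4], axes = axes, modality = modality)
}

write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  xfm <- volume_xform(volume)
  RNifti::qform(img) <- structure(xfm, code = 2L)
  RNifti::sform(img) <- structure(xfm, code = 2L)
  RNifti::writeNifti(img, path)
}

# ---- NRRD (attached raw or gzip payload) ---------------------------------

write_volume_nrrd <- function(volume, path) {
  dirs <- volume$axes %*% diag(volume$spacing)
  vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  hdr <- c("NRRD0004",
           "# produced by capfuse",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste0("sizes: ", paste(dim(volume$data), collapse = " ")),
           paste0("space directions: ", vec(dirs[, 1]), " ",
                  vec(dirs[, 2]), " ", vec(dirs[, 3])),
           "endian: little",
           "encoding: raw",
           paste0("space origin: ", vec(volume$origin)),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writLines <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeBin(charToRaw(writLines), con)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
}

read_volume_nrrd <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("unexpected end of NRRD header: ", path)
      if (b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    line <- rawToChar(bytes)
    if (nchar(trimws(line)) == 0) break
    lines <- c(lines, line)
  }
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  fields <- lines[grepl(":", lines) & !grepl("^#", lines)]
  key <- tolower(trimws(sub(":.*$", "", fields)))
  val <- trimws(sub("^[^:]*:=?", "", fields))
  getf <- function(k, default = NULL) {
    i <- match(k, key)
    if (is.na(i)) default else val[i]
  }
  sizes <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported: ", path)
  type <- getf("type")
  enc <- getf("encoding", "raw")
  endian <- getf("endian", "little")
  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    vapply(m, function(x)
      as.numeric(strsplit(gsub("[()]", "", x), ",")[[1]]), numeric(3))
  }
  dirs <- getf("space directions")
  if (!is.null(dirs)) {
    D <- unname(parse_vecs(dirs))
    sp <- sqrt(colSums(D^2))
    axes <- sweep(D, 2, sp, `/`)
  } else {
    sp <- c(1, 1, 1); axes <- diag(3)
    spc <- getf("spacings")
    if (!is.null(spc)) sp <- as.numeric(strsplit(spc, "\\s+")[[1]])
  }
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("non-orthonormal space directions in NRRD header: ", path)
  org <- getf("space origin")
  origin <- if (is.null(org)) c(0, 0, 0) else as.numeric(parse_vecs(org))
  n <- prod(sizes)
  rtype <- switch(type,
                  "double" = list(what = "numeric", size = 8),
                  "float" = list(what = "numeric", size = 4),
                  "short" = list(what = "integer", size = 2),
                  "unsigned short" = list(what = "integer", size = 2),
                  "int" = list(what = "integer", size = 4),
                  "uchar" = , "unsigned char" =
                    list(what = "integer", size = 1),
                  stop("unsupported NRRD type: ", type))
  dcon <- con
  if (enc %in% c("gzip", "gz")) {
    payload <- readBin(con, "raw", n = file.size(path))
    dcon <- gzcon(rawConnection(payload))
    on.exit(close(dcon), add = TRUE)
  } else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  unsigned <- type %in% c("uchar", "unsigned char", "ushort",
                          "unsigned short")
  dat <- readBin(dcon, rtype$what, n = n, size = rtype$size,
                 endian = endian, signed = !unsigned || rtype$size > 2)
  image_volume(array(as.numeric(dat), sizes), spacing = sp,
               origin = origin, axes = axes, modality = modality)
}
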