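# Minimal DICOM support: explicit-VR little-endian, uncompressed,
# single-frame monochrome slices, one series per directory. This covers
# reading a CT/MR series into a cf_volume; writing DICOM is a non-goal
# (the internal single-frame writer exists only so the test suite can
# synthesize a series programmatically).

dicom_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT",
                    "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(raw[at + 0:3]) * 256^(0:3))
  elems <- list()
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dicom_long_vrs) {
      len <- u32(pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_at <- pos + 8L
    }
    if (vr == "SQ") stop("DICOM sequences are not supported: ", path)
    tag <- sprintf("%04x,%04x", group, elem)
    elems[[tag]] <- list(vr = vr,
                         data = if (len > 0)
                           raw[data_at:(data_at + len - 1L)] else raw(0))
    pos <- data_at + len
  }
  elems
}

dicom_str <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$data))
}

dicom_num <- function(elems, tag) {
  s <- dicom_str(elems, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_u16val <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$data, "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read an uncompressed DICOM series into a volume
#'
#' All files in the directory must belong to one series (same
#' SeriesInstanceUID); slices are sorted by position along the slice
#' normal and the through-plane spacing is taken from the slice pitch.
#' Patient coordinates (LPS) are converted to the package's RAS-style
#' frame.
#'
#' @param path directory containing the `.dcm` files.
#' @param modality `"MRI"` or `"CT"`.
#' @return A [image_volume()] object.
#' @export
read_dicom_series <- function(path, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files found in ", path)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(e) {
    u <- dicom_str(e, "0020,000e")
    if (is.null(u)) "<missing>" else u
  }, "")
  if (length(unique(uids)) > 1)
    stop("directory mixes multiple DICOM series; UIDs found: ",
         paste(unique(uids), collapse = ", "))
  first <- slices[[1]]
  rows <- dicom_u16val(first, "0028,0010")
  cols <- dicom_u16val(first, "0028,0011")
  ps <- dicom_num(first, "0028,0030")
  iop <- dicom_num(first, "0020,0037")
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(iop))
    stop("DICOM series misses required geometry tags: ", path)
  lps2ras <- diag(c(-1, -1, 1))
  row_dir <- as.numeric(lps2ras %*% iop[1:3])  # along columns (x index)
  col_dir <- as.numeric(lps2ras %*% iop[4:6])  # along rows (y index)
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  ipp <- t(vapply(slices, function(e)
    as.numeric(lps2ras %*% dicom_num(e, "0020,0032")), numeric(3)))
  ord <- order(ipp %*% normal)
  slices <- slices[ord]
  ipp <- ipp[ord, , drop = FALSE]
  nz <- length(slices)
  dz <- if (nz > 1) median(diff(as.numeric(ipp %*% normal))) else 1
  bits <- dicom_u16val(first, "0028,0100")
  if (is.null(bits)) bits <- 16L
  rep0 <- dicom_u16val(first, "0028,0103")
  signed <- !is.null(rep0) && rep0 == 1L
  slope <- dicom_num(first, "0028,1053"); if (is.null(slope)) slope <- 1
  inter <- dicom_num(first, "0028,1052"); if (is.null(inter)) inter <- 0
  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]][["7fe0,0010"]]
    if (is.null(px)) stop("DICOM slice without pixel data in ", path)
    v <- readBin(px$data, "integer", n = rows * cols,
                 size = bits / 8, signed = signed, endian = "little")
    # pixel order is row-major (row = y), our first index is x
    arr[, , k] <- matrix(v, nrow = cols)
  }
  arr <- arr * slope + inter
  axes <- cbind(row_dir, col_dir, normal)
  colnames(axes) <- NULL
  image_volume(arr, spacing = c(ps[2], ps[1], abs(dz)),
               origin = ipp[1, ], axes = axes, modality = modality)
}

# Internal single-slice writer (test support only): explicit VR little
# endian, monochrome, 16-bit unsigned.
write_dicom_slice <- function(path, pixels, position_lps, spacing_rc,
                              orientation_lps = c(1, 0, 0, 0, 1, 0),
                              series_uid = "1.2.3.4.5") {
  pixels <- as.matrix(pixels)  # [x, y]
  rows <- ncol(pixels); cols <- nrow(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  put <- function(group, elem, vr, payload) {
    if (length(payload) %% 2 == 1) {
      pad <- if (vr %in% c("OB", "UI")) as.raw(0) else charToRaw(" ")
      payload <- c(payload, pad)
    }
    writeBin(writeBin(as.integer(c(group, elem)), raw(), size = 2,
                      endian = "little"), con)
    writeBin(charToRaw(vr), con)
    if (vr %in% dicom_long_vrs) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(as.integer(length(payload)), con, size = 4,
               endian = "little")
    } else {
      writeBin(as.integer(length(payload)), con, size = 2,
               endian = "little")
    }
    writeBin(payload, con)
  }
  str_pl <- function(s) charToRaw(s)
  us_pl <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                endian = "little")
  put(0x0008, 0x0060, "CS", str_pl("CT"))
  put(0x0020, 0x000e, "UI", str_pl(series_uid))
  put(0x0020, 0x0032, "DS",
      str_pl(paste(sprintf("%.6f", position_lps), collapse = "\\")))
  put(0x0020, 0x0037, "DS",
      str_pl(paste(sprintf("%.6f", orientation_lps), collapse = "\\")))
  put(0x0028, 0x0010, "US", us_pl(rows))
  put(0x0028, 0x0011, "US", us_pl(cols))
  put(0x0028, 0x0030, "DS",
      str_pl(paste(sprintf("%.6f", spacing_rc), collapse = "\\")))
  put(0x0028, 0x0100, "US", us_pl(16))
  put(0x0028, 0x0101, "US", us_pl(16))
  put(0x0028, 0x0102, "US", us_pl(15))
  put(0x0028, 0x0103, "US", us_pl(0))
  put(0x7fe0, 0x0010, "OW", us_pl(as.integer(pixels)))
  invisible(path)
}
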