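# Volume IO: NIfTI-1 through RNifti; NRRD and MetaImage through minimal
# readers/writers implemented here (raw little-endian payloads, single-file
# .nrrd/.mha or detached .mhd + .raw). Array storage order on disk is the
# in-memory order (lateral fastest), recorded once in the header convention
# note below.
#
# Header convention: dimension 1 of the file (the fastest-varying axis) is
# lateral, dimension 2 axial, dimension 3 elevational. Files produced by
# other tools are mapped positionally under the same convention; no axis
# permutation is attempted.

#' Read a 3D volume from a standard volumetric format
#'
#' Supported formats: NRRD (`.nrrd`), NIfTI-1 (`.nii`, `.nii.gz`) and
#' MetaImage (`.mha`, `.mhd`). Voxel size is taken from file metadata; an
#' anisotropic spacing triggers a warning and the mean spacing is used (the
#' choice is recorded in the `provenance` attribute).
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"nrrd"`, `"nifti"`, `"metaimage"`;
#'   `"auto"` infers from the file extension.
#' @return An [us_volume]. Convert with [as_label_volume()] or
#'   [as_prob_volume()] when the payload is a mask or probability map.
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") format <- infer_format(path)
  res <- switch(format,
    nrrd = read_nrrd(path),
    nifti = read_nifti_file(path),
    metaimage = read_metaimage(path))
  spacing <- res$spacing
  if (length(spacing) == 0 || any(!is.finite(spacing)) || any(spacing <= 0))
    spacing <- rep(1, 3)
  provenance <- NULL
  if (max(spacing) - min(spacing) > 1e-6) {
    warn(sprintf(
      "anisotropic spacing (%s) in %s; using mean spacing %.6g mm",
      paste(signif(spacing, 6), collapse = ", "), basename(path),
      mean(spacing)))
    provenance <- sprintf("anisotropic spacing %s replaced by mean %.6g",
                          paste(signif(spacing, 6), collapse = ","),
                          mean(spacing))
  }
  v <- us_volume(res$data, mean(spacing), origin_mm = res$origin)
  if (!is.null(provenance)) attr(v, "provenance") <- provenance
  v
}

#' Write a volume to a standard volumetric format
#'
#' Integer payloads (label volumes, integer-valued intensities in
#' \[0, 255\]) are written as `uint8` and round-trip bit-exactly; other
#' payloads are written as 64-bit floats.
#'
#' @param v An [us_volume], [label_volume] or [prob_volume].
#' @param path Output path.
#' @param format As in [read_volume()]; `"auto"` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "nrrd", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- infer_format(path)
  dat <- vol_data(v)
  is_u8 <- inherits(v, "label_volume") ||
    (is.integer(dat) && min(dat) >= 0 && max(dat) <= 255) ||
    (all(dat == round(dat)) && min(dat) >= 0 && max(dat) <= 255)
  ok <- tryCatch({
    switch(format,
      nrrd = write_nrrd(dat, path, v$voxel_size_mm, v$origin_mm, is_u8),
      nifti = write_nifti_file(dat, path, v$voxel_size_mm, v$origin_mm, is_u8),
      metaimage = write_metaimage(dat, path, v$voxel_size_mm, v$origin_mm, is_u8))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort(sprintf("failed to write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}

#' @rdname read_volume
#' @export
as_label_volume <- function(v) {
  dat <- vol_data(v)
  label_volume(array(as.integer(dat > 0.5), dim(dat)), v$voxel_size_mm,
               v$origin_mm)
}

#' @rdname read_volume
#' @export
as_prob_volume <- function(v) {
  prob_volume(vol_data(v), v$voxel_size_mm, v$origin_mm)
}

infer_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) return("nrrd")
  if (grepl("\\.(nii|nii\\.gz)$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
  abort(paste0("cannot infer volume format from extension of: ", path))
}

## ---- NIfTI (RNifti) --------------------------------------------------

read_nifti_file <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) abort(sprintf("expected a 3D NIfTI, got %dD", length(d)))
  list(data = array(as.numeric(img), d),
       spacing = abs(RNifti::pixdim(img))[1:3], origin = c(0, 0, 0))
}

write_nifti_file <- function(dat, path, spacing, origin, is_u8) {
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::`pixdim<-`(img, rep(spacing, 3)) -> img
  RNifti::writeNifti(img, path, datatype = if (is_u8) "uint8" else "double")
}

## ---- NRRD ------------------------------------------------------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) abort(paste0("not an NRRD file: ", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":[ =]?", perl = TRUE)[[1]]
    key <- tolower(trimws(kv[1]))
    fields[[key]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) abort("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  spacing <- rep(1, 3)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(s) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  vals <- if (enc %in% c("raw")) {
    read_binary_payload(con, type, n, fields[["endian"]] %||% "little")
  } else if (enc %in% c("txt", "text", "ascii")) {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  } else abort(paste0("unsupported NRRD encoding: ", enc))
  if (length(vals) != n) abort("NRRD payload shorter than `sizes` imply")
  list(data = array(as.numeric(vals), sizes), spacing = spacing,
       origin = origin)
}

write_nrrd <- function(dat, path, spacing, origin, is_u8) {
  type <- if (is_u8) "uint8" else "double"
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(dat), collapse = " ")),
    paste0("spacings: ", paste(rep(spacing, 3), collapse = " ")),
    paste0("space origin: (", paste(origin, collapse = ","), ")"),
    "encoding: raw",
    "endian: little",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  write_binary_payload(con, dat, is_u8)
}

## ---- MetaImage -------------------------------------------------------

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    fields[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  if (length(sizes) != 3L) abort("only 3D MetaImage volumes are supported")
  spacing <- if (!is.null(fields[["ElementSpacing"]]))
    as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(fields[["Offset"]]))
    as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- switch(fields[["ElementType"]],
    MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
    MET_FLOAT = "float", MET_DOUBLE = "double",
    abort(paste0("unsupported ElementType: ", fields[["ElementType"]])))
  msb <- identical(fields[["BinaryDataByteOrderMSB"]], "True") ||
    identical(fields[["ElementByteOrderMSB"]], "True")
  n <- prod(sizes)
  datafile <- fields[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    vals <- read_binary_payload(con, type, n, if (msb) "big" else "little")
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path))
      abort(paste0("MetaImage data file not found: ", raw_path))
    con2 <- file(raw_path, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- read_binary_payload(con2, type, n, if (msb) "big" else "little")
  }
  if (length(vals) != n) abort("MetaImage payload shorter than DimSize implies")
  list(data = array(as.numeric(vals), sizes), spacing = spacing,
       origin = origin)
}

write_metaimage <- function(dat, path, spacing, origin, is_u8) {
  detached <- grepl("\\.mhd$", tolower(path))
  datafile <- if (detached)
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("DimSize = ", paste(dim(dat), collapse = " ")),
    paste0("ElementSpacing = ", paste(rep(spacing, 3), collapse = " ")),
    paste0("Offset = ", paste(origin, collapse = " ")),
    paste0("ElementType = ", if (is_u8) "MET_UCHAR" else "MET_DOUBLE"),
    paste0("ElementDataFile = ", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (detached) {
    close(con)
    con2 <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con2))
    write_binary_payload(con2, dat, is_u8)
  } else {
    on.exit(close(con))
    write_binary_payload(con, dat, is_u8)
  }
}

## ---- shared binary helpers ------------------------------------------

read_binary_payload <- function(con, type, n, endian_word) {
  endian <- if (grepl("big", endian_word)) "big" else "little"
  switch(type,
    uint8 = , uchar = as.numeric(readBin(con, "integer", n, size = 1,
                                         signed = FALSE)),
    int16 = , short = as.numeric(readBin(con, "integer", n, size = 2,
                                         signed = TRUE, endian = endian)),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
    int32 = , int = as.numeric(readBin(con, "integer", n, size = 4,
                                       endian = endian)),
    float = as.numeric(readBin(con, "numeric", n, size = 4, endian = endian)),
    double = readBin(con, "numeric", n, size = 8, endian = endian),
    abort(paste0("unsupported voxel type: ", type)))
}

write_binary_payload <- function(con, dat, is_u8) {
  if (is_u8) {
    writeBin(as.integer(dat), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(dat), con, size = 8, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
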