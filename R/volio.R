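#' Read a 3D volume from MetaImage or NIfTI
#'
#' Supported formats are MetaImage (`.mha` single-file or `.mhd` + raw) and
#' NIfTI (`.nii`, `.nii.gz`). Spacing and origin are taken from the header.
#' Only axis-aligned orientation is supported: a non-identity direction /
#' rotation matrix in the header is rejected with an explicit error rather
#' than silently reinterpreted, because a silently dropped direction would
#' misregister every downstream measurement. If a units sidecar written by
#' [write_volume()] is present the normalized/raw flag is restored,
#' otherwise the volume is flagged `"raw"`.
#'
#' @param path file path.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- volume_format(path)
  vol <- switch(fmt,
    metaimage = read_metaimage(path),
    nifti = read_nifti_volume(path))
  side <- read_units_sidecar(path)
  if (!is.null(side)) vol$unit_state <- side
  vol
}

#' Write a 3D volume to MetaImage or NIfTI
#'
#' Values are stored as 64-bit floats so the round trip is bit-exact. For a
#' normalized volume a small JSON sidecar (`<path>.units.json`) records the
#' unit state so [read_volume()] can restore it; raw volumes write no
#' sidecar.
#'
#' @param vol a [volume_image()].
#' @param path destination; format chosen from the extension
#'   (`.mha`/`.mhd`/`.nii`/`.nii.gz`).
#' @return `invisible(path)`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume_image(vol))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  fmt <- volume_format(path)
  switch(fmt,
    metaimage = write_metaimage(vol$values, vol$spacing, vol$origin, path,
                                type = "MET_DOUBLE"),
    nifti = write_nifti_volume(vol$values, vol$spacing, vol$origin, path))
  sidecar <- units_sidecar_path(path)
  if (identical(vol$unit_state, "normalized")) {
    jsonlite::write_json(list(unit_state = "normalized"), sidecar,
                         auto_unbox = TRUE)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  invisible(path)
}

#' Read/write a binary mask volume
#'
#' Masks are stored as 8-bit 0/1 images for maximal format compatibility;
#' any nonzero voxel reads back as `TRUE`.
#'
#' @param path file path (`.mha`/`.mhd`/`.nii`/`.nii.gz`).
#' @return [read_mask()]: a [binary_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$values != 0, vol$spacing, vol$origin)
}

#' @rdname read_mask
#' @param mask a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  fmt <- volume_format(path)
  vals <- array(as.double(mask$values), dim(mask$values))
  switch(fmt,
    metaimage = write_metaimage(vals, mask$spacing, mask$origin, path,
                                type = "MET_UCHAR"),
    nifti = write_nifti_volume(vals, mask$spacing, mask$origin, path,
                               datatype = "uint8"))
  invisible(path)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.mha$|\\.mhd$", lower)) return("metaimage")
  if (grepl("\\.nii$|\\.nii\\.gz$", lower)) return("nifti")
  stop("unsupported volume format (use .mha, .mhd, .nii or .nii.gz): ", path)
}

units_sidecar_path <- function(path) paste0(path, ".units.json")

read_units_sidecar <- function(path) {
  sidecar <- units_sidecar_path(path)
  if (!file.exists(sidecar)) return(NULL)
  meta <- jsonlite::read_json(sidecar)
  if (identical(meta$unit_state, "normalized")) "normalized" else "raw"
}

## ---- MetaImage ----------------------------------------------------------

met_types <- list(
  MET_UCHAR  = list(size = 1L, signed = FALSE, what = "integer"),
  MET_CHAR   = list(size = 1L, signed = TRUE,  what = "integer"),
  MET_SHORT  = list(size = 2L, signed = TRUE,  what = "integer"),
  MET_USHORT = list(size = 2L, signed = FALSE, what = "integer"),
  MET_INT    = list(size = 4L, signed = TRUE,  what = "integer"),
  MET_FLOAT  = list(size = 4L, signed = TRUE,  what = "double"),
  MET_DOUBLE = list(size = 8L, signed = TRUE,  what = "double"))

# MetaImage headers are ASCII `Key = value` lines; .mha appends the raw
# voxel block after the `ElementDataFile = LOCAL` line.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  read_header_line <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) return(NULL)
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  repeat {
    line <- read_header_line()
    if (is.null(line)) stop("truncated MetaImage header: ", path)
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L) stop("only 3D scalar images are supported (NDims=",
                        ndims, ")")
  if (!is.null(hdr[["ElementNumberOfChannels"]]) &&
      as.integer(hdr[["ElementNumberOfChannels"]]) != 1L)
    stop("vector images are not supported")
  if (identical(toupper(hdr[["CompressedData"]] %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data is not supported")
  if (identical(toupper(hdr[["BinaryDataByteOrderMSB"]] %||% "FALSE"), "TRUE"))
    stop("big-endian MetaImage data is not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("invalid DimSize in MetaImage header")
  spacing_key <- if (!is.null(hdr[["ElementSpacing"]])) "ElementSpacing"
                 else "ElementSize"
  if (is.null(hdr[[spacing_key]]))
    stop("MetaImage header lacks ElementSpacing")
  spacing <- as.numeric(strsplit(hdr[[spacing_key]], "\\s+")[[1]])
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid voxel spacing in header (must be 3 positive values)")
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(hdr[["TransformMatrix"]])) {
    tm <- as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop("only axis-aligned (identity TransformMatrix) images are supported")
  }
  type <- hdr[["ElementType"]] %||% "MET_FLOAT"
  tinfo <- met_types[[type]]
  if (is.null(tinfo)) stop("unsupported MetaImage ElementType: ", type)
  data_file <- hdr[["ElementDataFile"]]
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw_vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                        signed = tinfo$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_vals <- readBin(rcon, tinfo$what, n = n, size = tinfo$size,
                        signed = tinfo$signed, endian = "little")
  }
  if (length(raw_vals) != n) stop("truncated MetaImage voxel data")
  volume_image(array(as.double(raw_vals), dims), spacing, origin,
               unit_state = "raw")
}

write_metaimage <- function(values, spacing, origin, path,
                            type = "MET_DOUBLE") {
  tinfo <- met_types[[type]]
  dims <- dim(values)
  is_mhd <- grepl("\\.mhd$", tolower(path))
  data_ref <- if (is_mhd) paste0(sub("\\.mhd$", "", basename(path),
                                     ignore.case = TRUE), ".raw") else "LOCAL"
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =",
          paste(format(spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", data_ref))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  payload <- if (tinfo$what == "integer") as.integer(values)
             else as.double(values)
  if (is_mhd) {
    rcon <- file(file.path(dirname(path), data_ref), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon, size = tinfo$size, endian = "little")
  } else {
    writeBin(payload, con, size = tinfo$size, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI --------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("only 3D scalar NIfTI images are supported")
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid voxel spacing in NIfTI header (must be positive)")
  dirmat <- xf[1:3, 1:3] %*% diag(1 / spacing)
  if (max(abs(dirmat - diag(3))) > 1e-4)
    stop("only axis-aligned NIfTI orientations are supported")
  origin <- as.numeric(xf[1:3, 4])
  volume_image(array(as.double(arr), dim(arr)), spacing, origin,
               unit_state = "raw")
}

write_nifti_volume <- function(values, spacing, origin, path,
                               datatype = "double") {
  arr <- values
  attr(arr, "pixdim") <- spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  m <- diag(4)
  m[cbind(1:3, 1:3)] <- spacing
  m[1:3, 4] <- origin
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- measurement tables -------------------------------------------------

#' Read and validate a graft-volume measurement table
#'
#' The CSV must have columns `patient_id`, `treated_side`, `side`,
#' `timepoint`, `volume_mm3`, one row per (patient, side, timepoint) with
#' sides in `{Dx, Sin}` (dexter/sinister), timepoints in `{baseline, 6mo}`
#' and non-negative volumes in mm^3. `treated_side` marks which side
#' received the ibandronate-treated graft and must be constant within a
#' patient.
#'
#' @param path CSV path.
#' @return validated `data.frame` with the columns above.
#' @seealso [build_records()], [graft_volume_fixture()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  validate_measurements(tab)
}

#' @rdname read_measurements
#' @param table measurement `data.frame` to write.
#' @export
write_measurements <- function(table, path) {
  table <- validate_measurements(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
validate_measurements <- function(table) {
  required <- c("patient_id", "treated_side", "side", "timepoint",
                "volume_mm3")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    stop("measurement table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  table <- as.data.frame(table)[required]
  table$patient_id <- as.character(table$patient_id)
  table$volume_mm3 <- as.numeric(table$volume_mm3)
  if (nrow(table) == 0L) return(table)
  if (!all(table$side %in% c("Dx", "Sin")))
    stop("`side` must be 'Dx' or 'Sin'")
  if (!all(table$treated_side %in% c("Dx", "Sin")))
    stop("`treated_side` must be 'Dx' or 'Sin'")
  if (!all(table$timepoint %in% c("baseline", "6mo")))
    stop("`timepoint` must be 'baseline' or '6mo'")
  if (any(!is.finite(table$volume_mm3)) || any(table$volume_mm3 < 0))
    stop("volumes must be finite and non-negative")
  key <- paste(table$patient_id, table$side, table$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (patient, side, timepoint) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  per_patient <- tapply(table$treated_side, table$patient_id,
                        function(x) length(unique(x)))
  if (any(per_patient > 1L))
    stop("`treated_side` must be constant within a patient")
  table
}

#' Measured graft volumes of the published ibandronate trial
#'
#' Per-patient graft volumes (mm^3) at baseline (2 weeks post-op) and the
#' 6-month control for both mandible sides, for the randomized
#' internal-control trial of ibandronate-soaked mandibular bone grafts:
#' nine analyzed patients plus one patient (8606) with baseline volumes
#' only, who was excluded after reoperation. These printed integer volumes
#' are the package's acceptance surface for the paired statistics.
#'
#' @return [graft_volume_fixture()]: path to the CSV;
#'   [load_graft_volumes()]: the validated measurement table.
#' @export
graft_volume_fixture <- function() {
  system.file("extdata", "graft_volumes.csv", package = "graftquant",
              mustWork = TRUE)
}

#' @rdname graft_volume_fixture
#' @export
load_graft_volumes <- function() {
  read_measurements(graft_volume_fixture())
}
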