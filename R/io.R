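## Volume file I/O -----------------------------------------------------------
##
## NIfTI-1 (.nii / .nii.gz) goes through RNifti; MetaImage (.mha / .mhd+.raw)
## is parsed here directly (header keys as written by ITK/MetaIO,
## uncompressed payloads). Internally everything is LPS; NIfTI affines are
## RAS, so the first two axes are sign-flipped on the way in and out.
## NIfTI-1 stores spacing/affine header fields as 32-bit floats, so geometry
## round-trips at float32 precision; MetaImage headers are written with full
## double precision.

LPS_FLIP <- diag(c(-1, -1, 1))

guess_format <- function(path) {
  if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) "metaimage"
  else stop("cannot infer volume format from extension of: ", path)
}

#' Read a 3D volume
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param format `"nifti"` or `"metaimage"`; inferred from the extension by
#'   default.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = guess_format(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("nifti", "metaimage"))
  if (format == "nifti") read_nifti_volume(path) else read_meta_volume(path)
}

#' Write a 3D volume
#'
#' @param v A [volume()].
#' @param path Output path; the extension selects the container unless
#'   `format` is given.
#' @param format `"nifti"` or `"metaimage"`.
#' @export
write_volume <- function(v, path, format = guess_format(path)) {
  stopifnot_volume(v)
  format <- match.arg(format, c("nifti", "metaimage"))
  if (format == "nifti") write_nifti_volume(v, path)
  else write_meta_volume(v, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("non-3D payload: NIfTI image has ", length(dim(img)), " dimensions")
  data <- array(as.numeric(img), dim(img))
  aff <- RNifti::xform(img)            # 4x4, RAS
  M <- LPS_FLIP %*% aff[1:3, 1:3]
  origin <- as.numeric(LPS_FLIP %*% aff[1:3, 4])
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("malformed header: non-positive spacing")
  direction <- M %*% diag(1 / spacing)
  volume(data, spacing, origin, direction)
}

write_nifti_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing   # before the xforms, or scales are lost
  M <- LPS_FLIP %*% (v$direction %*% diag(v$spacing))
  aff <- rbind(cbind(M, LPS_FLIP %*% v$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
}

meta_type_info <- function(type) {
  switch(type,
         MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
         MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
         MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
         MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
         MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
         MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
         MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
         MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE),
         stop("malformed header: unsupported ElementType '", type, "'"))
}

read_meta_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed header: no ElementDataFile key")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (is.na(ndims)) stop("malformed header: missing NDims")
  if (ndims != 3L) stop("non-3D payload: NDims = ", ndims)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    stop("malformed header: DimSize")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr[["TransformMatrix"]] %||%
                              "1 0 0 0 1 0 0 0 1", "\\s+")[[1]])
  direction <- matrix(tm, 3, 3, byrow = TRUE)
  if (identical(tolower(hdr[["CompressedData"]] %||% "false"), "true"))
    stop("malformed header: compressed MetaImage payloads are not supported")
  msb <- identical(tolower(hdr[["BinaryDataByteOrderMSB"]] %||% "false"),
                   "true")
  ti <- meta_type_info(hdr[["ElementType"]] %||% "MET_DOUBLE")
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(toupper(datafile), "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) stop("file not found: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("malformed payload: expected ", n, " voxels")
  volume(array(as.double(vals), dims), spacing, origin, direction)
}

write_meta_volume <- function(v, path) {
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path),
                                  ignore.case = TRUE), ".raw") else "LOCAL"
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", num(as.numeric(t(v$direction)))),
           paste("Offset =", num(v$origin)),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", num(v$spacing)),
           paste("DimSize =", paste(dim(v$data), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (mhd) {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(v$data), rcon, size = 8L, endian = "little")
  } else {
    writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a grid specification to JSON
#' @param g A [grid_spec()].
#' @param path Output path.
#' @export
write_grid_spec <- function(g, path) {
  if (is_volume(g)) g <- grid_of(g)
  jsonlite::write_json(list(shape = g$shape, spacing = g$spacing,
                            origin = g$origin, direction = g$direction),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a grid specification from JSON
#' @param path JSON path.
#' @return A [grid_spec()].
#' @export
read_grid_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_spec(o$shape, o$spacing, o$origin,
            matrix(unlist(o$direction), 3, 3, byrow = TRUE))
}

#' Read a binary mask volume
#'
#' Reads like [read_volume()] and validates that the payload is binary.
#' @inheritParams read_volume
#' @return A `volume` whose data is 0/1.
#' @export
read_mask <- function(path, format = guess_format(path)) {
  m <- read_volume(path, format)
  u <- unique(as.vector(m$data))
  if (!all(u %in% c(0, 1)))
    stop("mask payload is not binary (values: ",
         paste(utils::head(sort(u), 5), collapse = ", "), ")")
  m
}
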