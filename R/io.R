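# Volume and cohort-table I/O.  Downstream modules consume only
# LabelVolume objects and validated cohort data frames, never raw files.

#' Read a labelled segmentation volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or uncompressed MetaImage (`.mha`)
#' label maps.  The affine must be axis-aligned with positive scales
#' (oblique acquisitions are rejected and must be resampled upstream);
#' voxel spacing is taken from the header, the origin from the affine
#' translation.
#'
#' @param path Path to the volume file.
#' @param schema Role-to-label map; default [defaultLabelSchema()].
#' @return A [LabelVolume-class] with the schema attached.
#' @examples
#' v <- array(0L, c(4, 4, 4)); v[2, 2, 2] <- 1L
#' f <- tempfile(fileext = ".nii.gz")
#' writeLabelVolume(LabelVolume(v, c(0.5, 0.5, 1)), f)
#' readLabelVolume(f)
#' @export
readLabelVolume <- function(path, schema = defaultLabelSchema()) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    dims <- dim(img)
    if (length(dims) != 3L)
      stop(sprintf("format error: expected a 3D volume, got %d dimensions",
                   length(dims)))
    aff <- RNifti::xform(img)
    rot <- aff[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))) ||
        any(diag(rot) <= 0))
      stop("format error: volume orientation is not axis-aligned with ",
           "positive scales; resample before analysis")
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- aff[1:3, 4]
    vox <- array(as.vector(img), dim = dims)
  } else if (ext == ".mha") {
    m <- .readMha(path)
    vox <- m$voxels; spacing <- m$spacing; origin <- m$origin
  } else {
    stop(sprintf("format error: unsupported volume format '%s'", path))
  }
  if (any(vox != round(vox)))
    stop("format error: volume does not contain integer label data")
  storage.mode(vox) <- "integer"
  LabelVolume(vox, spacing = spacing, origin = origin, schema = schema)
}

#' Write a labelled segmentation volume
#'
#' Writes NIfTI or uncompressed MetaImage depending on the file extension.
#' Label maps are stored as unsigned 8-bit when the labels fit, so a
#' read-write round trip reproduces voxels, spacing and origin exactly.
#'
#' @param vol A [LabelVolume-class].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  dtype <- if (max(vol@voxels) <= 255L && min(vol@voxels) >= 0L)
    "uint8" else "int16"
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol@voxels)
    RNifti::pixdim(img) <- vol@spacing
    aff <- rbind(cbind(diag(vol@spacing), vol@origin), c(0, 0, 0, 1))
    aff <- structure(aff, code = 2L)
    RNifti::qform(img) <- aff
    ok <- tryCatch({
      RNifti::writeNifti(img, path, datatype = dtype); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("I/O error writing '%s': %s", path,
                   conditionMessage(ok)))
  } else if (ext == ".mha") {
    .writeMha(vol, path)
  } else {
    stop(sprintf("format error: unsupported volume format '%s'", path))
  }
  invisible(path)
}

# -- minimal uncompressed MetaImage support ---------------------------------

.readMha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("format error: truncated MetaImage header")
    kv <- strsplit(line, " *= *")[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("format error: only LOCAL MetaImage payloads are supported")
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE")
    stop("format error: compressed MetaImage is not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], " +")[[1]])
  if (length(dims) != 3L)
    stop("format error: expected a 3D MetaImage")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], " +")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], " +")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  rb <- switch(type,
    MET_UCHAR = function(n) readBin(con, "integer", n, size = 1L,
                                    signed = FALSE),
    MET_CHAR = function(n) readBin(con, "integer", n, size = 1L),
    MET_SHORT = function(n) readBin(con, "integer", n, size = 2L,
                                    endian = "little"),
    MET_USHORT = function(n) readBin(con, "integer", n, size = 2L,
                                     signed = FALSE, endian = "little"),
    MET_INT = function(n) readBin(con, "integer", n, size = 4L,
                                  endian = "little"),
    stop(sprintf("format error: unsupported MetaImage ElementType '%s'",
                 type)))
  vox <- array(rb(prod(dims)), dim = dims)
  list(voxels = vox, spacing = spacing, origin = origin)
}

.writeMha <- function(vol, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("I/O error opening '%s' for writing", path)))
  on.exit(close(con))
  d <- dim(vol@voxels)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", vol@spacing[1],
                   vol@spacing[2], vol@spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g", vol@origin[1],
                   vol@origin[2], vol@origin[3]),
           if (max(vol@voxels) <= 255L && min(vol@voxels) >= 0L)
             "ElementType = MET_UCHAR" else "ElementType = MET_SHORT",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (max(vol@voxels) <= 255L && min(vol@voxels) >= 0L)
    writeBin(as.integer(vol@voxels), con, size = 1L)
  else
    writeBin(as.integer(vol@voxels), con, size = 2L, endian = "little")
  invisible(path)
}

# -- cohort tables ----------------------------------------------------------

.cohortRequired <- c("id", "age_days", "bsa_m2", "prepvo", "time_months",
                     "event")

#' Read a clinical cohort table
#'
#' CSV with header `id,age_days,bsa_m2,prepvo,time_months,event` and one
#' row per patient; `prepvo` (preoperative pulmonary venous obstruction)
#' and `event` (postsurgical pulmonary vein stenosis) are coded 0/1.
#' `time_months` is the time to PPVS when `event` is 1, otherwise the
#' censoring time.  Extra columns are retained as additional covariates.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with typed columns, one row per patient.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohortRequired, names(df))
  if (length(missing))
    stop(sprintf("cohort table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate patient id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  for (col in c("age_days", "bsa_m2", "time_months")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]))
      stop(sprintf("validation error: non-numeric '%s' at row %d", col,
                   which(is.na(df[[col]]))[1]))
  }
  bad <- which(df$bsa_m2 <= 0)
  if (length(bad))
    stop(sprintf("validation error: bsa_m2 must be > 0 (row %d)", bad[1]))
  bad <- which(df$time_months < 0)
  if (length(bad))
    stop(sprintf("validation error: time_months must be >= 0 (row %d)",
                 bad[1]))
  bad <- which(df$age_days < 0)
  if (length(bad))
    stop(sprintf("validation error: age_days must be >= 0 (row %d)", bad[1]))
  for (col in c("prepvo", "event")) {
    v <- df[[col]]
    if (is.character(v)) v <- match(tolower(v), c("false", "true")) - 1L
    v <- as.integer(v)
    if (anyNA(v) || any(!v %in% 0:1))
      stop(sprintf("validation error: '%s' must be coded 0/1", col))
    df[[col]] <- as.logical(v)
  }
  df
}
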