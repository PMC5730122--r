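#' Volume container on a fixed voxel lattice
#'
#' A `volume_grid` is a 3-D (or 4-D, for control/label time series) numeric
#' array together with voxel-size metadata in mm. All volumes in one pipeline
#' run must share shape and voxel size. The third array axis is the slice
#' axis used for per-slice post-labeling-delay adjustment; slice numbering
#' for acquisition timing is 1-based.
#'
#' @param data numeric array, 3-D or 4-D (x, y, slice\[, frame\]).
#' @param voxel_size numeric length-3, (dx, dy, dz) in mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size = c(3.5, 3.5, 8.0)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    stop("volume_grid data must be a 3-D or 4-D array, got ", nd, " dims")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size, collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

vg_like <- function(template, data) {
  volume_grid(array(data, dim(template$data)[1:3]), template$voxel_size)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3]))
    stop("shape mismatch between ", what, ": ",
         paste(dim(a$data)[1:3], collapse = "x"), " vs ",
         paste(dim(b$data)[1:3], collapse = "x"))
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-9)
    stop("voxel size mismatch between ", what)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a NIfTI-1 file into a [volume_grid], taking orientation as stored
#' (no reorientation: all pipeline inputs are assumed pre-aligned on one
#' native-space grid).
#'
#' @param path file path to a `.nii` or `.nii.gz` volume.
#' @param expect_4d if `FALSE` (default) a 4-D file is an error; set `TRUE`
#'   for control/label series.
#' @return A [volume_grid].
#' @export
read_volume <- function(path, expect_4d = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot parse '", path, "' as NIfTI: ",
                         conditionMessage(e), call. = FALSE))
  nd <- length(dim(img))
  if (!expect_4d && nd == 4L)
    stop("'", path, "' is 4-D where a 3-D volume was expected")
  if (expect_4d && nd == 3L)
    dim(img) <- c(dim(img), 1L)
  pix <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim(img)), pix)
}

#' Write a [volume_grid] as NIfTI-1
#'
#' Data are stored as 64-bit floats so that a write/read round trip is
#' bit-exact.
#'
#' @param volume a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$data)
  nd <- length(dim(volume$data))
  RNifti::pixdim(img) <- c(volume$voxel_size, rep(1, nd - 3L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Columns every cohort table must provide (after name mapping), and the
# ASL-derived subset whose absence flags — but does not drop — a subject.
cohort_required_cols <- function() {
  c("subject_id", "age", "htn", "dm", "side_occluded",
    "occlusion_complete", "collateral",
    "m1_cbf_occ", "m1_cbf_unocc", "v1_cbf_occ", "v1_cbf_unocc",
    "h_cbf_occ", "h_cbf_unocc",
    "m1_thick_occ", "m1_thick_unocc", "v1_thick_occ", "v1_thick_unocc",
    "wmh_occ", "wmh_unocc")
}

cohort_asl_cols <- function() {
  c("m1_cbf_occ", "m1_cbf_unocc", "v1_cbf_occ", "v1_cbf_unocc",
    "h_cbf_occ", "h_cbf_unocc")
}

#' Read a cohort table (CSV or SPSS .sav)
#'
#' One row per subject: demographics (age, hypertension, diabetes), side of
#' occlusion, occlusion vs high-grade stenosis, circle-of-Willis collateral
#' status, per-side M1/V1/hemispheral gray-matter CBF, per-side cortical
#' thickness and per-hemisphere white-matter-hyperintensity volume. Rows
#' missing any ASL-derived field are retained and flagged in the logical
#' `asl_missing` column; they are excluded per analysis downstream
#' (complete-case), never silently dropped here.
#'
#' @param path file path.
#' @param dialect `"csv"` (default) or `"sav"` (SPSS, e.g. a deposited raw
#'   data table).
#' @param mapping optional named character vector mapping required canonical
#'   column names to the names used in the file,
#'   e.g. `c(m1_cbf_occ = "OCCL_M1_CBF")`.
#' @return A `data.frame` of class `cohort_table` with canonical columns and
#'   an `asl_missing` flag.
#' @export
read_cohort <- function(path, dialect = c("csv", "sav"), mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- switch(dialect,
    csv = tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                     stop("cannot parse '", path, "' as CSV: ",
                          conditionMessage(e), call. = FALSE)),
    sav = suppressWarnings(
      foreign::read.spss(path, to.data.frame = TRUE,
                         use.value.labels = FALSE)))
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("mapping refers to absent column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df a data frame holding the canonical cohort columns.
#' @return The validated `cohort_table` with an `asl_missing` flag column.
#' @export
as_cohort_table <- function(df) {
  req <- cohort_required_cols()
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(req, c("subject_id", "side_occluded", "collateral"))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if (!all(df$side_occluded %in% c("L", "R")))
    stop("side_occluded must be 'L' or 'R'")
  thick <- unlist(df[, grep("_thick_", names(df))])
  if (any(!is.na(thick) & (thick <= 0 | thick >= 6)))
    stop("cortical thickness values must lie in (0, 6) mm")
  cbf <- unlist(df[, grep("_cbf_", names(df))])
  if (any(!is.na(cbf) & cbf < 0))
    stop("CBF values must be non-negative")
  df$asl_missing <- apply(is.na(df[, cohort_asl_cols()]), 1L, any)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table as CSV
#'
#' @param table a `cohort_table` (or plain data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table)
  df$asl_missing <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
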