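#' Read a volume from disk
#'
#' Supported dialects: NIfTI (`.nii` / `.nii.gz`, via the RNifti
#' library) and raw binary with a YAML sidecar header (a `.yaml` file
#' with fields `data` (relative binary filename), `shape` (3 integers),
#' `spacing` (mm), `dtype` (`double`, `float`, `int16` or `int32`) and
#' `endian`).  DICOM series are not supported by this build; convert to
#' NIfTI first.
#'
#' @param path File path (`.nii`, `.nii.gz`, or the `.yaml` header of a
#'   raw volume).
#' @param spacing Optional spacing override (mm); required if the header
#'   carries none.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    if (!is.null(spacing)) sp <- rep(as.numeric(spacing), length.out = 3)
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("NIfTI header carries no usable voxel spacing; ",
           "supply `spacing`")
    a <- as.array(img)
    if (length(dim(a)) == 4L && dim(a)[4] == 1L)
      a <- array(a, dim = dim(a)[1:3])
    return(scalar_volume(a, sp))
  }
  if (grepl("\\.ya?ml$", path)) {
    hdr <- yaml::read_yaml(path)
    need <- c("data", "shape", "dtype")
    if (!all(need %in% names(hdr)))
      stop("raw header missing fields: ",
           paste(setdiff(need, names(hdr)), collapse = ", "),
           " (expected a YAML header describing the binary volume)")
    sp <- spacing %||% hdr$spacing
    if (is.null(sp)) stop("raw header carries no spacing; supply `spacing`")
    shape <- as.integer(hdr$shape)
    if (length(shape) != 3L) stop("raw header shape must have 3 entries")
    bin <- file.path(dirname(path), hdr$data)
    if (!file.exists(bin)) stop("raw data file not found: ", bin)
    what <- switch(hdr$dtype,
                   double = "double", float = "double",
                   int16 = "integer", int32 = "integer",
                   stop("unsupported dtype: ", hdr$dtype))
    size <- switch(hdr$dtype, double = 8L, float = 4L, int16 = 2L,
                   int32 = 4L)
    n <- prod(shape)
    v <- readBin(bin, what = what, n = n + 1, size = size,
                 endian = hdr$endian %||% "little")
    if (length(v) != n)
      stop("raw volume size mismatch: header declares ", n,
           " voxels, file holds ", length(v))
    return(scalar_volume(array(as.numeric(v), dim = shape), sp))
  }
  if (grepl("\\.dcm$", path) || dir.exists(path))
    stop("DICOM series input is not supported by this build; ",
         "convert the series to NIfTI")
  stop("unrecognised volume format: ", path,
       " (expected .nii, .nii.gz or a .yaml raw header)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume or mask to NIfTI
#'
#' @param vol A [scalar_volume()], or a logical/numeric array with
#'   `spacing` given.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Spacing when `vol` is a bare array.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "scalar_volume")) {
    a <- vol$data; sp <- vol$spacing
  } else {
    a <- vol * 1; sp <- rep(as.numeric(spacing), length.out = 3)
    if (is.null(spacing)) stop("supply `spacing` for bare arrays")
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume as raw binary plus YAML header
#'
#' @param vol A [scalar_volume()].
#' @param stem Output path stem; writes `<stem>.yaml` and `<stem>.bin`.
#' @return The header path, invisibly.
#' @export
write_volume_raw <- function(vol, stem) {
  bin <- paste0(stem, ".bin")
  hdr <- paste0(stem, ".yaml")
  writeBin(as.numeric(vol$data), bin, size = 8, endian = "little")
  yaml::write_yaml(list(data = basename(bin),
                        shape = dim(vol$data),
                        spacing = vol$spacing,
                        dtype = "double", endian = "little"), hdr)
  invisible(hdr)
}

#' Write a segmentation/quantification report as JSON
#'
#' @param x A list (or `rv_quant` / `glance()`able object).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "rv_quant"))
    x <- list(segments = x$segments,
              global_max_ratio = x$global_max_ratio,
              cavity_volume_ml = x$cavity_volume_ml)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write a polar map as a CSV matrix
#'
#' @param map An `rv_polar_map`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_polar_map_csv <- function(map, path) {
  m <- map$grid
  colnames(m) <- sprintf("az%02d", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
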