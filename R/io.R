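#' Write a multi-echo series as NIfTI with a JSON sidecar
#'
#' The image stack is stored as a float32 NIfTI volume with the echo
#' dimension last; echo times (ms), pixel size, and labels go into a JSON
#' sidecar next to the stack (same path with the NIfTI extension replaced by
#' `.json`).
#'
#' @param series An [echo_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  img <- RNifti::asNifti(series$pixels, datatype = "float")
  RNifti::writeNifti(img, path)
  side <- list(echo_times_ms = series$echo_times,
               pixel_size_mm = series$pixel_size,
               sample_id = series$sample_id,
               time_point = series$time_point)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a multi-echo series written by [write_echo_series()]
#'
#' @param path Path to the NIfTI stack; the JSON sidecar must sit next to it.
#' @return An [echo_series()].
#' @export
read_echo_series <- function(path) {
  side_path <- .sidecar_path(path)
  if (!file.exists(side_path))
    stop("missing echo-time sidecar: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  echo_series(arr, echo_times = side$echo_times_ms,
              pixel_size = side$pixel_size_mm,
              sample_id = side$sample_id, time_point = side$time_point)
}

#' Write / read a binary mask as PNG
#'
#' Nonzero pixels are inside the region.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path Output `.png` path.
#' @return `path` invisibly (write) or a logical matrix (read).
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask)) mask <- mask > 0
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a T2 map as float32 NIfTI
#'
#' Pixels outside the fitted region are stored as NaN.
#'
#' @param map A [fit_t2_map()] result.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_t2_map <- function(map, path) {
  stopifnot(inherits(map, "t2_map"))
  RNifti::writeNifti(RNifti::asNifti(map$t2, datatype = "float"), path)
  invisible(path)
}

#' Render a color-coded T2 map as PNG
#'
#' Maps T2 values onto a blue-to-red color scale over a fixed display range
#' (the conventional presentation of cartilage T2 maps); pixels outside the
#' fitted region are black.
#'
#' @param map A [fit_t2_map()] result or a numeric matrix of ms values.
#' @param path Output `.png` path.
#' @param display_range Length-2 display window in ms (default `c(0, 120)`).
#' @return `path`, invisibly.
#' @export
write_t2_png <- function(map, path, display_range = c(0, 120)) {
  vals <- if (inherits(map, "t2_map")) map$t2 else map
  stopifnot(is.matrix(vals), display_range[2] > display_range[1])
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "green",
                                 "yellow", "red", "#7F0000"))
  x <- (vals - display_range[1]) / diff(display_range)
  x <- pmin(pmax(x, 0), 1)
  rgb <- array(0, dim = c(nrow(vals), ncol(vals), 3))
  ok <- !is.na(x)
  if (any(ok)) {
    cols <- ramp(x[ok]) / 255
    for (ch in 1:3) {
      plane <- matrix(0, nrow(vals), ncol(vals))
      plane[ok] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
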