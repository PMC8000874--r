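#' Split a sample mask into equally thick superficial and deep layers
#'
#' Determines the tissue height in every image column of the whole-sample mask
#' and partitions each column into two equally thick layers: the top
#' `ceiling(h / 2)` pixels (articular-surface side, row 1 upward) become the
#' superficial layer, the remainder the deep layer. Odd column heights assign
#' the extra pixel to the superficial layer. For data acquired with the
#' opposite vertical convention set `surface_top = FALSE`.
#'
#' Within every occupied column the mask must be vertically contiguous;
#' columns with gaps raise an error since the local height would be undefined.
#'
#' @param mask Logical (or 0/1) matrix; nonzero pixels are inside the sample.
#' @param surface_top Is row 1 the articular surface? Default `TRUE`.
#' @return An object of class `roi_layers`: logical matrices `whole`,
#'   `superficial`, `deep` (disjoint, union = whole) and the integer vector
#'   `heights` of per-column pixel counts (0 for empty columns).
#' @examples
#' m <- matrix(TRUE, 5, 10)
#' l <- split_layers(m)
#' colSums(l$superficial)  # 3 everywhere (ceil rule)
#' @export
split_layers <- function(mask, surface_top = TRUE) {
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nr <- nrow(mask)
  sup <- deep <- matrix(FALSE, nr, ncol(mask))
  heights <- integer(ncol(mask))
  for (cc in seq_len(ncol(mask))) {
    rows <- which(mask[, cc])
    h <- length(rows)
    heights[cc] <- h
    if (h == 0L) next
    if (rows[h] - rows[1] + 1L != h)
      stop(sprintf("mask column %d is not vertically contiguous", cc),
           call. = FALSE)
    n_sup <- as.integer(ceiling(h / 2))
    if (surface_top) {
      sup[rows[seq_len(n_sup)], cc] <- TRUE
      deep[rows[seq.int(n_sup + 1L, length.out = h - n_sup)], cc] <- TRUE
    } else {
      deep[rows[seq_len(h - n_sup)], cc] <- TRUE
      sup[rows[seq.int(h - n_sup + 1L, length.out = n_sup)], cc] <- TRUE
    }
  }
  structure(list(whole = mask, superficial = sup, deep = deep,
                 heights = heights),
            class = "roi_layers")
}

#' Summary statistics of a T2 map over a region of interest
#'
#' Mean, sample standard deviation, and pixel count of the fitted T2 values
#' inside `roi`, restricted to pixels the map marks as includable (fitted,
#' unclamped, above the R-squared threshold).
#'
#' @param map A [fit_t2_map()] result, or a plain numeric matrix (then all
#'   non-`NA` pixels are includable).
#' @param roi Logical (or 0/1) matrix, same shape as the map.
#' @param roi_name Label used in error messages and output.
#' @return A one-row data.frame: `roi`, `mean` (ms), `sd` (ms), `n_pixels`.
#' @export
roi_summary <- function(map, roi, roi_name = "roi") {
  if (inherits(map, "t2_map")) {
    vals <- map$t2
    ok <- map$include
  } else {
    stopifnot(is.matrix(map))
    vals <- map
    ok <- !is.na(map)
  }
  if (!is.logical(roi)) roi <- roi > 0
  stopifnot(identical(dim(roi), dim(vals)))
  v <- vals[roi & ok]
  if (length(v) == 0L)
    stop(sprintf("ROI '%s' contains no usable fitted pixels", roi_name),
         call. = FALSE)
  data.frame(roi = roi_name, mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             n_pixels = length(v), stringsAsFactors = FALSE)
}
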