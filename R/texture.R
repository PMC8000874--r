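#' Quantize a T2 map into gray levels for GLCM analysis
#'
#' Uniformly bins T2 values inside the ROI into `levels` gray levels. With the
#' default fixed 0-120 ms range, level images are comparable across samples
#' and time points, so longitudinal texture trends are not normalized away;
#' `"roi_minmax"` rescales per map instead. Values are clipped to the range
#' ends; a degenerate (constant) `roi_minmax` range collapses to a single
#' level by convention.
#'
#' @param map A [fit_t2_map()] result or a plain numeric matrix (ms).
#' @param roi Logical (or 0/1) matrix delimiting the region of interest.
#' @param levels Number of gray levels L (>= 2, default 32).
#' @param range_mode `"fixed"` (default) or `"roi_minmax"`.
#' @param range_ms Length-2 numeric, the fixed binning range in ms
#'   (default `c(0, 120)`); ignored under `"roi_minmax"`.
#' @return An object of class `quantized_map`: `levels_img` (integer matrix of
#'   levels `0..L-1`, `NA` outside the usable ROI), `L`, `value_range` (ms),
#'   `bin_centers` (ms, one per level).
#' @export
quantize <- function(map, roi, levels = 32, range_mode = c("fixed", "roi_minmax"),
                     range_ms = c(0, 120)) {
  range_mode <- match.arg(range_mode)
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be >= 2", call. = FALSE)
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
  use <- roi & ok
  if (!any(use)) stop("ROI contains no usable pixels to quantize", call. = FALSE)
  if (range_mode == "fixed") {
    lo <- range_ms[1]; hi <- range_ms[2]
    if (!(hi > lo)) stop("fixed range must have max > min", call. = FALSE)
  } else {
    lo <- min(vals[use]); hi <- max(vals[use])
  }
  img <- matrix(NA_integer_, nrow(vals), ncol(vals))
  if (hi > lo) {
    lv <- floor((vals[use] - lo) / (hi - lo) * levels)
    img[use] <- as.integer(pmin(pmax(lv, 0), levels - 1L))
    centers <- lo + (seq_len(levels) - 0.5) * (hi - lo) / levels
  } else {
    img[use] <- 0L                       # constant map: one occupied level
    centers <- rep(lo, levels)
  }
  structure(list(levels_img = img, L = levels, value_range = c(lo, hi),
                 bin_centers = centers),
            class = "quantized_map")
}

# Pixel offset (drow, dcol) for a GLCM orientation in degrees. With row 1 at
# the top of the image, 90 degrees is the vertical neighbour; the sign is
# irrelevant under symmetric accumulation.
.glcm_offset <- function(orientation) {
  switch(as.character(orientation),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("orientation must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix over a masked region
#'
#' Counts all pixel pairs `(p, p + offset)` one pixel apart in the given
#' orientation where both pixels are inside the ROI and quantized; pairs
#' crossing the ROI boundary or touching undefined pixels are discarded, so no
#' texture is fabricated at edges. Accumulation is symmetric (each pair is
#' counted in both directions) and the matrix is normalized to sum 1.
#'
#' @param qmap A [quantize()] result.
#' @param orientation One of 0, 45, 90, 135 (degrees).
#' @return An object of class `glcm`: `matrix` (L x L, sums to 1, symmetric),
#'   `orientation`, `offset`, `n_pairs` (number of distinct pixel pairs).
#' @export
glcm <- function(qmap, orientation) {
  stopifnot(inherits(qmap, "quantized_map"))
  off <- .glcm_offset(orientation)
  img <- qmap$levels_img
  nr <- nrow(img); nc <- ncol(img)
  r_lo <- max(1L, 1L - off[1]); r_hi <- min(nr, nr - off[1])
  c_lo <- max(1L, 1L - off[2]); c_hi <- min(nc, nc - off[2])
  if (r_lo > r_hi || c_lo > c_hi)
    stop(sprintf("no valid pixel pairs at orientation %s", orientation),
         call. = FALSE)
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  a <- img[r1, c1, drop = FALSE]
  b <- img[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep))
    stop(sprintf("no valid pixel pairs at orientation %s", orientation),
         call. = FALSE)
  L <- qmap$L
  i <- a[keep]; j <- b[keep]
  counts <- tabulate(i * L + j + 1L, nbins = L * L) +
    tabulate(j * L + i + 1L, nbins = L * L)
  m <- matrix(counts / sum(counts), L, L)
  structure(list(matrix = m, orientation = orientation, offset = off,
                 n_pairs = sum(keep)),
            class = "glcm")
}

#' Texture features of a single GLCM
#'
#' With `p(i, j)` the normalized co-occurrence frequencies over 0-based levels:
#' contrast `sum p (i - j)^2` (local gray-level variation), homogeneity
#' `sum p / (1 + |i - j|)` (similarity of neighbouring pixels), energy
#' `sum p^2` (angular second moment; orderliness), and variance
#' `sum p (i - mu)^2` with `mu = sum i p(i, j)` (spread around the mean level;
#' the symmetric accumulation makes the row and column means equal). When bin
#' centres are supplied, `variance_ms2` additionally reports the variance on
#' the T2 scale in ms^2.
#'
#' @param g A [glcm()] result.
#' @param bin_centers Optional bin centres in ms for the ms^2 variance.
#' @return A one-row data.frame: `contrast`, `homogeneity`, `energy`,
#'   `variance` (level units), and `variance_ms2` if requested.
#' @export
glcm_features <- function(g, bin_centers = NULL) {
  stopifnot(inherits(g, "glcm"))
  p <- g$matrix
  if (abs(sum(p) - 1) > 1e-8)
    stop("GLCM is not normalized to sum 1", call. = FALSE)
  L <- nrow(p)
  idx <- 0:(L - 1)
  ii <- matrix(idx, L, L)        # row level index
  jj <- t(ii)
  contrast <- sum(p * (ii - jj)^2)
  homogeneity <- sum(p / (1 + abs(ii - jj)))
  energy <- sum(p^2)
  mu <- sum(ii * p)
  variance <- sum(p * (ii - mu)^2)
  out <- data.frame(contrast = contrast, homogeneity = homogeneity,
                    energy = energy, variance = variance)
  if (!is.null(bin_centers)) {
    stopifnot(length(bin_centers) == L)
    ci <- matrix(bin_centers, L, L)
    mu_ms <- sum(ci * p)
    out$variance_ms2 <- sum(p * (ci - mu_ms)^2)
  }
  out
}

#' Orientation-averaged GLCM texture features
#'
#' Computes the four features for each one-pixel offset orientation (0, 45,
#' 90, 135 degrees) and arithmetic-means each feature over the orientations
#' that produced at least one valid pixel pair. Feature values, not matrices,
#' are averaged.
#'
#' @param qmap A [quantize()] result.
#' @param orientations Orientations to use (default all four).
#' @param ms_variance Also report variance on the ms scale?
#' @return A list: `averaged` (one-row data.frame of averaged features),
#'   `per_orientation` (data.frame with one row per contributing orientation,
#'   including `n_pairs`), `orientations_used`.
#' @export
orientation_averaged_features <- function(qmap,
                                          orientations = c(0, 45, 90, 135),
                                          ms_variance = TRUE) {
  stopifnot(inherits(qmap, "quantized_map"))
  rows <- list()
  for (o in orientations) {
    g <- tryCatch(glcm(qmap, o), error = function(e) NULL)
    if (is.null(g)) next
    f <- glcm_features(g, bin_centers = if (ms_variance) qmap$bin_centers)
    f <- cbind(data.frame(orientation = o, n_pairs = g$n_pairs), f)
    rows[[length(rows) + 1L]] <- f
  }
  if (length(rows) == 0L)
    stop("no orientation produced a valid pixel pair", call. = FALSE)
  per <- do.call(rbind, rows)
  feat_cols <- setdiff(names(per), c("orientation", "n_pairs"))
  averaged <- as.data.frame(as.list(colMeans(per[feat_cols])))
  list(averaged = averaged, per_orientation = per,
       orientations_used = per$orientation)
}
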