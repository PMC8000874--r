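#' Pixel-wise mono-exponential T2 fitting
#'
#' Fits `S(TE) = S0 * exp(-TE / T2)` to each row of a signal matrix.
#'
#' The default `loglinear` method is an unweighted least-squares fit of
#' `log(S)` against TE; it is closed-form, deterministic, and exact on
#' noiseless mono-exponential data. The `nonlinear` method refines the
#' loglinear estimate by damped Gauss-Newton (Levenberg-Marquardt) iterations
#' on the untransformed signal, which is preferable on noisy magnitude data
#' where the log transform distorts the error distribution.
#'
#' Pixels with any non-positive signal (loglinear) or an all-zero decay are
#' marked unfittable rather than raising an error. Fitted T2 is clamped to
#' `t2_range` and clamped pixels are flagged.
#'
#' @param signals Numeric matrix, pixels x echoes (a single pixel may be given
#'   as a vector).
#' @param te Echo times in ms, one per column.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @param t2_range Allowed T2 interval in ms; estimates outside are clamped
#'   and flagged.
#' @return A list of vectors: `t2` (ms), `s0`, `r_squared` in `[0, 1]`,
#'   `fittable` (logical), `clamped` (logical). `r_squared` is computed on the
#'   log-signal scale for the loglinear method and on the signal scale for the
#'   nonlinear method; negative values are truncated to 0.
#' @examples
#' te <- (2:7) * 8.38
#' s <- 1000 * exp(-te / 35)
#' fit_t2_pixels(s, te)$t2  # 35
#' @export
fit_t2_pixels <- function(signals, te, method = c("loglinear", "nonlinear"),
                          t2_range = c(1, 300)) {
  method <- match.arg(method)
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  stopifnot(is.matrix(signals), ncol(signals) == length(te))
  if (ncol(signals) < 3L)
    stop("need at least 3 echoes to fit a two-parameter decay", call. = FALSE)
  fit <- .fit_loglinear(signals, te)
  if (method == "nonlinear")
    fit <- .fit_nonlinear(signals, te, fit)
  # clamp and flag
  lo <- t2_range[1]; hi <- t2_range[2]
  clamped <- fit$fittable & (fit$t2 < lo | fit$t2 > hi | !is.finite(fit$t2))
  t2 <- fit$t2
  t2[fit$fittable & (!is.finite(t2) | t2 > hi)] <- hi
  t2[fit$fittable & t2 < lo] <- lo
  t2[!fit$fittable] <- NA_real_
  list(t2 = t2, s0 = fit$s0, r_squared = fit$r_squared,
       fittable = fit$fittable, clamped = clamped)
}

# Closed-form least squares of log(S) on TE, vectorized over pixels.
.fit_loglinear <- function(signals, te) {
  n_px <- nrow(signals); n_e <- length(te)
  fittable <- rowSums(signals <= 0 | !is.finite(signals)) == 0L
  t2 <- s0 <- r2 <- rep(NA_real_, n_px)
  if (any(fittable)) {
    y <- log(signals[fittable, , drop = FALSE])
    tc <- te - mean(te)
    ybar <- rowMeans(y)
    sxx <- sum(tc^2)
    sxy <- as.vector(y %*% tc)           # sum over echoes of tc * y
    slope <- sxy / sxx
    intercept <- ybar                     # at centred te
    resid <- y - outer(slope, tc) - intercept
    ss_res <- rowSums(resid^2)
    ss_tot <- rowSums((y - ybar)^2)
    r2f <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1)
    t2[fittable] <- ifelse(slope < 0, -1 / slope, Inf)
    s0[fittable] <- exp(intercept - slope * mean(te))
    r2[fittable] <- pmin(1, pmax(0, r2f))
  }
  list(t2 = t2, s0 = s0, r_squared = r2, fittable = fittable)
}

# Damped Gauss-Newton refinement of (S0, R = 1/T2) on the signal scale,
# vectorized over pixels with a per-pixel Levenberg-Marquardt damping factor.
.fit_nonlinear <- function(signals, te, init, max_iter = 60L, tol = 1e-12) {
  fittable <- init$fittable & rowSums(!is.finite(signals)) == 0L &
    rowSums(abs(signals)) > 0
  t2 <- init$t2; s0 <- init$s0; r2 <- init$r_squared
  if (!any(fittable)) return(list(t2 = t2, s0 = s0, r_squared = r2,
                                  fittable = fittable))
  y <- signals[fittable, , drop = FALSE]
  t2i <- init$t2[fittable]
  t2i[!is.finite(t2i) | t2i <= 0] <- max(te)     # start mid-range if degenerate
  a <- init$s0[fittable]
  bad <- !is.finite(a) | a <= 0
  a[bad] <- pmax(y[bad, 1], .Machine$double.eps)
  r <- 1 / t2i
  sse <- function(a, r) {
    model <- a * exp(-outer(r, te))
    rowSums((model - y)^2)
  }
  f_old <- sse(a, r)
  lambda <- rep(1e-3, length(a))
  for (iter in seq_len(max_iter)) {
    e <- exp(-outer(r, te))               # n_px x n_e
    model <- a * e
    res <- model - y
    # Jacobian columns: d/da = e ; d/dr = -te * a * e
    j2 <- -model * rep(te, each = nrow(e))
    a11 <- rowSums(e * e)
    a12 <- rowSums(e * j2)
    a22 <- rowSums(j2 * j2)
    g1 <- rowSums(e * res)
    g2 <- rowSums(j2 * res)
    d11 <- a11 * (1 + lambda)
    d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12^2
    det[det == 0] <- .Machine$double.eps
    da <- -(d22 * g1 - a12 * g2) / det
    dr <- -(d11 * g2 - a12 * g1) / det
    a_new <- a + da
    r_new <- pmax(r + dr, 1e-6)
    a_new <- pmax(a_new, .Machine$double.eps)
    f_new <- sse(a_new, r_new)
    accept <- f_new <= f_old
    a <- ifelse(accept, a_new, a)
    r <- ifelse(accept, r_new, r)
    f_prev <- f_old
    f_old <- ifelse(accept, f_new, f_old)
    lambda <- ifelse(accept, pmax(lambda / 3, 1e-12), pmin(lambda * 5, 1e10))
    if (max(abs(f_prev - f_old) / pmax(f_prev, 1e-300)) < tol) break
  }
  ybar <- rowMeans(y)
  ss_tot <- rowSums((y - ybar)^2)
  r2f <- ifelse(ss_tot > 0, 1 - f_old / ss_tot, 1)
  t2[fittable] <- 1 / r
  s0[fittable] <- a
  r2[fittable] <- pmin(1, pmax(0, r2f))
  list(t2 = t2, s0 = s0, r_squared = r2, fittable = fittable)
}

#' Fit a pixel-wise T2 map over a masked region
#'
#' Applies [fit_t2_pixels()] to every pixel inside `mask`, using only the
#' echoes selected by the schedule's `fit_echo_indices` (default echoes 2-7,
#' i.e. TE < 60 ms excluding the first echo).
#'
#' @param series An [echo_series()].
#' @param mask Logical matrix matching the image plane; pixels to fit.
#' @param schedule An [echo_schedule()]; its echo count must match the series.
#' @param method Passed to [fit_t2_pixels()].
#' @param t2_range T2 clamp interval in ms.
#' @param r2_threshold Minimum R-squared for a pixel to enter downstream ROI
#'   statistics (the `include` raster).
#' @return An object of class `t2_map`: matrices `t2`, `s0`, `r_squared`
#'   (`NA` outside the fitted region), `fit_mask` (pixels that yielded a fit),
#'   `clamped`, and `include` (fitted, unclamped, and above the R-squared
#'   threshold), plus `pixel_size`, `sample_id`, `time_point`.
#' @export
fit_t2_map <- function(series, mask, schedule = echo_schedule(),
                       method = c("loglinear", "nonlinear"),
                       t2_range = c(1, 300), r2_threshold = 0.7) {
  method <- match.arg(method)
  stopifnot(inherits(series, "echo_series"), inherits(schedule, "echo_schedule"))
  dims <- dim(series$pixels)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dims[1:2]))
    stop("mask shape does not match the image plane", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (dims[3] != schedule$n_echoes)
    stop("echo count of the series does not match the schedule", call. = FALSE)
  sel <- schedule$fit_echo_indices
  if (length(sel) < 3L)
    stop("need at least 3 echoes in the fit subset", call. = FALSE)
  te <- series$echo_times[sel]
  flat <- matrix(series$pixels, prod(dims[1:2]), dims[3])
  sig <- flat[as.vector(mask), sel, drop = FALSE]
  fit <- fit_t2_pixels(sig, te, method = method, t2_range = t2_range)
  blank <- matrix(NA_real_, dims[1], dims[2])
  t2 <- s0 <- r2 <- blank
  t2[mask] <- fit$t2
  s0[mask] <- fit$s0
  r2[mask] <- fit$r_squared
  fit_mask <- clamped <- matrix(FALSE, dims[1], dims[2])
  fit_mask[mask] <- fit$fittable
  clamped[mask] <- fit$clamped
  include <- fit_mask & !clamped & !is.na(r2) & r2 >= r2_threshold
  structure(
    list(t2 = t2, s0 = s0, r_squared = r2, fit_mask = fit_mask,
         clamped = clamped, include = include,
         r2_threshold = r2_threshold, t2_range = t2_range,
         pixel_size = series$pixel_size, sample_id = series$sample_id,
         time_point = series$time_point),
    class = "t2_map"
  )
}
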