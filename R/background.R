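#' Cubic polynomial basis for background fields
#'
#' Evaluates the 10-term third-degree basis used for the spatial background,
#' in the coefficient order `a1..a10`:
#' `x^2, y^2, xy, x, y, 1, x^3, y^3, x^2 y, y^2 x`.
#'
#' @param x,y Numeric pixel coordinates (0-based pixel centers).
#' @return A `length(x) x 10` design matrix.
#' @export
poly_background_basis <- function(x, y) {
  cbind(x^2, y^2, x * y, x, y, 1, x^3, y^3, x^2 * y, y^2 * x)
}

#' Evaluate a background polynomial
#'
#' @param coefficients Length-10 vector `a1..a10`.
#' @inheritParams poly_background_basis
#' @return Numeric vector of background values.
#' @export
eval_poly_background <- function(coefficients, x, y) {
  as.vector(poly_background_basis(x, y) %*% coefficients)
}

#' Identify signal (non-background) pixels in the first frame
#'
#' Marks pixels whose value in the first excitation-illuminated frame
#' exceeds a robust background level — median plus `n_mad` MAD-based sigmas —
#' then dilates the mask to swallow PSF tails, and additionally masks all
#' designated evaluation regions. Masked pixels are excluded from every
#' polynomial background fit.
#'
#' @param first_frame Numeric matrix (one image).
#' @param evaluation_regions Optional data frame with columns `x`, `y`
#'   (0-based region centers) whose full regions are always masked.
#' @param region_size Edge length of the evaluation regions.
#' @param n_mad Threshold in MAD-based sigmas above the median (default 5).
#' @param dilate Dilation radius in pixels applied to the thresholded mask.
#' @return Logical matrix, `TRUE` for discarded (signal) pixels.
#' @export
identify_signal_pixels <- function(first_frame, evaluation_regions = NULL,
                                   region_size = 7, n_mad = 5, dilate = 2) {
  stopifnot(is.matrix(first_frame))
  v <- as.vector(first_frame)
  thr <- stats::median(v) + n_mad * stats::mad(v)
  mask <- first_frame > thr
  if (dilate > 0 && any(mask)) mask <- dilate_mask(mask, dilate)
  if (!is.null(evaluation_regions) && nrow(evaluation_regions) > 0) {
    H <- nrow(first_frame); W <- ncol(first_frame)
    for (i in seq_len(nrow(evaluation_regions))) {
      px <- region_pixels(c(evaluation_regions$x[i],
                            evaluation_regions$y[i]), region_size)
      keep <- px$x >= 0 & px$x <= W - 1 & px$y >= 0 & px$y <= H - 1
      mask[cbind(px$y[keep] + 1L, px$x[keep] + 1L)] <- TRUE
    }
  }
  if (mean(mask) > 0.9) {
    warning("more than 90% of pixels masked; background fit may be ",
            "unreliable", call. = FALSE)
  }
  mask
}

# binary dilation by a square structuring element of radius r
dilate_mask <- function(mask, r) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dy in -r:r) {
    ys <- pmin(pmax(seq_len(H) + dy, 1L), H)
    for (dx in -r:r) {
      if (dx == 0 && dy == 0) next
      xs <- pmin(pmax(seq_len(W) + dx, 1L), W)
      out <- out | mask[ys, xs, drop = FALSE]
    }
  }
  out
}

#' Fit the cubic polynomial background to one frame
#'
#' Least-squares fit of the 10-term third-degree basis over unmasked pixels.
#' Internally the fit runs on coordinates rescaled to `[-1, 1]` per axis —
#' cubic terms in raw pixel coordinates are numerically ill-conditioned —
#' and the coefficients are converted back to the raw 0-based coordinate
#' basis, so the returned `a1..a10` apply directly to pixel coordinates.
#'
#' @param frame Numeric matrix (one image).
#' @param mask Optional logical matrix of discarded pixels
#'   ([identify_signal_pixels()]).
#' @return A list with `coefficients` (length 10, raw basis), `residual_rms`
#'   and `n_pixels`.
#' @export
fit_polynomial_background <- function(frame, mask = NULL) {
  stopifnot(is.matrix(frame))
  H <- nrow(frame); W <- ncol(frame)
  use <- if (is.null(mask)) rep(TRUE, H * W) else {
    stopifnot(dim(mask) == dim(frame)); !as.vector(mask)
  }
  xs <- rep(0:(W - 1), each = H)[use]
  ys <- rep(0:(H - 1), times = W)[use]
  z <- as.vector(frame)[use]
  if (length(z) < 10) {
    stop("need at least 10 unmasked pixels for the 10-term basis",
         call. = FALSE)
  }
  # scaled coordinates for conditioning
  sx <- max(W - 1, 1) / 2; sy <- max(H - 1, 1) / 2
  A <- poly_background_basis((xs - sx) / sx, (ys - sy) / sy)
  qrA <- qr(A)
  if (qrA$rank < 10) {
    stop("rank-deficient background design (rank ", qrA$rank,
         " of 10): unmasked pixels do not span the cubic basis",
         call. = FALSE)
  }
  b <- qr.coef(qrA, z)
  fitted <- as.vector(A %*% b)
  # convert to the raw-coordinate basis by exact interpolation on a grid
  gx <- seq(0, max(W - 1, 3), length.out = 4)
  gy <- seq(0, max(H - 1, 3), length.out = 4)
  g <- expand.grid(x = gx, y = gy)
  vals <- as.vector(poly_background_basis((g$x - sx) / sx,
                                          (g$y - sy) / sy) %*% b)
  a <- qr.solve(poly_background_basis(g$x, g$y), vals)
  list(coefficients = as.vector(a),
       residual_rms = sqrt(mean((z - fitted)^2)),
       n_pixels = length(z))
}

#' Fit the background polynomial to every frame of a stack
#'
#' @param frames `height x width x n_frames` array or `synthetic_movie`.
#' @param mask Logical matrix of discarded pixels, applied to all frames.
#' @return An object of class `polynomial_background`: `coefficients`
#'   (`n_frames x 10` matrix), `mask`, `residual_rms` per frame.
#' @export
fit_background_stack <- function(frames, mask = NULL) {
  if (inherits(frames, "synthetic_movie")) frames <- frames$frames
  stopifnot(length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  coefs <- matrix(0, nf, 10)
  rms <- numeric(nf)
  for (t in seq_len(nf)) {
    f <- fit_polynomial_background(frames[, , t], mask)
    coefs[t, ] <- f$coefficients
    rms[t] <- f$residual_rms
  }
  structure(list(coefficients = coefs, mask = mask, residual_rms = rms),
            class = "polynomial_background")
}

#' Per-frame background sum over an evaluation region
#'
#' @param background A `polynomial_background` ([fit_background_stack()]).
#' @param center `c(x, y)` 0-based region center.
#' @param region_size Odd edge length (default 7).
#' @return Numeric vector: `sum_i P_t(x_i, y_i)` for each frame `t`.
#' @export
background_region_sum <- function(background, center, region_size = 7) {
  stopifnot(inherits(background, "polynomial_background"))
  px <- region_pixels(center, region_size)
  B <- poly_background_basis(px$x, px$y)
  as.vector(background$coefficients %*% colSums(B))
}

#' Estimate the region-specific background offset
#'
#' After subtraction of the global polynomial background a region trace
#' still carries a small region-specific offset `mu`. It is estimated by
#' fitting a Gaussian (center `mu`, width `s`) to the histogram of trace
#' values; blink frames are excluded by iteratively trimming values beyond
#' 3 current widths from the current center, so only the background-
#' dominated central peak is fit. Binning uses the Freedman–Diaconis rule
#' and the Gaussian is fit by least squares on bin counts.
#'
#' @param trace Numeric vector, or data frame with a `value` column, of
#'   polynomial-subtracted region values.
#' @param max_iter Maximum trimming iterations.
#' @return An object of class `region_calibration`: list with `mu`, `s`,
#'   `n_used`, `iterations`, and the final histogram fit.
#' @export
estimate_region_offset <- function(trace, max_iter = 10) {
  v <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  v <- v[is.finite(v)]
  if (length(v) < 20) {
    stop("need at least 20 frames to calibrate the region offset",
         call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    stop("degenerate trace (all values equal): spread s would be 0",
         call. = FALSE)
  }
  mu <- stats::median(v); s <- stats::mad(v)
  if (s == 0) s <- stats::sd(v)
  keep_old <- rep(TRUE, length(v))
  fit <- NULL; it <- 0L
  for (it in seq_len(max_iter)) {
    keep <- abs(v - mu) <= 3 * s
    if (sum(keep) < 20) break
    fit <- gaussian_histogram_fit(v[keep], mu, s)
    mu <- fit$mu; s <- fit$s
    if (identical(keep, keep_old)) break
    keep_old <- keep
  }
  structure(list(mu = mu, s = s, n_used = sum(keep_old),
                 iterations = it, fit = fit),
            class = "region_calibration")
}

#' @export
print.region_calibration <- function(x, ...) {
  cat("<region_calibration> mu =", format(x$mu), " s =", format(x$s),
      " (", x$n_used, "frames,", x$iterations, "iterations )\n")
  invisible(x)
}

# least-squares Gaussian fit to a Freedman-Diaconis histogram of v
gaussian_histogram_fit <- function(v, mu0, s0) {
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (bw <= 0) bw <- diff(range(v)) / 30
  brk <- seq(min(v) - bw, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = brk, plot = FALSE)
  d <- data.frame(mid = h$mids, count = h$counts)
  start <- list(A = max(d$count), mu = mu0, s = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * s^2)),
                      data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # moment fallback when the histogram is too coarse for the LS fit
    return(list(mu = mean(v), s = stats::sd(v), histogram = d,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), s = abs(unname(cf["s"])), histogram = d,
       converged = TRUE)
}

#' Background-correct a raw region trace
#'
#' Subtracts, frame by frame, the polynomial background summed over the
#' region pixels and the region-specific offset `mu`:
#' `Y_t = Y_t,measured - sum_i P_t(x_i, y_i) - mu`.
#'
#' @param raw_trace Numeric vector or data frame with `frame`, `value`
#'   columns: raw per-frame region sums.
#' @param background A `polynomial_background` covering every frame of the
#'   trace.
#' @param calibration Optional `region_calibration`; `mu = 0` when `NULL`.
#' @param center `c(x, y)` region center used for the polynomial sum.
#' @param region_size Odd edge length (default 7).
#' @return A tibble with `frame`, `value` (corrected signal).
#' @export
correct_trace <- function(raw_trace, background, calibration = NULL,
                          center, region_size = 7) {
  v <- if (is.data.frame(raw_trace)) raw_trace$value else
    as.numeric(raw_trace)
  nf <- length(v)
  if (nrow(background$coefficients) < nf) {
    stop("background fitted for ", nrow(background$coefficients),
         " frames but the trace has ", nf, call. = FALSE)
  }
  bsum <- background_region_sum(background, center, region_size)[seq_len(nf)]
  mu <- if (is.null(calibration)) 0 else calibration$mu
  tibble::tibble(frame = seq_len(nf), value = v - bsum - mu)
}

#' Detect candidate evaluation regions in the first frame
#'
#' Heuristic spot finder: smooths the first frame with a small Gaussian
#' kernel and returns local maxima above a robust threshold, spaced at least
#' one region apart. Intended to seed the per-region analysis; any external
#' detection can be substituted.
#'
#' @param first_frame Numeric matrix.
#' @param region_size Region edge length (also the minimum spot separation).
#' @param n_mad Detection threshold in MAD sigmas above the median.
#' @return A tibble with 0-based `x`, `y` centers and `peak` values.
#' @export
detect_evaluation_regions <- function(first_frame, region_size = 7,
                                      n_mad = 5) {
  stopifnot(is.matrix(first_frame))
  H <- nrow(first_frame); W <- ncol(first_frame)
  sm <- smooth_image(first_frame, sigma = 1)
  thr <- stats::median(sm) + n_mad * stats::mad(sm)
  half <- (region_size - 1) / 2
  cand <- which(sm > thr, arr.ind = TRUE)
  cand <- cand[order(sm[cand], decreasing = TRUE), , drop = FALSE]
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    yy <- cand[i, 1]; xx <- cand[i, 2]
    if (xx - 1 < half || yy - 1 < half ||
        xx - 1 > W - 1 - half || yy - 1 > H - 1 - half) next
    if (nrow(centers) > 0 &&
        any(pmax(abs(centers[, 1] - (xx - 1)),
                 abs(centers[, 2] - (yy - 1))) < region_size)) next
    centers <- rbind(centers, c(xx - 1, yy - 1))
  }
  tibble::tibble(x = centers[, 1], y = centers[, 2],
                 peak = sm[cbind(centers[, 2] + 1, centers[, 1] + 1)])
}

# separable Gaussian smoothing with reflected edges
smooth_image <- function(img, sigma = 1) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    H <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(H), H + 1 - seq_len(r))
    mp <- m[pmin(pmax(idx, 1), H), , drop = FALSE]
    out <- matrix(0, H, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(seq_len(H)) + (j - 1), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}
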