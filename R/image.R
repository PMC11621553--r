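#' Select a contiguous sub-stack
#'
#' Keeps slices `first:last` (1-based, inclusive) of an image stack, e.g.
#' the 4-6 successive confocal sections that encompass a cytoplasmic
#' structure of interest.
#'
#' @param stack 3D numeric array `[y, x, slice]`; the third axis is the
#'   z (or time) axis.
#' @param first,last Slice bounds, `1 <= first <= last <= dim(stack)[3]`.
#' @return The sub-stack, a 3D array.
#' @export
select_substack <- function(stack, first, last) {
  stack <- as_stack(stack)
  ns <- dim(stack)[3]
  if (!(first >= 1 && last <= ns && first <= last &&
        first == trunc(first) && last == trunc(last))) {
    stop_calspike(
      sprintf("slice range (%s, %s) invalid for a %d-slice stack",
              format(first), format(last), ns),
      "calspike_bounds_error"
    )
  }
  stack[, , first:last, drop = FALSE]
}

#' Project a stack along its slice axis
#'
#' Element-wise maximum or arithmetic-mean z-projection.
#'
#' @param stack 3D numeric array `[y, x, slice]`.
#' @param reducer `"max"` or `"mean"`.
#' @return A 2D matrix `[y, x]`.
#' @export
project_stack <- function(stack, reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  stack <- as_stack(stack)
  d <- dim(stack)
  m <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  out <- if (reducer == "max") do.call(pmax, as.data.frame(m))
         else rowMeans(m)
  matrix(out, d[1], d[2])
}

#' Automatic (or fixed) threshold mask of a 2D image
#'
#' Computes a foreground mask `image >= threshold`. `"isodata"`
#' (Ridler-Calvard iterative intermeans, the classic ImageJ default) and
#' `"otsu"` (maximal between-class variance) pick the threshold from the
#' data; a numeric `method` uses that fixed cutoff. Foreground is bright:
#' the quantified signal is a fluorophore on a dark background.
#'
#' @param image 2D numeric matrix.
#' @param method `"isodata"` (default), `"otsu"`, or a single number for a
#'   fixed threshold.
#' @return A logical matrix with attribute `threshold` (the cutoff used)
#'   and `method`.
#' @export
threshold_mask <- function(image, method = "isodata") {
  stopifnot(is.matrix(image))
  if (is.numeric(method)) {
    thr <- method
    method_name <- "fixed"
  } else {
    method_name <- match.arg(method, c("isodata", "otsu"))
    if (length(unique(as.vector(image))) < 2L) {
      stop_calspike(
        "image has a single intensity level; automatic threshold undefined",
        "calspike_degenerate_histogram"
      )
    }
    thr <- switch(method_name,
                  isodata = isodata_threshold(image),
                  otsu = otsu_threshold(image))
  }
  mask <- image >= thr
  structure(mask, threshold = thr, method = method_name)
}

# Ridler-Calvard: iterate T <- mean(below T)/2 + mean(>= T)/2 to a fixed point.
isodata_threshold <- function(image, tol = 1e-8, max_iter = 1000L) {
  x <- as.vector(image)
  thr <- mean(range(x))
  for (i in seq_len(max_iter)) {
    lo <- x[x < thr]
    hi <- x[x >= thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < tol) { thr <- new; break }
    thr <- new
  }
  thr
}

# Otsu on the empirical distribution: maximise between-class variance over
# cuts between consecutive distinct values; threshold at the midpoint of the
# best cut so the >= rule reproduces the class split exactly.
otsu_threshold <- function(image) {
  x <- sort(as.vector(image))
  u <- unique(x)
  n <- length(x)
  counts <- tabulate(match(x, u), nbins = length(u))
  w <- cumsum(counts)
  s <- cumsum(counts * u)
  total <- s[length(s)]
  best <- -Inf
  cut <- 1L
  for (k in seq_len(length(u) - 1L)) {
    w0 <- w[k]; w1 <- n - w0
    m0 <- s[k] / w0
    m1 <- (total - s[k]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; cut <- k }
  }
  (u[cut] + u[cut + 1L]) / 2
}

#' Mean grey value under a mask
#'
#' Arithmetic mean of the pixels of `image` selected by `mask` — the
#' standard ROI readout on a projection.
#'
#' @param image 2D numeric matrix.
#' @param mask Logical matrix of the same shape with at least one `TRUE`.
#' @return A single number.
#' @export
mean_gray <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    stop_calspike("image and mask shapes differ", "calspike_invalid_input")
  }
  if (!any(mask)) {
    stop_calspike("mask selects no pixels", "calspike_empty_roi")
  }
  mean(image[mask])
}

#' Extract a fluorescence trace from a time-lapse stack
#'
#' Per frame, the mean grey value under the ROI mask; returned as a trace
#' table ready for [compute_snr()].
#'
#' @param stack 3D array `[y, x, frame]` with frames along the third axis.
#' @param mask Logical ROI matrix matching the frame shape.
#' @param dt Sampling interval in seconds between frames.
#' @param nucleus_id Identifier attached to the trace.
#' @return A tibble with columns `nucleus_id`, `time_s`, `intensity`.
#' @export
extract_trace <- function(stack, mask, dt = 5, nucleus_id = "roi_1") {
  stack <- as_stack(stack)
  vals <- vapply(seq_len(dim(stack)[3]),
                 function(k) mean_gray(stack[, , k], mask), numeric(1))
  tibble(nucleus_id = nucleus_id,
         time_s = (seq_along(vals) - 1) * dt,
         intensity = vals)
}

as_stack <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (!(is.array(stack) && length(dim(stack)) == 3L && dim(stack)[3] >= 1L)) {
    stop_calspike("`stack` must be a [y, x, slice] array with >= 1 slice",
                  "calspike_invalid_input")
  }
  if (any(stack < 0)) {
    stop_calspike("stack intensities must be non-negative",
                  "calspike_invalid_input")
  }
  stack
}

#' Simulate an image stack with known foreground regions
#'
#' Builds a toy grayscale stack: constant background plus rectangular (or
#' arbitrary-mask) foreground regions with per-slice intensities, and
#' optional additive Gaussian noise — a ground-truth fixture for the
#' projection / threshold / mean-grey pipeline and for ROI trace
#' extraction.
#'
#' @param n_slices,ny,nx Stack shape (slices along z or t, then rows, cols).
#' @param background Background intensity.
#' @param regions List of regions, each a list with `mask` (logical
#'   `ny x nx` matrix) and `intensities` (length 1 or `n_slices`). Regions
#'   must not overlap.
#' @param noise_sigma SD of additive Gaussian noise (intensity units);
#'   negative results are clipped at 0.
#' @param seed Integer seed for the noise.
#' @return A list of class `ca_stack_sim`: `stack` (3D array
#'   `[y, x, slice]`) and `masks` (list of the ground-truth logical masks).
#' @examples
#' sq <- matrix(FALSE, 8, 8); sq[3:4, 3:4] <- TRUE
#' sim <- simulate_stack(4, 8, 8, background = 10,
#'                       regions = list(list(mask = sq, intensities = 100)))
#' max(sim$stack)
#' @export
simulate_stack <- function(n_slices, ny, nx, background = 10,
                           regions = list(), noise_sigma = 0, seed = NULL) {
  check_number(n_slices, "n_slices", lower = 1, integerish = TRUE)
  check_number(ny, "ny", lower = 1, integerish = TRUE)
  check_number(nx, "nx", lower = 1, integerish = TRUE)
  check_number(background, "background", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)

  cover <- matrix(0L, ny, nx)
  for (r in regions) {
    if (!is.logical(r$mask) || !identical(dim(r$mask), c(as.integer(ny),
                                                         as.integer(nx)))) {
      stop_calspike("each region mask must be a logical ny x nx matrix",
                    "calspike_invalid_parameter")
    }
    cover <- cover + r$mask
  }
  if (any(cover > 1L)) {
    stop_calspike("foreground regions overlap", "calspike_invalid_parameter")
  }

  stack <- array(background, dim = c(ny, nx, n_slices))
  for (r in regions) {
    ints <- rep_len(r$intensities, n_slices)
    for (k in seq_len(n_slices)) {
      slice <- stack[, , k]
      slice[r$mask] <- ints[k]
      stack[, , k] <- slice
    }
  }
  if (noise_sigma > 0) {
    stack <- with_seed(seed, {
      pmax(stack + array(stats::rnorm(length(stack), 0, noise_sigma),
                         dim = dim(stack)), 0)
    })
  }
  structure(list(stack = stack, masks = purrr::map(regions, "mask")),
            class = "ca_stack_sim")
}

#' TIFF input/output for stacks and masks
#'
#' Stacks are written as multi-page grayscale TIFF (16-bit by default,
#' integer-rounded); masks as 8-bit 0/255 TIFF. `read_stack()` returns the
#' integer pixel values as a `[y, x, slice]` array; `read_mask()` returns a
#' logical matrix.
#'
#' @param stack 3D array `[y, x, slice]` of non-negative intensities.
#' @param path File path.
#' @param bits Bits per sample, 8 or 16.
#' @return `write_*` return `path` invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stack <- as_stack(stack)
  stopifnot(bits %in% c(8, 16))
  maxval <- 2^bits - 1
  if (any(stack > maxval)) {
    stop_calspike(sprintf("intensities exceed %d-bit range", bits),
                  "calspike_invalid_input")
  }
  pages <- purrr::map(seq_len(dim(stack)[3]),
                      function(k) round(stack[, , k]) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @rdname write_stack
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  img > 0
}
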