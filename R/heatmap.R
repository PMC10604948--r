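#' Gaussian heatmap specification
#'
#' Landmarks are encoded as unnormalised 2D Gaussians
#' \deqn{H(x, y) = \frac{\phi}{\sigma\sqrt{2\pi}}
#'   \exp\!\left[-\frac{(x - L^x)^2 + (y - L^y)^2}{2\sigma^2}\right]}
#' clamped to \[0, 1\]. The amplitude \eqn{\phi} defaults to 5; the default
#' \eqn{\sigma = \phi / \sqrt{2\pi} \approx 1.9947} px makes the peak value
#' exactly 1 at the landmark, so each pixel reads as a detection
#' probability.
#'
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param amplitude Scale factor \eqn{\phi} (> 0).
#' @param clamp_to_unit Clamp encoded values into \[0, 1\] (default `TRUE`).
#' @return An object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(sigma = 5 / sqrt(2 * pi), amplitude = 5,
                         clamp_to_unit = TRUE) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be positive")
  structure(list(sigma = sigma, amplitude = amplitude,
                 clamp_to_unit = isTRUE(clamp_to_unit)),
            class = "heatmap_spec")
}

#' Pixel calibration of the scanned cephalograms
#'
#' Captures the acquisition geometry: 0.1 mm per pixel on the original
#' 2400 x 3000 scan, network input resized to 576 x 736. Radial errors are
#' always converted to millimetres by mapping coordinates back to the
#' original frame first (the resize is anisotropic).
#'
#' @param mm_per_pixel_original Millimetres per pixel in the original frame.
#' @param original_size,resized_size `(width, height)` pairs in pixels.
#' @return An object of class `ceph_calibration`.
#' @export
ceph_calibration <- function(mm_per_pixel_original = 0.1,
                             original_size = c(2400, 3000),
                             resized_size = c(576, 736)) {
  stopifnot(mm_per_pixel_original > 0, all(original_size > 0),
            all(resized_size > 0), all(resized_size <= original_size))
  structure(list(mm_per_pixel_original = mm_per_pixel_original,
                 original_size = as.numeric(original_size),
                 resized_size = as.numeric(resized_size)),
            class = "ceph_calibration")
}

#' Encode one landmark as a single-channel heatmap
#'
#' @param point Numeric `(x, y)`, 0-based pixel coordinates (may lie outside
#'   the grid; the Gaussian tail is still rendered).
#' @param width,height Grid size in pixels.
#' @param spec A [heatmap_spec].
#' @return `height` x `width` matrix (row = y, column = x).
#' @export
encode_landmark <- function(point, width, height, spec = heatmap_spec()) {
  if (length(point) != 2L || !all(is.finite(point)))
    stop("point must be two finite coordinates")
  stopifnot(width >= 1, height >= 1)
  xs <- seq_len(width) - 1
  ys <- seq_len(height) - 1
  peak <- spec$amplitude / (spec$sigma * sqrt(2 * pi))
  gx <- exp(-(xs - point[1])^2 / (2 * spec$sigma^2))
  gy <- exp(-(ys - point[2])^2 / (2 * spec$sigma^2))
  h <- peak * outer(gy, gx)
  if (spec$clamp_to_unit) h[h > 1] <- 1
  h
}

#' Encode a landmark set as a 20-channel heatmap stack
#'
#' Channels 1..19 are the landmark Gaussians in canonical order; channel 20
#' is the background complement `max(0, 1 - sum(landmark channels))`, so a
#' per-pixel softmax output can approximate the target.
#'
#' @param landmarks A [landmark_set] bound to the grid frame.
#' @param width,height Grid size; defaults to the landmark frame size.
#' @param spec A [heatmap_spec].
#' @return `height` x `width` x 20 array with values in \[0, 1\].
#' @export
encode_stack <- function(landmarks, width = landmarks$width,
                         height = landmarks$height, spec = heatmap_spec()) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (width != landmarks$width || height != landmarks$height)
    stop("landmark frame does not match the target grid; map_coordinates() first")
  stack <- array(0, dim = c(height, width, 20L))
  for (i in 1:19)
    stack[, , i] <- encode_landmark(landmarks$points[i, ], width, height, spec)
  bg <- 1 - rowSums(stack[, , 1:19, drop = FALSE], dims = 2L)
  bg[bg < 0] <- 0
  stack[, , 20L] <- bg
  stack
}

#' Decode a heatmap stack to landmark coordinates
#'
#' Takes the argmax of each of the 19 landmark channels (the background
#' channel is ignored). Ties are broken in row-major scan order: smallest
#' `y`, then smallest `x`, so a uniform channel decodes to `(0, 0)`.
#'
#' @param stack `height` x `width` x 20 array.
#' @param frame,image_id Frame tag and id for the returned [landmark_set].
#' @return A [landmark_set] with integer pixel coordinates.
#' @export
decode_stack <- function(stack, frame = "phantom", image_id = "decoded") {
  d <- dim(stack)
  if (length(d) != 3L || d[3] != 20L) stop("stack must be H x W x 20")
  h <- d[1]
  pts <- matrix(0, 19, 2)
  for (i in 1:19) {
    ch <- stack[, , i]
    if (all(is.na(ch))) stop(sprintf("channel %d is all-NA; cannot decode", i))
    m <- max(ch, na.rm = TRUE)
    hits <- which(ch == m)             # column-major linear indices
    y <- (hits - 1) %% h
    x <- (hits - 1) %/% h
    o <- order(y, x)[1]                # row-major tie rule
    pts[i, ] <- c(x[o], y[o])
  }
  landmark_set(pts, frame = frame, width = d[2], height = d[1],
               image_id = image_id)
}

#' Persist a heatmap stack as multi-page float TIFF
#'
#' @param stack `H x W x C` array with values in \[0, 1\].
#' @param path Output TIFF file (one page per channel, 32-bit float).
#' @export
write_heatmap_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_tiff
#' @export
read_heatmap_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
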