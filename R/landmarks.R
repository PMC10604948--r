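#' Create a landmark set
#'
#' A `landmark_set` holds the 19 named cephalometric points of one image in a
#' declared coordinate frame. Coordinates are continuous, 0-based, with `x`
#' the column and `y` the row, origin at the top-left of the image.
#'
#' @param points Numeric 19 x 2 matrix (columns `x`, `y`), rows in canonical
#'   order (see [ceph_landmark_names()]); row names, if present, must match.
#' @param frame Frame tag, one of `"original"`, `"resized"`, `"phantom"`.
#' @param width,height Frame dimensions in pixels.
#' @param image_id Identifier of the source image.
#' @param check If `TRUE`, verify that all points lie inside the frame.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame = c("original", "resized", "phantom"),
                         width, height, image_id = "image", check = FALSE) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (nrow(points) != 19L || ncol(points) != 2L)
    stop("landmark_set needs a 19 x 2 coordinate matrix")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  if (!is.null(rownames(points)) &&
      !identical(rownames(points), ceph_landmark_names()))
    stop("landmark rows must follow the canonical order")
  dimnames(points) <- list(ceph_landmark_names(), c("x", "y"))
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0) stop("frame dimensions must be positive")
  if (check &&
      (any(points[, "x"] < 0) || any(points[, "x"] >= width) ||
       any(points[, "y"] < 0) || any(points[, "y"] >= height)))
    stop("landmarks fall outside the declared frame")
  structure(list(image_id = as.character(image_id), frame = frame,
                 width = width, height = height, points = points),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s [%s %g x %g]\n", x$image_id, x$frame,
              x$width, x$height))
  print(round(x$points, 2))
  invisible(x)
}

#' Rescale landmark coordinates to another frame
#'
#' Applies the separable scaling `x' = x * W_to / W_from`,
#' `y' = y * H_to / H_from`. The mapping is invertible up to floating-point
#' rounding, so millimetre errors can always be measured in the original
#' frame regardless of the frame predictions were made in.
#'
#' @param landmarks A [landmark_set].
#' @param width,height Target frame dimensions in pixels.
#' @param frame Frame tag for the result (defaults to the source tag).
#' @return A [landmark_set] in the target frame.
#' @export
map_coordinates <- function(landmarks, width, height,
                            frame = landmarks$frame) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (width <= 0 || height <= 0) stop("target frame must have positive size")
  p <- landmarks$points
  p[, "x"] <- p[, "x"] * width / landmarks$width
  p[, "y"] <- p[, "y"] * height / landmarks$height
  landmark_set(p, frame = frame, width = width, height = height,
               image_id = landmarks$image_id)
}

#' Write landmark sets to CSV
#'
#' One row per landmark with columns
#' `image_id,landmark,x,y,frame_width,frame_height`.
#'
#' @param landmarks A [landmark_set] or a list of them.
#' @param path Output file.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- do.call(rbind, lapply(landmarks, function(l) {
    data.frame(image_id = l$image_id, landmark = rownames(l$points),
               x = l$points[, "x"], y = l$points[, "y"],
               frame_width = l$width, frame_height = l$height,
               row.names = NULL)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark sets from CSV
#'
#' @param path CSV file written by [write_landmarks_csv()] (or any file with
#'   the same columns).
#' @param frame Frame tag to attach to the sets.
#' @return A named list of [landmark_set] objects, one per `image_id`.
#' @export
read_landmarks_csv <- function(path, frame = "phantom") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "landmark", "x", "y", "frame_width", "frame_height")
  if (!all(need %in% names(d))) stop("missing landmark CSV columns")
  out <- lapply(split(d, d$image_id), function(g) {
    g <- g[match(ceph_landmark_names(), g$landmark), ]
    if (anyNA(g$landmark)) stop("landmark CSV is missing canonical names")
    landmark_set(cbind(x = g$x, y = g$y), frame = frame,
                 width = g$frame_width[1], height = g$frame_height[1],
                 image_id = g$image_id[1])
  })
  out[unique(d$image_id)]
}

#' @rdname write_landmarks_csv
#' @export
write_landmarks_json <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  obj <- lapply(landmarks, function(l)
    list(image_id = l$image_id, frame = l$frame, frame_width = l$width,
         frame_height = l$height,
         points = as.data.frame(l$points)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_landmarks_csv
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(obj)), function(i) {
    p <- obj$points[[i]]
    landmark_set(cbind(x = p$x, y = p$y), frame = obj$frame[i],
                 width = obj$frame_width[i], height = obj$frame_height[i],
                 image_id = obj$image_id[i])
  })
  names(out) <- obj$image_id
  out
}
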