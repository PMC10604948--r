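#' Cross-entropy loss between heatmap stacks
#'
#' Elementwise binary cross-entropy averaged over all elements:
#' \deqn{CEL(y, \hat y) = -\frac{1}{N}\sum_i \left[y_i \log \hat y_i +
#'   (1 - y_i)\log(1 - \hat y_i)\right]}
#' with predictions clipped to `[eps, 1 - eps]` before the logs. `N` is the
#' total element count (channels x pixels x batch), so the loss scale does
#' not depend on batch size.
#'
#' @param y Ground-truth stack, values in \[0, 1\].
#' @param y_hat Predicted stack, same shape.
#' @param eps Clip bound for the log arguments.
#' @return Non-negative scalar.
#' @export
cel <- function(y, y_hat, eps = 1e-7) {
  if (!identical(dim(y), dim(y_hat)) && length(y) != length(y_hat))
    stop("shape mismatch between target and prediction")
  .cm_cel(y, y_hat, eps)
}

#' Deep-supervision loss: sum of per-stage cross-entropies
#'
#' @param y Ground-truth stack.
#' @param y_hats List of exactly `n_stages` predicted stacks.
#' @param eps Clip bound passed to [cel()].
#' @param n_stages Expected number of supervised outputs.
#' @return `sum(cel(y, y_hats[[k]]))`, exactly.
#' @export
fcel <- function(y, y_hats, eps = 1e-7, n_stages = length(y_hats)) {
  if (!is.list(y_hats) || length(y_hats) != n_stages)
    stop(sprintf("expected %d stage predictions", n_stages))
  sum(vapply(y_hats, function(p) cel(y, p, eps), 0))
}

#' Training configuration
#'
#' RMSprop with the reduce-on-plateau schedule: the learning rate is
#' multiplied by `plateau_factor` whenever the monitored validation loss
#' has not strictly improved for `plateau_patience` consecutive epochs.
#'
#' @param epochs Training epochs.
#' @param batch_size Samples per gradient step.
#' @param initial_lr Initial learning rate.
#' @param plateau_factor Learning-rate multiplier on plateau (0, 1).
#' @param plateau_patience Epochs without improvement before decay.
#' @param rho RMSprop moving-average coefficient.
#' @param optimizer_eps RMSprop denominator offset.
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 100L, batch_size = 8L, initial_lr = 1e-4,
                          plateau_factor = 0.5, plateau_patience = 25L,
                          rho = 0.9, optimizer_eps = 1e-7, seed = 0L) {
  stopifnot(plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1,
            batch_size >= 1, epochs >= 1, initial_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 rho = rho, optimizer_eps = optimizer_eps,
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Data augmentation specification
#'
#' Per-sample independent draws of rotation (degrees, about the image
#' centre), isotropic zoom, and a multiplicative intensity factor. The
#' geometric transform is applied identically to the image (bilinear
#' interpolation, edge padding) and to the landmark coordinates; heatmap
#' targets are regenerated from the transformed landmarks, never warped.
#'
#' @param rotation_deg `(min, max)` rotation range in degrees.
#' @param zoom `(min, max)` zoom range.
#' @param intensity_scale `(min, max)` multiplicative intensity range
#'   (applied then clipped to \[0, 1\]).
#' @param max_retries Redraws allowed when a transformed landmark leaves
#'   the frame before the sample is skipped.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_deg = c(-10, 10), zoom = c(0.95, 1.05),
                         intensity_scale = c(0.5, 1.5), max_retries = 10L) {
  structure(list(rotation_deg = rotation_deg, zoom = zoom,
                 intensity_scale = intensity_scale,
                 max_retries = as.integer(max_retries)),
            class = "augment_spec")
}

# Bilinear sampling of `img` at (continuous, 0-based) coordinates, with
# edge padding.
bilinear_sample <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  (1 - fy) * ((1 - fx) * idx(y0, x0) + fx * idx(y0, x1)) +
    fy * ((1 - fx) * idx(y1, x0) + fx * idx(y1, x1))
}

apply_affine <- function(img, rot_deg, zoom) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- rot_deg * pi / 180
  # inverse map: out(x') = in(R(-th)/zoom (x' - c) + c)
  co <- cos(th) / zoom; si <- sin(th) / zoom
  gx <- rep(0:(w - 1), each = h) - cx
  gy <- rep(0:(h - 1), times = w) - cy
  xs <- co * gx + si * gy + cx
  ys <- -si * gx + co * gy + cy
  matrix(bilinear_sample(img, xs, ys), h, w)
}

transform_points <- function(points, rot_deg, zoom, w, h) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- rot_deg * pi / 180
  x <- points[, 1] - cx; y <- points[, 2] - cy
  cbind(x = zoom * (cos(th) * x - sin(th) * y) + cx,
        y = zoom * (sin(th) * x + cos(th) * y) + cy)
}

#' Augment an image / landmark pair
#'
#' @param image `H x W` matrix with values in \[0, 1\].
#' @param landmarks A [landmark_set] bound to the image frame.
#' @param spec An [augment_spec()].
#' @return List `(image, landmarks, draw)`, or `NULL` if every redraw left
#'   a landmark outside the frame (the caller should skip the sample).
#' @export
augment <- function(image, landmarks, spec = augment_spec()) {
  h <- nrow(image); w <- ncol(image)
  for (try in seq_len(spec$max_retries + 1L)) {
    rot <- runif(1, spec$rotation_deg[1], spec$rotation_deg[2])
    zm <- runif(1, spec$zoom[1], spec$zoom[2])
    its <- runif(1, spec$intensity_scale[1], spec$intensity_scale[2])
    pts <- transform_points(landmarks$points, rot, zm, w, h)
    if (all(pts[, 1] >= 0 & pts[, 1] < w & pts[, 2] >= 0 & pts[, 2] < h)) {
      img <- apply_affine(image, rot, zm) * its
      img[img > 1] <- 1; img[img < 0] <- 0
      lm <- landmark_set(pts, frame = landmarks$frame, width = w, height = h,
                         image_id = landmarks$image_id)
      return(list(image = img, landmarks = lm,
                  draw = c(rotation = rot, zoom = zm, intensity = its)))
    }
  }
  NULL
}

# Reduce-on-plateau bookkeeping for one epoch: strict improvement resets
# the counter; `plateau_patience` consecutive non-improvements multiply the
# learning rate by `plateau_factor` (no floor).
plateau_step <- function(val_loss, best_val, since_improve, lr, control) {
  if (val_loss < best_val)
    return(list(improved = TRUE, since_improve = 0L, lr = lr))
  since_improve <- since_improve + 1L
  if (since_improve >= control$plateau_patience) {
    lr <- lr * control$plateau_factor
    since_improve <- 0L
  }
  list(improved = FALSE, since_improve = since_improve, lr = lr)
}

rmsprop_step <- function(params, grads, cache, lr, rho, eps) {
  for (nmp in names(grads)) {
    for (f in names(grads[[nmp]])) {
      g <- grads[[nmp]][[f]]
      c0 <- cache[[nmp]][[f]]
      if (is.null(c0)) c0 <- 0
      c1 <- rho * c0 + (1 - rho) * g * g
      cache[[nmp]][[f]] <- c1
      params[[nmp]][[f]] <- params[[nmp]][[f]] - lr * g / (sqrt(c1) + eps)
    }
  }
  list(params = params, cache = cache)
}

batch_targets <- function(landmarks, width, height, spec) {
  B <- length(landmarks)
  y <- array(0, dim = c(height, width, 20L, B))
  for (j in seq_len(B))
    y[, , , j] <- encode_stack(landmarks[[j]], width, height, spec)
  y
}

#' Fit the stacked FCN by heatmap regression
#'
#' Minimises the deep-supervision cross-entropy ([fcel()]) with RMSprop.
#' The learning rate follows the reduce-on-plateau schedule of
#' [train_control()]; the returned object keeps the parameters of the
#' epoch with the lowest validation loss.
#'
#' @param object A `ceph_fcn` built by [build_network()].
#' @param train_set,val_set Lists with elements `images` (H x W x 1 x n
#'   array or list of matrices) and `landmarks` (list of [landmark_set]).
#' @param control A [train_control()].
#' @param augmentation An [augment_spec()], or `NULL` to train on the raw
#'   samples.
#' @param heatmap A [heatmap_spec()] used to encode targets.
#' @param early_stop Optional `function(network, epoch, history)`; training
#'   stops after any epoch for which it returns `TRUE` (e.g. a validation
#'   detection-rate probe).
#' @param verbose Print one line per epoch.
#' @param ... Unused.
#' @return An object of class `ceph_fit`: the trained network plus a
#'   per-epoch history (`train_loss`, `val_loss`, `lr`), the best epoch,
#'   and a count of augmentation skips.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
fit.ceph_fcn <- function(object, train_set, val_set,
                         control = train_control(),
                         augmentation = NULL,
                         heatmap = heatmap_spec(), early_stop = NULL,
                         verbose = FALSE, ...) {
  net <- object
  xtr <- images_to_batch(train_set$images)
  xva <- images_to_batch(val_set$images)
  h <- dim(xtr)[1]; w <- dim(xtr)[2]
  ntr <- dim(xtr)[4]
  set.seed(control$seed)
  opt_cache <- list()
  lr <- control$initial_lr
  best_val <- Inf; best_params <- net$params; best_state <- net$state
  best_epoch <- 0L
  since_improve <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  n_skipped <- 0L
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, ntr, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1, ntr)]
      imgs <- lapply(idx, function(i) xtr[, , 1, i])
      lms <- train_set$landmarks[idx]
      if (!is.null(augmentation)) {
        keep <- logical(length(idx))
        for (j in seq_along(idx)) {
          a <- augment(imgs[[j]], lms[[j]], augmentation)
          if (is.null(a)) {
            n_skipped <- n_skipped + 1L
            message(sprintf("augmentation skipped sample %s (epoch %d)",
                            lms[[j]]$image_id, ep))
          } else {
            imgs[[j]] <- a$image; lms[[j]] <- a$landmarks; keep[j] <- TRUE
          }
        }
        imgs <- imgs[keep]; lms <- lms[keep]
        if (!length(imgs)) next
      }
      xb <- images_to_batch(imgs)
      yb <- batch_targets(lms, w, h, heatmap)
      fwd <- net_forward(net, xb, train = TRUE)
      net$state <- fwd$state
      loss <- fcel(yb, fwd$outputs)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d (lr %g)",
                     ep, nb + 1L, lr))
      grads <- net_backward(net, fwd, yb)
      st <- rmsprop_step(net$params, grads, opt_cache, lr, control$rho,
                         control$optimizer_eps)
      net$params <- st$params; opt_cache <- st$cache
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    val_loss <- evaluate_loss(net, xva, val_set$landmarks, heatmap,
                              control$batch_size)
    ps <- plateau_step(val_loss, best_val, since_improve, lr, control)
    lr <- ps$lr; since_improve <- ps$since_improve
    if (ps$improved) {
      best_val <- val_loss; best_params <- net$params
      best_state <- net$state; best_epoch <- ep
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %g",
                      ep, ep_loss / nb, val_loss, lr))
    if (!is.null(early_stop) && isTRUE(early_stop(net, ep, hist))) break
  }
  last <- net
  net$params <- best_params
  net$state <- best_state
  structure(list(network = net, last_network = last, history = hist,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 control = control, heatmap = heatmap,
                 n_augment_skipped = n_skipped),
            class = "ceph_fit")
}

evaluate_loss <- function(net, x, landmarks, heatmap, batch_size) {
  n <- dim(x)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  tot <- 0; nb <- 0L
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    yb <- batch_targets(landmarks[idx], w, h, heatmap)
    fwd <- net_forward(net, x[, , , idx, drop = FALSE], train = FALSE)
    tot <- tot + fcel(yb, fwd$outputs) * length(idx)
    nb <- nb + length(idx)
  }
  tot / nb
}

#' @export
print.ceph_fit <- function(x, ...) {
  cat(sprintf(paste0("<ceph_fit> %d epochs, best validation loss %.5f ",
                     "(epoch %d)\n"),
              nrow(x$history), x$best_val_loss, x$best_epoch))
  print(x$network)
  invisible(x)
}

#' @export
summary.ceph_fit <- function(object, ...) {
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5))
  cat(sprintf("best epoch %d, validation loss %.5f; %d samples skipped by augmentation\n",
              object$best_epoch, object$best_val_loss,
              object$n_augment_skipped))
  invisible(object$history)
}

#' @export
coef.ceph_fit <- function(object, ...) object$network$params

#' @export
plot.ceph_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss (FCEL)", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @rdname predict.ceph_fcn
#' @export
predict.ceph_fit <- function(object, images, ...) {
  predict(object$network, images, ...)
}

#' Save / load a trained network
#'
#' Writes the parameters as an RDS checkpoint next to a JSON manifest
#' recording the configuration and parameter count.
#'
#' @param network A `ceph_fcn` or `ceph_fit`.
#' @param path Checkpoint path (`.rds`); the manifest gets `.json`.
#' @export
save_checkpoint <- function(network, path) {
  if (inherits(network, "ceph_fit")) network <- network$network
  saveRDS(network, path)
  manifest <- list(config = unclass(network$config),
                   parameter_count = count_parameters(network))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  readRDS(path)
}
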