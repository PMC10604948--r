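#' Architecture configuration for the stacked FCN
#'
#' Describes the attention-based stacked regression network: a chain of
#' `stage_count` tied encoder-decoder FCNs. Stage 1 fuses average-pooled
#' copies of the input at each encoder level (multi-scale inputs, MSI) and
#' applies dual attention (spatial + channel, DSAM) at its bridge; later
#' stages receive the previous stage's final decoder features concatenated
#' with the raw image, concatenate the attention branch outputs at their
#' bridges, and pass the combined features through a multi-path convolution
#' module (MCM) with a plain and a dilated 3x3 path. Every stage ends in a
#' 3x3 convolution and a per-pixel softmax over `num_landmark_channels`
#' channels (deep supervision).
#'
#' @param input_size `(width, height)` of the network input in pixels; both
#'   must be divisible by `2^(length(encoder_widths) - 1)`.
#' @param encoder_widths Channel counts per encoder level, strictly
#'   increasing; the last entry is the bridge width.
#' @param stage_count Number of stacked FCNs.
#' @param use_msi,use_sam,use_cam Module toggles (ablation wiring).
#' @param mcm_dilations Dilation rate of the second MCM path for stages
#'   `2..stage_count`; defaults to `2, 3, ...`.
#' @param num_landmark_channels Output channels (19 landmarks + background).
#' @param input_channels Image channels (grayscale: 1).
#' @param sam_reduction Channel reduction of the two spatial-attention score
#'   projections (`C / sam_reduction`, at least 1).
#' @param attention_max_n Largest pixel count `N = H * W` for which the
#'   `N x N` spatial attention map may be materialised.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_size = c(576, 736),
                        encoder_widths = c(16, 32, 64, 128),
                        stage_count = 3L, use_msi = TRUE, use_sam = TRUE,
                        use_cam = TRUE, mcm_dilations = NULL,
                        num_landmark_channels = 20L, input_channels = 1L,
                        sam_reduction = 8L, attention_max_n = 8192L) {
  nl <- length(encoder_widths)
  if (nl < 2L) stop("need at least two encoder widths")
  if (any(diff(encoder_widths) <= 0))
    stop("encoder widths must be strictly increasing")
  if (stage_count < 1L) stop("stage_count must be >= 1")
  div <- 2^(nl - 1)
  if (any(input_size %% div != 0))
    stop(sprintf("input dimensions must be divisible by %d", div))
  if (is.null(mcm_dilations)) {
    mcm_dilations <- if (stage_count >= 2) seq(2L, length.out = stage_count - 1L)
                     else integer()
  }
  if (stage_count >= 2 && length(mcm_dilations) != stage_count - 1L)
    stop("one MCM dilation rate per stage after the first")
  if (any(mcm_dilations < 1)) stop("dilation rates must be positive")
  structure(list(input_size = as.integer(input_size),
                 encoder_widths = as.integer(encoder_widths),
                 stage_count = as.integer(stage_count),
                 use_msi = isTRUE(use_msi), use_sam = isTRUE(use_sam),
                 use_cam = isTRUE(use_cam),
                 mcm_dilations = as.integer(mcm_dilations),
                 num_landmark_channels = as.integer(num_landmark_channels),
                 input_channels = as.integer(input_channels),
                 sam_reduction = as.integer(sam_reduction),
                 attention_max_n = as.integer(attention_max_n)),
            class = "arch_config")
}

nm_s <- function(s, part) sprintf("s%d.%s", s, part)

#' Build the stacked attention FCN
#'
#' Allocates and initialises all trainable parameters (He-uniform
#' convolution weights, batch-norm scale 1 / shift 0, attention gains
#' exactly 0) according to an [arch_config()].
#'
#' @param config An [arch_config()].
#' @param seed Optional integer seed for the weight initialisation.
#' @return An object of class `ceph_fcn`.
#' @export
build_network <- function(config = arch_config(), seed = NULL) {
  stopifnot(inherits(config, "arch_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$encoder_widths; nl <- length(w); S <- config$stage_count
  ic <- config$input_channels; nc <- config$num_landmark_channels
  params <- list(); state <- list()
  add_bn <- function(name, cout) state[[name]] <<- list(mean = numeric(cout),
                                                        var = rep(1, cout))
  for (s in seq_len(S)) {
    in1 <- if (s == 1) ic else w[1] + ic
    params[[nm_s(s, "e1")]] <- conv_params(3, in1, w[1]); add_bn(nm_s(s, "e1"), w[1])
    for (l in 2:(nl - 1)) {
      cin <- w[l - 1] + if (s == 1 && config$use_msi) w[l] else 0
      params[[nm_s(s, paste0("e", l))]] <- conv_params(3, cin, w[l])
      add_bn(nm_s(s, paste0("e", l)), w[l])
    }
    cinb <- w[nl - 1] + if (s == 1 && config$use_msi) w[nl] else 0
    params[[nm_s(s, "b")]] <- conv_params(3, cinb, w[nl]); add_bn(nm_s(s, "b"), w[nl])
    if (s == 1 && config$use_msi) {
      for (l in 2:nl) {
        params[[paste0("s1.m", l)]] <- conv_params(3, ic, w[l])
        add_bn(paste0("s1.m", l), w[l])
      }
    }
    if (s == 1) {
      C <- w[nl]
      if (config$use_sam) {
        cp <- max(1L, C %/% config$sam_reduction)
        lim <- sqrt(6 / C)
        params$sam <- list(w0 = matrix(runif(C * cp, -lim, lim), C, cp),
                           b0 = numeric(cp),
                           w1 = matrix(runif(C * cp, -lim, lim), C, cp),
                           b1 = numeric(cp),
                           w2 = matrix(runif(C * C, -lim, lim), C, C),
                           b2 = numeric(C), gamma = 0)
      }
      if (config$use_cam) params$cam <- list(gamma = 0)
    } else {
      ccat <- w[nl] * (1L + config$use_sam + config$use_cam)
      dil <- config$mcm_dilations[s - 1]
      params[[nm_s(s, "mcm1")]] <- conv_params(3, ccat, w[nl])
      add_bn(nm_s(s, "mcm1"), w[nl])
      params[[nm_s(s, "mcm2")]] <- conv_params(3, ccat, w[nl])
      add_bn(nm_s(s, "mcm2"), w[nl])
      params[[nm_s(s, "mcmr")]] <- conv_params(3, 2 * w[nl], w[nl])
      add_bn(nm_s(s, "mcmr"), w[nl])
    }
    for (l in (nl - 1):1) {
      cin_up <- if (l == nl - 1) w[nl] else w[l + 1]
      params[[nm_s(s, paste0("u", l))]] <- convt_params(cin_up, w[l])
      params[[nm_s(s, paste0("d", l))]] <- conv_params(3, 2 * w[l], w[l])
      add_bn(nm_s(s, paste0("d", l)), w[l])
    }
    # output layer: background-channel bias starts at the log-prior of the
    # (overwhelmingly background) targets so the softmax begins near the
    # marginal distribution and training spends its steps on localisation
    params[[nm_s(s, "out")]] <- conv_params(3, w[1], nc, bn = FALSE)
    params[[nm_s(s, "out")]]$b[nc] <- 6
  }
  structure(list(config = config, params = params, state = state),
            class = "ceph_fcn")
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar (convolution weights and biases,
#' batch-norm scale/shift, attention projections and gains); batch-norm
#' running statistics are excluded.
#'
#' @param network A `ceph_fcn`.
#' @return Integer count.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "ceph_fcn"))
  sum(vapply(network$params,
             function(p) sum(vapply(p, length, 0L)), 0L))
}

#' @export
print.ceph_fcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<ceph_fcn> %d-stage stacked FCN, widths [%s], ",
                     "input %d x %d\n"),
              cfg$stage_count, paste(cfg$encoder_widths, collapse = ", "),
              cfg$input_size[1], cfg$input_size[2]))
  cat(sprintf("  modules: MSI=%s SAM=%s CAM=%s; %s trainable parameters\n",
              cfg$use_msi, cfg$use_sam, cfg$use_cam,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.ceph_fcn <- function(object, ...) {
  counts <- vapply(object$params,
                   function(p) sum(vapply(p, length, 0L)), 0L)
  out <- data.frame(block = names(counts), parameters = as.integer(counts),
                    row.names = NULL)
  print(out)
  cat(sprintf("total: %d\n", sum(counts)))
  invisible(out)
}

#' @export
coef.ceph_fcn <- function(object, ...) object$params

# ---------------------------------------------------------------------------
# Forward pass. Returns per-stage softmax heatmap stacks; with train = TRUE
# also the full activation cache needed by net_backward and updated BN
# running statistics.
net_forward <- function(net, x, train = FALSE) {
  cfg <- net$config; w <- cfg$encoder_widths; nl <- length(w)
  S <- cfg$stage_count; params <- net$params; state <- net$state
  x <- as_batch(x)
  d <- dim(x)
  if (any(d[1:2] %% 2^(nl - 1) != 0))
    stop(sprintf("input dims must be divisible by %d", 2^(nl - 1)))
  outputs <- vector("list", S)
  caches <- if (train) vector("list", S)
  prev_d1 <- NULL
  sam_out <- cam_out <- NULL
  attn_cache <- list()
  for (s in seq_len(S)) {
    cs <- list()
    Xs <- if (s == 1) x else concat_channels(prev_d1, x)
    if (train) cs$Xs <- Xs
    run <- function(name, xin, dil = 1L) {
      r <- conv_block_fwd(params[[name]], state[[name]], xin, dil, train)
      if (train) { state[[name]] <<- r$rs; cs[[name]] <<- r$cache }
      r$y
    }
    e <- vector("list", nl - 1)
    e[[1]] <- run(nm_s(s, "e1"), Xs)
    for (l in 2:(nl - 1)) {
      mp <- .cm_maxpool2_fwd(e[[l - 1]])
      if (train) cs[[paste0("mpidx", l)]] <- mp$idx
      din <- mp$y
      if (s == 1 && cfg$use_msi) {
        m <- run(paste0("s1.m", l), .cm_avgpool_fwd(x, as.integer(2^(l - 1))))
        din <- concat_channels(din, m)
      }
      e[[l]] <- run(nm_s(s, paste0("e", l)), din)
    }
    mp <- .cm_maxpool2_fwd(e[[nl - 1]])
    if (train) cs$mpidx_b <- mp$idx
    bp <- mp$y
    if (s == 1 && cfg$use_msi) {
      m <- run(paste0("s1.m", nl), .cm_avgpool_fwd(x, as.integer(2^(nl - 1))))
      bp <- concat_channels(bp, m)
    }
    b <- run(nm_s(s, "b"), bp)
    if (s == 1) {
      if (cfg$use_sam) {
        rs <- sam_fwd(b, params$sam, cfg$attention_max_n)
        sam_out <- rs$y
        if (train) attn_cache$sam <- rs$caches
      }
      if (cfg$use_cam) {
        rc <- cam_fwd(b, params$cam$gamma)
        cam_out <- rc$y
        if (train) attn_cache$cam <- rc$caches
      }
      f <- if (cfg$use_sam && cfg$use_cam) sam_out + cam_out
           else if (cfg$use_sam) sam_out
           else if (cfg$use_cam) cam_out
           else b
    } else {
      cc <- b
      if (cfg$use_sam) cc <- concat_channels(cc, sam_out)
      if (cfg$use_cam) cc <- concat_channels(cc, cam_out)
      y1 <- run(nm_s(s, "mcm1"), cc, 1L)
      y2 <- run(nm_s(s, "mcm2"), cc, cfg$mcm_dilations[s - 1])
      f <- run(nm_s(s, "mcmr"), concat_channels(y1, y2))
    }
    cur <- f
    for (l in (nl - 1):1) {
      pu <- params[[nm_s(s, paste0("u", l))]]
      up <- .cm_convt2_fwd(cur, pu$w, pu$b)
      if (train) cs[[paste0("upin", l)]] <- cur
      cur <- run(nm_s(s, paste0("d", l)), concat_channels(up, e[[l]]))
    }
    po <- params[[nm_s(s, "out")]]
    z <- .cm_conv2d_fwd(cur, po$w, po$b, 1L, conv_double())
    p <- softmax_channels(z)
    outputs[[s]] <- p
    if (train) {
      cs$d1 <- cur
      cs$e_dims <- lapply(e, dim)
      caches[[s]] <- cs
    }
    prev_d1 <- cur
  }
  list(outputs = outputs, caches = caches, attn_cache = attn_cache,
       state = state, x = if (train) x)
}

add_grad <- function(grads, name, g) {
  if (is.null(grads[[name]])) grads[[name]] <- g
  else grads[[name]] <- mapply(`+`, grads[[name]], g, SIMPLIFY = FALSE)
  grads
}

# Backward pass for FCEL deep supervision: `targets` is the (H, W, 20, B)
# ground-truth stack shared by all three stage outputs. Returns parameter
# gradients keyed like net$params.
net_backward <- function(net, fwd, targets) {
  cfg <- net$config; w <- cfg$encoder_widths; nl <- length(w)
  S <- cfg$stage_count; params <- net$params
  grads <- list()
  g_sam <- g_cam <- NULL
  g_next <- NULL  # gradient into stage s's final decoder feature from s+1
  for (s in S:1) {
    cs <- fwd$caches[[s]]
    gz <- softmax_cel_grad(targets, fwd$outputs[[s]])
    po <- params[[nm_s(s, "out")]]
    co <- .cm_conv2d_bwd(cs$d1, po$w, gz, 1L, conv_double())
    grads <- add_grad(grads, nm_s(s, "out"), list(w = co$gw, b = co$gb))
    g_cur <- co$gx
    if (!is.null(g_next)) g_cur <- g_cur + g_next
    g_e <- vector("list", nl - 1)
    for (l in 1:(nl - 1)) {
      bname <- nm_s(s, paste0("d", l))
      r <- conv_block_bwd(params[[bname]], cs[[bname]], g_cur)
      grads <- add_grad(grads, bname, r$grads)
      sp <- split_channels(r$gx, c(w[l], w[l]))
      g_e[[l]] <- sp[[2]]
      pu <- params[[nm_s(s, paste0("u", l))]]
      ct <- .cm_convt2_bwd(cs[[paste0("upin", l)]], pu$w, sp[[1]])
      grads <- add_grad(grads, nm_s(s, paste0("u", l)),
                        list(w = ct$gw, b = ct$gb))
      g_cur <- ct$gx
    }
    g_f <- g_cur
    if (s > 1) {
      r <- conv_block_bwd(params[[nm_s(s, "mcmr")]], cs[[nm_s(s, "mcmr")]], g_f)
      grads <- add_grad(grads, nm_s(s, "mcmr"), r$grads)
      sp <- split_channels(r$gx, c(w[nl], w[nl]))
      r1 <- conv_block_bwd(params[[nm_s(s, "mcm1")]], cs[[nm_s(s, "mcm1")]],
                           sp[[1]])
      grads <- add_grad(grads, nm_s(s, "mcm1"), r1$grads)
      r2 <- conv_block_bwd(params[[nm_s(s, "mcm2")]], cs[[nm_s(s, "mcm2")]],
                           sp[[2]])
      grads <- add_grad(grads, nm_s(s, "mcm2"), r2$grads)
      g_cc <- r1$gx + r2$gx
      sizes <- c(w[nl], if (cfg$use_sam) w[nl], if (cfg$use_cam) w[nl])
      sp <- split_channels(g_cc, sizes)
      g_b <- sp[[1]]
      k <- 2L
      if (cfg$use_sam) {
        g_sam <- if (is.null(g_sam)) sp[[k]] else g_sam + sp[[k]]; k <- k + 1L
      }
      if (cfg$use_cam)
        g_cam <- if (is.null(g_cam)) sp[[k]] else g_cam + sp[[k]]
    } else {
      # stage-1 bridge fusion and the attention branches themselves
      if (cfg$use_sam) g_sam <- if (is.null(g_sam)) g_f else g_sam + g_f
      if (cfg$use_cam) g_cam <- if (is.null(g_cam)) g_f else g_cam + g_f
      g_b <- NULL
      if (cfg$use_sam) {
        rs <- sam_bwd(g_sam, fwd$attn_cache$sam, params$sam)
        grads <- add_grad(grads, "sam", rs$grads)
        g_b <- rs$gx
      }
      if (cfg$use_cam) {
        rc <- cam_bwd(g_cam, fwd$attn_cache$cam, params$cam$gamma)
        grads <- add_grad(grads, "cam", rc$grads)
        g_b <- if (is.null(g_b)) rc$gx else g_b + rc$gx
      }
      if (is.null(g_b)) g_b <- g_f
    }
    r <- conv_block_bwd(params[[nm_s(s, "b")]], cs[[nm_s(s, "b")]], g_b)
    grads <- add_grad(grads, nm_s(s, "b"), r$grads)
    g_bp <- r$gx
    if (s == 1 && cfg$use_msi) {
      sp <- split_channels(g_bp, c(w[nl - 1], w[nl]))
      g_bp <- sp[[1]]
      mr <- conv_block_bwd(params[[paste0("s1.m", nl)]],
                           cs[[paste0("s1.m", nl)]], sp[[2]])
      grads <- add_grad(grads, paste0("s1.m", nl), mr$grads)
    }
    ed <- cs$e_dims[[nl - 1]]
    g_e[[nl - 1]] <- g_e[[nl - 1]] +
      .cm_maxpool2_bwd(g_bp, cs$mpidx_b, ed[1], ed[2])
    for (l in (nl - 1):2) {
      bname <- nm_s(s, paste0("e", l))
      r <- conv_block_bwd(params[[bname]], cs[[bname]], g_e[[l]])
      grads <- add_grad(grads, bname, r$grads)
      g_din <- r$gx
      if (s == 1 && cfg$use_msi) {
        sp <- split_channels(g_din, c(w[l - 1], w[l]))
        g_din <- sp[[1]]
        mr <- conv_block_bwd(params[[paste0("s1.m", l)]],
                             cs[[paste0("s1.m", l)]], sp[[2]])
        grads <- add_grad(grads, paste0("s1.m", l), mr$grads)
      }
      ed <- cs$e_dims[[l - 1]]
      g_e[[l - 1]] <- g_e[[l - 1]] +
        .cm_maxpool2_bwd(g_din, cs[[paste0("mpidx", l)]], ed[1], ed[2])
    }
    r <- conv_block_bwd(params[[nm_s(s, "e1")]], cs[[nm_s(s, "e1")]],
                        g_e[[1]])
    grads <- add_grad(grads, nm_s(s, "e1"), r$grads)
    g_next <- if (s > 1)
      split_channels(r$gx, c(w[1], cfg$input_channels))[[1]]
  }
  grads
}

#' Forward pass of the network
#'
#' Runs the stacked FCN on a batch of images and returns the per-stage
#' 20-channel softmax heatmap stacks (deep supervision outputs in stage
#' order).
#'
#' @param network A `ceph_fcn`.
#' @param images `H x W` matrix, `H x W x 1 x B` array, or list of matrices.
#' @return List of `H x W x 20 x B` probability arrays, one per stage.
#' @export
forward_heatmaps <- function(network, images) {
  x <- images_to_batch(images)
  net_forward(network, x, train = FALSE)$outputs
}

images_to_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, dim = c(d[1], d[2], 1L, length(images)))
    for (i in seq_along(images)) x[, , 1, i] <- images[[i]]
    x
  } else as_batch(images)
}

#' Predict landmarks from images
#'
#' Runs the network and decodes the final stage's heatmap stack (argmax per
#' landmark channel); earlier deep-supervision outputs are training-only.
#'
#' @param object A `ceph_fcn`.
#' @param images Matrix, array, or list of matrices (values in \[0, 1\]).
#' @param frame Frame tag for the returned landmark sets.
#' @param image_ids Ids for the returned sets.
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return List of [landmark_set] objects.
#' @export
predict.ceph_fcn <- function(object, images, frame = "phantom",
                             image_ids = NULL, batch_size = 4L, ...) {
  x <- images_to_batch(images)
  n <- dim(x)[4]
  if (is.null(image_ids)) image_ids <- sprintf("image_%04d", seq_len(n))
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    p <- net_forward(object, x[, , , idx, drop = FALSE],
                     train = FALSE)$outputs
    last <- p[[length(p)]]
    for (j in seq_along(idx))
      out[[idx[j]]] <- decode_stack(last[, , , j], frame = frame,
                                    image_id = image_ids[idx[j]])
  }
  names(out) <- image_ids
  out
}
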