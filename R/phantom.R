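# Seed-deterministic synthetic cephalogram phantoms.
#
# A phantom is a low-contrast grayscale rendering of a lateral-skull-like
# scene: cranial vault and base, orbit, sella ring, mandible, palatal line,
# incisors, and a fainter soft-tissue profile, all drawn through 19
# analytically placed landmark points. Landmarks are exact functions of the
# drawn shape parameters, so detector error on phantoms is attributable
# entirely to the model.

# Template landmark positions as fractions of (width, height); profile
# faces right. Curves are drawn through these points, so with zero noise
# the landmarks lie exactly on their defining strokes.
phantom_template <- function() {
  rbind(sella = c(0.38, 0.32), nasion = c(0.62, 0.30),
        orbitale = c(0.60, 0.40), porion = c(0.32, 0.41),
        subspinale = c(0.63, 0.55), supramentale = c(0.62, 0.66),
        pogonion = c(0.62, 0.74), menton = c(0.58, 0.78),
        gnathion = c(0.60, 0.77), gonion = c(0.38, 0.66),
        incision_inferius = c(0.63, 0.62), incision_superius = c(0.64, 0.59),
        upper_lip = c(0.70, 0.58), lower_lip = c(0.70, 0.64),
        subnasale = c(0.68, 0.52), soft_tissue_pogonion = c(0.68, 0.75),
        posterior_nasal_spine = c(0.50, 0.52),
        anterior_nasal_spine = c(0.64, 0.52), articulare = c(0.36, 0.45))
}

#' Phantom generation specification
#'
#' Controls canvas size, shape-parameter ranges, contrast, and degradation
#' of the synthetic cephalograms. The `easy` preset renders bright,
#' high-gradient landmark markers with little noise (visually unambiguous
#' points, suitable for desk-scale learning experiments); `realistic`
#' lowers contrast (soft tissue well below bone), widens the shape ranges,
#' and adds more blur and noise, emulating scanned-film radiographs.
#'
#' @param image_size `(width, height)` in pixels (both >= 64 and divisible
#'   by 8 if fed to the network).
#' @param preset `"easy"` or `"realistic"`.
#' @param scale_range,rotation_range,shift_range,jitter_frac Shape
#'   variability: global scale, rotation (degrees), centre shift and
#'   per-landmark jitter (fractions of the canvas).
#' @param bone_intensity,soft_intensity,marker_intensity,background
#'   Rendering intensities in \[0, 1\]; soft tissue must stay below bone.
#' @param blur_sd,noise_sd Gaussian blur and additive noise (pixels /
#'   intensity units).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(576, 736),
                         preset = c("easy", "realistic"),
                         scale_range = NULL, rotation_range = NULL,
                         shift_range = NULL, jitter_frac = NULL,
                         bone_intensity = NULL, soft_intensity = NULL,
                         marker_intensity = NULL, background = NULL,
                         blur_sd = NULL, noise_sd = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "easy") {
    list(scale_range = c(0.90, 1.06), rotation_range = c(-3, 3),
         shift_range = c(-0.015, 0.015), jitter_frac = c(-0.010, 0.010),
         bone_intensity = 0.35, soft_intensity = 0.20,
         marker_intensity = 1.0, background = 0.10,
         blur_sd = 0.4, noise_sd = 0.01)
  } else {
    list(scale_range = c(0.86, 1.08), rotation_range = c(-5, 5),
         shift_range = c(-0.025, 0.025), jitter_frac = c(-0.016, 0.016),
         bone_intensity = 0.45, soft_intensity = 0.16,
         marker_intensity = 0.30, background = 0.15,
         blur_sd = 1.1, noise_sd = 0.04)
  }
  user <- list(scale_range = scale_range, rotation_range = rotation_range,
               shift_range = shift_range, jitter_frac = jitter_frac,
               bone_intensity = bone_intensity,
               soft_intensity = soft_intensity,
               marker_intensity = marker_intensity, background = background,
               blur_sd = blur_sd, noise_sd = noise_sd)
  for (nmu in names(user)) if (!is.null(user[[nmu]])) def[[nmu]] <- user[[nmu]]
  spec <- c(list(image_size = as.integer(image_size), preset = preset), def)
  if (any(image_size < 64)) stop("phantom canvas must be at least 64 x 64")
  if (spec$soft_intensity >= spec$bone_intensity)
    stop("soft-tissue contrast must stay below bone contrast")
  structure(spec, class = "phantom_spec")
}

# distance-field stroke of one polyline, composited by per-pixel max
stroke_polyline <- function(img, pts, intensity, width = 0.8) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    margin <- 3
    x0 <- max(0, floor(min(p[1], q[1]) - margin))
    x1 <- min(w - 1, ceiling(max(p[1], q[1]) + margin))
    y0 <- max(0, floor(min(p[2], q[2]) - margin))
    y1 <- min(h - 1, ceiling(max(p[2], q[2]) + margin))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    v <- q - p; vv <- sum(v^2)
    t <- if (vv == 0) 0 else
      pmin(pmax(((px - p[1]) * v[1] + (py - p[2]) * v[2]) / vv, 0), 1)
    d2 <- (px - (p[1] + t * v[1]))^2 + (py - (p[2] + t * v[2]))^2
    val <- intensity * exp(-d2 / (2 * width^2))
    sub <- img[ys + 1, xs + 1]
    img[ys + 1, xs + 1] <- pmax(sub, matrix(val, length(ys), length(xs)))
  }
  img
}

circle_points <- function(center, r, n = 48) {
  a <- seq(0, 2 * pi, length.out = n)
  cbind(center[1] + r * sin(a), center[2] - r * cos(a))
}

gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sd))
  k1 <- exp(-((-r):r)^2 / (2 * sd^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  x <- img; dim(x) <- c(dim(img), 1L, 1L)
  kw <- array(k2, dim = c(2 * r + 1, 2 * r + 1, 1, 1))
  y <- .cm_conv2d_fwd(x, kw, 0, 1L)
  matrix(y, nrow(img), ncol(img))
}

#' Generate one synthetic cephalogram phantom
#'
#' Fully determined by `(spec, index, seed)`: shape parameters are drawn
#' from a counter-based substream, the 19 landmarks are placed as analytic
#' functions of those parameters, the scene is rendered with anti-aliased
#' strokes, then blurred and corrupted by noise.
#'
#' @param spec A [phantom_spec()].
#' @param index Sample index (>= 1); part of the random substream.
#' @param seed Integer master seed.
#' @return An object of class `phantom_sample`: list with `image`
#'   (`H x W` matrix in \[0, 1\]), `landmarks` (a [landmark_set], frame
#'   `"phantom"`), `params`, and `stratum` (age-like covariate derived from
#'   the global size parameter).
#' @export
sample_phantom <- function(spec = phantom_spec(), index = 1L, seed = 0L) {
  set.seed(substream_seed(seed, index))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  g <- runif(1, spec$scale_range[1], spec$scale_range[2])
  rot <- runif(1, spec$rotation_range[1], spec$rotation_range[2]) * pi / 180
  shift <- runif(2, spec$shift_range[1], spec$shift_range[2]) * c(w, h)
  jit <- matrix(runif(38, spec$jitter_frac[1], spec$jitter_frac[2]),
                19, 2) * min(w, h)
  tp <- phantom_template()
  base <- cbind(tp[, 1] * w, tp[, 2] * h)
  cx <- w / 2; cy <- h / 2
  xr <- base[, 1] - cx; yr <- base[, 2] - cy
  pts <- cbind(cx + g * (cos(rot) * xr - sin(rot) * yr) + shift[1],
               cy + g * (sin(rot) * xr + cos(rot) * yr) + shift[2]) + jit
  rownames(pts) <- rownames(tp)
  lm <- landmark_set(pts, frame = "phantom", width = w, height = h,
                     image_id = sprintf("phantom_%05d", index), check = TRUE)
  # auxiliary anchors share the global transform (no jitter)
  aux_t <- rbind(v1 = c(0.25, 0.42), v2 = c(0.22, 0.28), v3 = c(0.35, 0.14),
                 v4 = c(0.55, 0.10), v5 = c(0.68, 0.16), v6 = c(0.70, 0.24),
                 nose = c(0.70, 0.44), chin1 = c(0.68, 0.61),
                 chin2 = c(0.67, 0.70), ui = c(0.60, 0.56),
                 li = c(0.60, 0.65), prof0 = c(0.66, 0.30))
  ab <- cbind(aux_t[, 1] * w, aux_t[, 2] * h)
  axr <- ab[, 1] - cx; ayr <- ab[, 2] - cy
  aux <- cbind(cx + g * (cos(rot) * axr - sin(rot) * ayr) + shift[1],
               cy + g * (sin(rot) * axr + cos(rot) * ayr) + shift[2])
  rownames(aux) <- rownames(aux_t)
  img <- matrix(spec$background, h, w)
  bone <- spec$bone_intensity; soft <- spec$soft_intensity
  p <- function(nms) pts[nms, , drop = FALSE]
  a <- function(nms) aux[nms, , drop = FALSE]
  # cranial vault and base
  img <- stroke_polyline(img, rbind(a(c("v1", "v2", "v3", "v4", "v5", "v6")),
                                    p("nasion")), bone)
  img <- stroke_polyline(img, rbind(p("sella"), p("nasion")), bone * 0.8)
  img <- stroke_polyline(img, rbind(p("articulare"), p("sella")), bone * 0.8)
  # sella ring (landmark at the lowest point of the ring)
  r_s <- 0.022 * min(w, h) * g
  img <- stroke_polyline(img, circle_points(pts["sella", ] - c(0, r_s), r_s),
                         bone)
  # orbit (landmark on the lower rim)
  r_o <- 0.03 * min(w, h) * g
  img <- stroke_polyline(img,
                         circle_points(pts["orbitale", ] - c(0, r_o), r_o),
                         bone * 0.9)
  # porion bar
  img <- stroke_polyline(img, rbind(pts["porion", ] + c(-0.02 * w, 0),
                                    pts["porion", ] + c(0.02 * w, 0)),
                         bone * 0.9)
  # mandible
  img <- stroke_polyline(img, rbind(p("articulare"), p("gonion"), p("menton"),
                                    p("gnathion"), p("pogonion"),
                                    p("supramentale")), bone)
  # maxilla / palatal plane and A-point ridge
  img <- stroke_polyline(img, rbind(p("posterior_nasal_spine"),
                                    p("anterior_nasal_spine")), bone)
  img <- stroke_polyline(img, rbind(p("anterior_nasal_spine"),
                                    p("subspinale"),
                                    p("incision_superius")), bone * 0.9)
  # incisors
  img <- stroke_polyline(img, rbind(a("ui"), p("incision_superius")), bone)
  img <- stroke_polyline(img, rbind(a("li"), p("incision_inferius")), bone)
  # soft-tissue profile
  img <- stroke_polyline(img, rbind(a("prof0"), a("nose"), p("subnasale"),
                                    p("upper_lip"), a("chin1"),
                                    p("lower_lip"), a("chin2"),
                                    p("soft_tissue_pogonion")), soft)
  # landmark markers: bright blob plus a short tick at a per-landmark
  # angle, so every landmark is a locally unambiguous high-gradient point
  # (the identity cue is local, not positional)
  if (spec$marker_intensity > 0) {
    for (i in 1:19) {
      # identity is coded locally: a graded blob intensity plus a tick at a
      # per-landmark angle, so each landmark is a visually unambiguous
      # high-gradient point distinguishable from its neighbourhood alone
      amp <- spec$marker_intensity * (0.55 + 0.45 * (i - 1) / 18)
      img <- stroke_polyline(img, rbind(pts[i, ], pts[i, ]), amp,
                             width = 1.3)
      ang <- 2 * pi * (i - 1) / 19
      tick <- pts[i, ] + 5.5 * c(cos(ang), sin(ang))
      img <- stroke_polyline(img, rbind(pts[i, ], tick), amp * 0.8,
                             width = 0.8)
    }
  }
  img <- gaussian_blur(img, spec$blur_sd)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  img[img > 1] <- 1; img[img < 0] <- 0
  ages <- c(8, 9, 10, 11, 13, 14, 15, 16)
  bin <- min(7, floor((g - spec$scale_range[1]) /
                        diff(spec$scale_range) * 8))
  structure(list(image = img, landmarks = lm,
                 params = list(scale = g, rotation = rot * 180 / pi,
                               shift = shift),
                 stratum = as.character(ages[bin + 1]), index = index),
            class = "phantom_sample")
}

#' Generate an in-memory phantom dataset
#'
#' @param n Number of samples.
#' @param spec A [phantom_spec()].
#' @param seed Master seed.
#' @return List with `images` (`H x W x 1 x n` array), `landmarks` (list of
#'   [landmark_set]), `strata` (named character vector).
#' @export
phantom_dataset <- function(n, spec = phantom_spec(), seed = 0L) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  images <- array(0, dim = c(h, w, 1L, n))
  landmarks <- vector("list", n)
  strata <- character(n)
  for (i in seq_len(n)) {
    s <- sample_phantom(spec, i, seed)
    images[, , 1, i] <- s$image
    landmarks[[i]] <- s$landmarks
    strata[i] <- s$stratum
  }
  names(strata) <- vapply(landmarks, function(l) l$image_id, "")
  list(images = images, landmarks = landmarks, strata = strata)
}

#' Write a phantom dataset to disk
#'
#' Writes `n` PNG images, the landmark CSV, and a JSON manifest recording
#' the spec, seed, per-sample parameters, strata, file checksums, and the
#' train/validation/test split. Re-running with the same arguments
#' reproduces identical bytes.
#'
#' @param n Number of samples.
#' @param spec A [phantom_spec()].
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param split Fractions `(train, val, test)`; sizes are
#'   `floor(f * n)` for train and validation, remainder test.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 0L, out_dir,
                             split = c(0.7, 0.15, 0.15), overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop(sprintf("refusing to write into non-empty directory %s", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- floor(split[1] * n); n_val <- floor(split[2] * n)
  assign_split <- c(rep("train", n_train), rep("val", n_val),
                    rep("test", n - n_train - n_val))
  landmarks <- vector("list", n)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_phantom(spec, i, seed)
    f <- sprintf("phantom_%05d.png", i)
    png::writePNG(s$image, file.path(out_dir, f))
    landmarks[[i]] <- s$landmarks
    entries[[i]] <- list(index = i, file = f, stratum = s$stratum,
                         split = assign_split[i], params = s$params)
  }
  write_landmarks_csv(landmarks, file.path(out_dir, "landmarks.csv"))
  md5 <- tools::md5sum(file.path(out_dir,
                                 vapply(entries, `[[`, "", "file")))
  for (i in seq_len(n)) entries[[i]]$md5 <- unname(md5[i])
  manifest <- list(spec = unclass(spec), seed = seed, n = n,
                   split_fractions = split, samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

rot_dir <- function(u, deg) {
  th <- deg * pi / 180
  c(cos(th) * u[1] - sin(th) * u[2], sin(th) * u[1] + cos(th) * u[2])
}

#' Construct a landmark set achieving prescribed measurement values
#'
#' Inverse geometry for test fixtures: places nasion at a fixed origin,
#' sella behind it on the horizontal, subspinale/supramentale at polar
#' angles realizing the requested SNA/SNB/ANB, gonion on the circle fixing
#' FHI along the direction fixing FMA, and (when requested) rotates the
#' palatal plane for ODI and the facial plane for APDI. Unconstrained
#' landmarks take plausible default positions.
#'
#' @param targets Named list with any of `SNA`, `SNB`, `ANB` (degrees;
#'   must satisfy `ANB = SNA - SNB` when all three are given), `FHI`,
#'   `FMA`, `ODI`, `APDI`.
#' @param tol Consistency tolerance for over-determined angle targets.
#' @return A [landmark_set] whose [compute_measurements()] match each
#'   requested target within 1e-6.
#' @export
landmarks_with_measurements <- function(targets = list(), tol = 1e-6) {
  t <- targets
  sna <- t$SNA; snb <- t$SNB; anb <- t$ANB
  if (!is.null(anb) && !is.null(sna) && !is.null(snb) &&
      abs(anb - (sna - snb)) > tol)
    stop("inconsistent targets: ANB must equal SNA - SNB")
  if (is.null(snb)) snb <- if (!is.null(anb) && !is.null(sna)) sna - anb
                           else 77.5
  if (is.null(sna)) sna <- if (!is.null(anb)) snb + anb else snb + 4
  fhi <- if (is.null(t$FHI)) 0.70 else t$FHI
  fma <- if (is.null(t$FMA)) 29 else t$FMA
  N <- c(200, 120); S <- c(100, 120)
  u0 <- c(-1, 0)                      # N -> S
  A <- N + 110 * rot_dir(u0, -sna)    # rotate towards the face (down-front)
  B <- N + 100 * rot_dir(u0, -snb)
  Me <- c(180, 260); Gn <- c(192, 258)
  v <- c(cos(fma * pi / 180), sin(fma * pi / 180))  # Go -> Gn direction
  r <- fhi * sqrt(sum((N - Me)^2))
  gs <- Gn - S
  bq <- sum(v * gs); cq <- sum(gs^2) - r^2
  disc <- bq^2 - cq
  if (disc < 0)
    stop("infeasible targets: no gonion satisfies FHI and FMA jointly")
  tq <- bq - sqrt(disc)
  if (tq <= 0) tq <- bq + sqrt(disc)
  if (tq <= 0) stop("infeasible targets: gonion would coincide with gnathion")
  Go <- Gn - tq * v
  Po <- c(90, 130); Or <- c(210, 140)
  fh <- (Or - Po) / sqrt(sum((Or - Po)^2))
  Mpal <- c(182.5, 166.5); Lpal <- 32.5
  wpal <- (c(215, 168) - c(150, 165)); wpal <- wpal / sqrt(sum(wpal^2))
  if (!is.null(t$ODI)) {
    term1 <- as.numeric(line_angle(A, B, Me, Go))
    tau <- t$ODI - term1
    if (tau < 0 || tau > 180)
      stop(sprintf("infeasible targets: ODI needs a palatal-FH angle of %.2f",
                   tau))
    wpal <- rot_dir(fh, tau)
  }
  PNS <- Mpal - Lpal * wpal; ANS <- Mpal + Lpal * wpal
  Pog <- c(196, 252)
  if (!is.null(t$APDI)) {
    rp <- sqrt(sum((Pog - N)^2))
    fobj <- function(th) {
      d <- rot_dir(fh, th)
      as.numeric(line_angle(Po, Or, N, N + d)) +
        as.numeric(line_angle(N, N + d, A, B)) +
        as.numeric(line_angle(Po, Or, PNS, ANS)) - t$APDI
    }
    grid <- seq(1, 179, by = 2)
    fv <- vapply(grid, fobj, 0)
    k <- which(fv[-1] * fv[-length(fv)] <= 0)[1]
    if (is.na(k))
      stop("infeasible targets: no facial-plane direction realizes APDI")
    th <- uniroot(fobj, c(grid[k], grid[k + 1]), tol = 1e-10)$root
    Pog <- N + rp * rot_dir(fh, th)
  }
  pts <- rbind(sella = S, nasion = N, orbitale = Or, porion = Po,
               subspinale = A, supramentale = B, pogonion = Pog,
               menton = Me, gnathion = Gn, gonion = Go,
               incision_inferius = c(205, 205), incision_superius = c(208, 195),
               upper_lip = c(235, 180), lower_lip = c(237, 205),
               subnasale = c(228, 162), soft_tissue_pogonion = c(225, 250),
               posterior_nasal_spine = PNS, anterior_nasal_spine = ANS,
               articulare = c(95, 150))
  landmark_set(pts, frame = "phantom", width = 400, height = 400,
               image_id = "constructed")
}
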