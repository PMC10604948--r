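# Independent oracles used across the suite. These are deliberately naive
# transcriptions (scalar loops, brute force) kept free of any package
# internals so they can arbitrate the optimised implementations.

# direct scalar evaluation of the Gaussian heatmap value at one pixel
oracle_heatmap_value <- function(x, y, lx, ly, sigma, amplitude,
                                 clamp = TRUE) {
  v <- amplitude / (sigma * sqrt(2 * pi)) *
    exp(-((x - lx)^2 + (y - ly)^2) / (2 * sigma^2))
  if (clamp) min(v, 1) else v
}

# naive same-padding dilated convolution
oracle_conv2d <- function(x, w, b, dil = 1) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  c0 <- (k - 1) / 2
  y <- array(0, c(d[1], d[2], cout, d[4]))
  for (bb in seq_len(d[4])) for (co in seq_len(cout))
    for (xx in seq_len(d[2])) for (yy in seq_len(d[1])) {
      acc <- b[co]
      for (ci in seq_len(d[3])) for (kw in seq_len(k)) for (kh in seq_len(k)) {
        sy <- yy + (kh - 1 - c0) * dil
        sx <- xx + (kw - 1 - c0) * dil
        if (sy >= 1 && sy <= d[1] && sx >= 1 && sx <= d[2])
          acc <- acc + x[sy, sx, ci, bb] * w[kh, kw, ci, co]
      }
      y[yy, xx, co, bb] <- acc
    }
  y
}

# four-nested-loop transcription of the spatial attention equations:
# scores s[i, j] = <F0_i, F1_j> over positions, softmax over i,
# out_j = gamma * sum_i p[i, j] F2_i + F_j
oracle_spatial_attention <- function(f, gamma) {
  d <- dim(f); N <- d[1] * d[2]; C <- d[3]
  G <- matrix(f, nrow = N)              # N x C, F_i = G[i, ]
  S <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) S[i, j] <- sum(G[i, ] * G[j, ])
  P <- matrix(0, N, N)
  for (j in 1:N) {
    e <- exp(S[, j] - max(S[, j]))
    P[, j] <- e / sum(e)
  }
  O <- matrix(0, N, C)
  for (j in 1:N) {
    acc <- numeric(C)
    for (i in 1:N) acc <- acc + P[i, j] * G[i, ]
    O[j, ] <- gamma * acc + G[j, ]
  }
  array(O, dim = d)
}

# loop transcription of channel attention: s[i, j] = <F_i, F_j> over
# channels, softmax over i, out_j = gamma * sum_i a[i, j] F_i + F_j
oracle_channel_attention <- function(f, gamma) {
  d <- dim(f); N <- d[1] * d[2]; C <- d[3]
  G <- matrix(f, nrow = N)              # channel i = G[, i]
  S <- matrix(0, C, C)
  for (i in 1:C) for (j in 1:C) S[i, j] <- sum(G[, i] * G[, j])
  A <- matrix(0, C, C)
  for (j in 1:C) {
    e <- exp(S[, j] - max(S[, j]))
    A[, j] <- e / sum(e)
  }
  O <- matrix(0, N, C)
  for (j in 1:C) {
    acc <- numeric(N)
    for (i in 1:C) acc <- acc + A[i, j] * G[, i]
    O[, j] <- gamma * acc + G[, j]
  }
  array(O, dim = d)
}

# elementwise scalar-loop cross-entropy
oracle_cel <- function(y, p, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    s <- s + y[i] * log(max(p[i], eps)) +
      (1 - y[i]) * log(max(1 - p[i], eps))
  }
  -s / length(y)
}

# independent per-layer parameter ledger for a given architecture config:
# conv k^2*Cin*Cout + Cout, BN 2*Cout, transposed conv 4*Cin*Cout + Cout,
# attention projections and the two gains counted once. Derived from the
# wiring description, not from the package's parameter containers.
oracle_parameter_ledger <- function(widths, stages = 3, msi = TRUE,
                                    sam = TRUE, cam = TRUE, nc = 20,
                                    ic = 1, sam_red = 8) {
  nl <- length(widths)
  conv <- function(cin, cout, bn = TRUE) 9 * cin * cout + cout +
    if (bn) 2 * cout else 0
  upconv <- function(cin, cout) 4 * cin * cout + cout
  total <- 0
  for (s in seq_len(stages)) {
    in1 <- if (s == 1) ic else widths[1] + ic
    total <- total + conv(in1, widths[1])
    for (l in 2:(nl - 1))
      total <- total + conv(widths[l - 1] +
                              if (s == 1 && msi) widths[l] else 0, widths[l])
    total <- total + conv(widths[nl - 1] +
                            if (s == 1 && msi) widths[nl] else 0, widths[nl])
    if (s == 1 && msi)
      for (l in 2:nl) total <- total + conv(ic, widths[l])
    if (s == 1) {
      C <- widths[nl]
      if (sam) {
        cp <- max(1, C %/% sam_red)
        total <- total + 2 * (C * cp + cp) + (C * C + C) + 1
      }
      if (cam) total <- total + 1
    } else {
      ccat <- widths[nl] * (1 + sam + cam)
      total <- total + 2 * conv(ccat, widths[nl]) +
        conv(2 * widths[nl], widths[nl])
    }
    for (l in (nl - 1):1) {
      cin_up <- if (l == nl - 1) widths[nl] else widths[l + 1]
      total <- total + upconv(cin_up, widths[l]) +
        conv(2 * widths[l], widths[l])
    }
    total <- total + conv(widths[1], nc, bn = FALSE)
  }
  total
}

# a landmark set with points scattered over a grid, for codec tests
random_landmark_set <- function(width, height, margin = 2, id = "rnd") {
  pts <- cbind(x = sample(margin:(width - 1 - margin), 19, replace = TRUE),
               y = sample(margin:(height - 1 - margin), 19, replace = TRUE))
  landmark_set(pts, frame = "phantom", width = width, height = height,
               image_id = id)
}

tiny_phantom_spec <- function() phantom_spec(image_size = c(96, 128),
                                             preset = "easy")
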