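test_that("default sigma makes the encoded peak exactly 1 at the landmark", {
  sp <- heatmap_spec()
  expect_equal(sp$amplitude, 5)
  expect_equal(sp$sigma, 5 / sqrt(2 * pi))
  h <- encode_landmark(c(5, 5), 11, 11, sp)
  expect_identical(h[6, 6], 1)
  # peak value equals amplitude / (sigma * sqrt(2*pi)) before clamping
  sp2 <- heatmap_spec(sigma = 2, amplitude = 5, clamp_to_unit = FALSE)
  h2 <- encode_landmark(c(5, 5), 11, 11, sp2)
  expect_equal(h2[6, 6], 5 / (2 * sqrt(2 * pi)))
})

test_that("encoded values match the scalar Gaussian oracle at every pixel", {
  sp <- heatmap_spec(sigma = 2, amplitude = 5)
  pt <- c(5, 5)
  h <- encode_landmark(pt, 11, 9, sp)
  for (x in 0:10) for (y in 0:8)
    expect_equal(h[y + 1, x + 1],
                 oracle_heatmap_value(x, y, pt[1], pt[2], 2, 5),
                 tolerance = 1e-12)
  # off-centre, non-integer landmark, point partly outside the grid
  sp3 <- heatmap_spec(sigma = 1.3, amplitude = 2)
  pt3 <- c(-1.25, 3.5)
  h3 <- encode_landmark(pt3, 7, 6, sp3)
  for (x in 0:6) for (y in 0:5)
    expect_equal(h3[y + 1, x + 1],
                 oracle_heatmap_value(x, y, pt3[1], pt3[2], 1.3, 2),
                 tolerance = 1e-12)
})

test_that("encoded heatmaps are radially symmetric around interior landmarks", {
  h <- encode_landmark(c(10, 12), 21, 25, heatmap_spec(sigma = 3))
  for (d in list(c(1, 0), c(0, 2), c(3, 4), c(2, -5)))
    expect_equal(h[12 + d[2] + 1, 10 + d[1] + 1],
                 h[12 - d[2] + 1, 10 - d[1] + 1], tolerance = 1e-12)
})

test_that("invalid heatmap inputs are rejected", {
  expect_error(encode_landmark(c(NA, 1), 5, 5), "finite")
  expect_error(heatmap_spec(sigma = 0), "positive")
  expect_error(heatmap_spec(amplitude = -1), "positive")
})

test_that("stack encoding fills 20 channels with a clamped background complement", {
  set.seed(11)
  lm <- random_landmark_set(32, 40)
  st <- encode_stack(lm)
  expect_identical(dim(st), c(40L, 32L, 20L))
  expect_true(all(st >= 0 & st <= 1))
  # where the landmark sum is below 1 the channels sum exactly to 1
  s19 <- rowSums(st[, , 1:19, drop = FALSE], dims = 2)
  tot <- s19 + st[, , 20]
  expect_true(all(tot[s19 <= 1] - 1 < 1e-12))
  # a pixel > 6 sigma away from every landmark has background ~ 1
  dmin <- matrix(0, 40, 32)
  for (y in 0:39) for (x in 0:31)
    dmin[y + 1, x + 1] <- min(sqrt((x - lm$points[, "x"])^2 +
                                     (y - lm$points[, "y"])^2))
  far <- which(dmin > 6 * heatmap_spec()$sigma, arr.ind = TRUE)
  if (nrow(far)) expect_equal(st[far[1, 1], far[1, 2], 20], 1,
                              tolerance = 1e-6)
})

test_that("coincident unit peaks clamp the background to zero, not negative", {
  pts <- matrix(rep(c(8, 8), 19), ncol = 2, byrow = TRUE)
  lm <- landmark_set(pts, frame = "phantom", width = 17, height = 17)
  st <- encode_stack(lm)
  expect_identical(st[9, 9, 20], 0)
  expect_true(all(st[, , 20] >= 0))
})

test_that("decoding returns the argmax with the row-major tie rule", {
  st <- array(0, c(30, 25, 20))
  st[21, 11, 1] <- 1                       # (x = 10, y = 20)
  out <- decode_stack(st)
  expect_equal(unname(out$points[1, ]), c(10, 20))
  # uniform channel decodes to (0, 0)
  expect_equal(unname(out$points[2, ]), c(0, 0))
  # tie between (5, 3) and (3, 5): smaller y wins
  st[4, 6, 3] <- 1; st[6, 4, 3] <- 1
  expect_equal(unname(decode_stack(st)$points[3, ]), c(5, 3))
  st[, , 4] <- NA
  expect_error(decode_stack(st), "channel 4")
})

test_that("decode after encode is the identity on interior integer landmarks", {
  set.seed(42)
  for (rep in 1:25) {
    lm <- random_landmark_set(28, 36, margin = 1)
    dec <- decode_stack(encode_stack(lm))
    expect_equal(unname(dec$points), unname(lm$points),
                 ignore_attr = TRUE, tolerance = 0)
  }
})

test_that("coordinate mapping scales by the frame ratio and round-trips", {
  set.seed(5)
  lm <- random_landmark_set(576, 736)
  up <- map_coordinates(lm, 2400, 3000, frame = "original")
  expect_equal(up$points[, "x"], lm$points[, "x"] * 25 / 6)
  expect_equal(up$points[, "y"], lm$points[, "y"] * 375 / 92)
  same <- map_coordinates(lm, 576, 736)
  expect_equal(same$points, lm$points)
  back <- map_coordinates(up, 576, 736, frame = "phantom")
  expect_equal(back$points, lm$points, tolerance = 1e-9)
  expect_error(map_coordinates(lm, 0, 10), "positive")
})

test_that("landmark CSV and JSON round-trip exactly", {
  set.seed(6)
  lms <- list(random_landmark_set(96, 128, id = "a"),
              random_landmark_set(96, 128, id = "b"))
  csv <- tempfile(fileext = ".csv")
  write_landmarks_csv(lms, csv)
  rd <- read_landmarks_csv(csv)
  expect_equal(rd$a$points, lms[[1]]$points)
  expect_equal(rd$b$points, lms[[2]]$points)
  js <- tempfile(fileext = ".json")
  write_landmarks_json(lms, js)
  rj <- read_landmarks_json(js)
  expect_equal(rj$b$points, lms[[2]]$points)
  expect_equal(rj$a$frame, "phantom")
})

test_that("heatmap stacks persist as multi-page float TIFF", {
  set.seed(7)
  lm <- random_landmark_set(24, 20)
  st <- encode_stack(lm)
  f <- tempfile(fileext = ".tif")
  write_heatmap_tiff(st, f)
  rt <- read_heatmap_tiff(f)
  expect_equal(dim(rt), dim(st))
  expect_equal(rt, st, tolerance = 1e-6)   # 32-bit storage
})

test_that("landmark container enforces order, count and finiteness", {
  expect_error(landmark_set(matrix(0, 18, 2), width = 10, height = 10),
               "19 x 2")
  bad <- matrix(0, 19, 2); bad[3, 1] <- Inf
  expect_error(landmark_set(bad, width = 10, height = 10), "finite")
  pts <- matrix(1, 19, 2)
  rownames(pts) <- rev(ceph_landmark_names())
  expect_error(landmark_set(pts, width = 10, height = 10), "canonical")
})
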