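test_that("vertex angles match the acos oracle and handle degeneracy", {
  expect_equal(angle_at_vertex(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(angle_at_vertex(c(2, 2), c(0, 0), c(1, 1)), 0)
  expect_equal(angle_at_vertex(c(-1, -1), c(0, 0), c(2, 2)), 180)
  set.seed(50)
  for (rep in 1:50) {
    a <- rnorm(2); v <- rnorm(2); b <- rnorm(2)
    u <- a - v; t <- b - v
    ref <- acos(max(-1, min(1, sum(u * t) / sqrt(sum(u^2) * sum(t^2))))) *
      180 / pi
    expect_equal(angle_at_vertex(a, v, b), ref, tolerance = 1e-9)
  }
  expect_error(angle_at_vertex(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("line angles respect the directed/undirected modes", {
  expect_equal(as.numeric(line_angle(c(0, 0), c(1, 0), c(2, 2), c(3, 2))), 0)
  expect_equal(as.numeric(line_angle(c(0, 0), c(1, 0), c(3, 2), c(2, 2))), 180)
  expect_equal(as.numeric(line_angle(c(0, 0), c(1, 0), c(3, 2), c(2, 2),
                                     mode = "undirected")), 0)
  set.seed(51)
  for (rep in 1:50) {
    p <- matrix(rnorm(8), 4, 2)
    u <- p[2, ] - p[1, ]; t <- p[4, ] - p[3, ]
    ref <- acos(max(-1, min(1, sum(u * t) / sqrt(sum(u^2) * sum(t^2))))) *
      180 / pi
    expect_equal(as.numeric(line_angle(p[1, ], p[2, ], p[3, ], p[4, ])),
                 ref, tolerance = 1e-9)
    expect_equal(as.numeric(line_angle(p[1, ], p[2, ], p[3, ], p[4, ],
                                       mode = "undirected")),
                 min(ref, 180 - ref), tolerance = 1e-9)
  }
  expect_error(line_angle(c(1, 1), c(1, 1), c(0, 0), c(1, 0)), "degenerate")
  # undirected mode is symmetric under endpoint swap within each line
  expect_equal(as.numeric(line_angle(c(0, 0), c(2, 1), c(1, 0), c(0, 3),
                                     mode = "undirected")),
               as.numeric(line_angle(c(2, 1), c(0, 0), c(0, 3), c(1, 0),
                                     mode = "undirected")), tolerance = 1e-12)
})

test_that("constructed landmark sets achieve the requested measurement values", {
  lm <- landmarks_with_measurements(list(SNA = 82, SNB = 78))
  m <- compute_measurements(lm)
  expect_equal(m$SNA, 82, tolerance = 1e-6)
  expect_equal(m$SNB, 78, tolerance = 1e-6)
  expect_equal(m$ANB, 4, tolerance = 1e-6)
  lm2 <- landmarks_with_measurements(list(FHI = 0.70, FMA = 27.5))
  m2 <- compute_measurements(lm2)
  expect_equal(m2$FHI, 0.70, tolerance = 1e-9)
  expect_equal(m2$FMA, 27.5, tolerance = 1e-6)
  lm3 <- landmarks_with_measurements(list(ODI = 74))
  expect_equal(compute_measurements(lm3)$ODI, 74, tolerance = 1e-6)
  lm4 <- landmarks_with_measurements(list(APDI = 130))
  expect_equal(compute_measurements(lm4)$APDI, 130, tolerance = 1e-6)
  # with unsigned directed plane angles, small APDI values are outside the
  # attainable range of the default geometry
  expect_error(landmarks_with_measurements(list(APDI = 80)), "infeasible")
  expect_error(landmarks_with_measurements(list(SNA = 82, SNB = 78,
                                                ANB = 10)),
               "inconsistent")
})

rigid_transform <- function(lm, deg, scale = 1, shift = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- scale * lm$points %*% t(R)
  p[, 1] <- p[, 1] + shift[1]; p[, 2] <- p[, 2] + shift[2]
  landmark_set(p, frame = lm$frame, width = 10000, height = 10000,
               image_id = lm$image_id)
}

test_that("all seven measurements are invariant to rigid motion and scale", {
  lm <- landmarks_with_measurements(list(SNA = 83, SNB = 77.2, FHI = 0.68))
  m0 <- unlist(compute_measurements(lm))
  for (tf in list(c(17, 1), c(-33, 2.5), c(121, 0.4))) {
    m1 <- unlist(compute_measurements(rigid_transform(lm, tf[1], tf[2],
                                                      c(40, -15))))
    expect_equal(m1, m0, tolerance = 1e-9)
  }
})

test_that("ANB equals SNA - SNB when A and B lie on the same side of S-N", {
  set.seed(52)
  for (rep in 1:10) {
    sna <- runif(1, 76, 88); snb <- runif(1, 72, min(sna, 84))
    m <- compute_measurements(landmarks_with_measurements(
      list(SNA = sna, SNB = snb)))
    expect_equal(m$ANB, abs(m$SNA - m$SNB), tolerance = 1e-9)
  }
})

test_that("classification follows the printed thresholds", {
  rules <- classification_rules("corrected")
  base <- unlist(compute_measurements(landmarks_with_measurements(list())))
  mk <- function(...) {
    v <- as.list(base); v[names(list(...))] <- list(...); v
  }
  cls <- function(v, mn) {
    r <- classify_measurements(v, rules)
    r$class[r$measurement == mn]
  }
  expect_identical(cls(mk(ANB = 4.0), "ANB"), 1L)
  expect_identical(cls(mk(ANB = 6.0), "ANB"), 2L)
  expect_identical(cls(mk(ANB = 2.0), "ANB"), 3L)
  expect_identical(cls(mk(FHI = 0.80), "FHI"), 2L)
  expect_identical(cls(mk(FHI = 0.60), "FHI"), 3L)
  expect_identical(cls(mk(SNA = 70.0), "SNA"), 3L)
  expect_identical(cls(mk(SNA = 85.0), "SNA"), 2L)
  expect_identical(cls(mk(SNB = 76.0), "SNB"), 1L)
  expect_identical(cls(mk(SNB = 72.0), "SNB"), 2L)
  expect_identical(cls(mk(FMA = 29.0), "FMA"), 1L)
  expect_identical(cls(mk(FMA = 33.0), "FMA"), 2L)
  expect_identical(cls(mk(FMA = 20.0), "FMA"), 3L)
  expect_identical(cls(mk(APDI = 90.0), "APDI"), 3L)
  expect_identical(cls(mk(APDI = 70.0), "APDI"), 2L)
})

test_that("boundary probes land in documented classes with boundary flags", {
  rules <- classification_rules("corrected")
  base <- as.list(unlist(compute_measurements(
    landmarks_with_measurements(list()))))
  probe <- function(anb) {
    v <- base; v$ANB <- anb
    classify_measurements(v, rules)[1, ]
  }
  eps <- 1e-9
  expect_identical(probe(3.2)$class, 1L)          # closed interval
  expect_true(probe(3.2)$boundary)
  expect_identical(probe(3.2 - eps)$class, 3L)
  expect_identical(probe(5.7)$class, 1L)
  expect_identical(probe(5.7 + eps)$class, 2L)
})

test_that("the literal rule variant flags the printed SNB/ODI/APDI overlaps", {
  lit <- classification_rules("literal")
  base <- as.list(unlist(compute_measurements(
    landmarks_with_measurements(list()))))
  r <- function(field, value) {
    v <- base; v[[field]] <- value
    classify_measurements(v, lit)
  }
  snb <- r("SNB", 76); snb <- snb[snb$measurement == "SNB", ]
  expect_identical(snb$class, 1L)                 # class-1 precedence
  expect_true(snb$overlap)                        # also satisfies "< 78.7"
  odi <- r("ODI", 79); odi <- odi[odi$measurement == "ODI", ]
  expect_true(odi$overlap)
  apdi <- r("APDI", 80); apdi <- apdi[apdi$measurement == "APDI", ]
  expect_true(apdi$overlap)
  # the printed SNA rules leave (83.2, 83.5] unclassifiable
  sna <- r("SNA", 83.4); sna <- sna[sna$measurement == "SNA", ]
  expect_true(sna$unclassifiable)
  expect_true(is.na(sna$class))
  # corrected variant classifies the same value
  snc <- classify_measurements({v <- base; v$SNA <- 83.4; v},
                               classification_rules("corrected"))
  expect_identical(snc$class[snc$measurement == "SNA"], 2L)
})

test_that("classification accuracy counts per-measurement matches", {
  rules <- classification_rules("corrected")
  base <- as.list(unlist(compute_measurements(
    landmarks_with_measurements(list()))))
  mk <- function(anb) {
    v <- base; v$ANB <- anb
    classify_measurements(v, rules)
  }
  truth <- list(mk(4), mk(6), mk(2), mk(4))
  pred <- list(mk(4), mk(6), mk(4), mk(2))       # 2 of 4 right
  acc <- classification_accuracy(pred, truth)
  expect_equal(unname(acc$per_measurement["ANB"]), 50)
  expect_equal(unname(acc$per_measurement["FHI"]), 100)
  expect_equal(classification_accuracy(truth, truth)$mean, 100)
  expect_error(classification_accuracy(pred[1:2], truth), "length")
  set.seed(53)
  anbs_t <- runif(20, 0, 8); anbs_p <- runif(20, 0, 8)
  t2 <- lapply(anbs_t, mk); p2 <- lapply(anbs_p, mk)
  acc2 <- classification_accuracy(p2, t2)
  ct <- vapply(t2, function(x) x$class[1], 0L)
  cp <- vapply(p2, function(x) x$class[1], 0L)
  expect_equal(unname(acc2$per_measurement["ANB"]), 100 * mean(ct == cp))
})

test_that("measurement computation names missing landmarks", {
  lm <- landmarks_with_measurements(list())
  expect_s3_class(compute_measurements(lm), "ceph_measurements")
  expect_output(print(compute_measurements(lm)), "ANB")
})
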