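shift_set <- function(lm, dx, dy, id = lm$image_id) {
  p <- lm$points; p[, 1] <- p[, 1] + dx; p[, 2] <- p[, 2] + dy
  landmark_set(p, frame = lm$frame, width = lm$width, height = lm$height,
               image_id = id)
}

px_cal <- function(w = 100, h = 100) ceph_calibration(1, c(w, h), c(w, h))

test_that("radial errors follow the calibrated Euclidean distance", {
  set.seed(40)
  truth <- random_landmark_set(2400, 3000, id = "img1")
  truth$frame <- "original"
  pred <- truth
  pred$points[1, ] <- c(0, 0); truth$points[1, ] <- c(3, 4)
  tab <- radial_errors(list(pred), list(truth), ceph_calibration())
  expect_equal(tab$error_mm[1], 0.5)             # 3-4-5 triangle at 0.1 mm/px
  expect_equal(tab$error_mm[-1], rep(0, 18))
})

test_that("radial errors match a scalar distance loop oracle", {
  set.seed(41)
  truth <- lapply(1:4, function(i) random_landmark_set(200, 200,
                                                       id = paste0("i", i)))
  pred <- lapply(truth, function(l) {
    l$points <- l$points + matrix(rnorm(38), 19, 2); l
  })
  tab <- radial_errors(pred, truth, px_cal(200, 200))
  k <- 0
  for (i in 1:4) for (j in 1:19) {
    k <- k + 1
    d <- sqrt(sum((pred[[i]]$points[j, ] - truth[[i]]$points[j, ])^2))
    expect_equal(tab$error_mm[k], d, tolerance = 1e-12)
  }
  expect_error(radial_errors(pred[1:2], truth[3:4], px_cal()), "unpaired")
})

test_that("errors computed via the resized frame equal errors in the original frame", {
  set.seed(42)
  truth <- random_landmark_set(2400, 3000, id = "x")
  truth$frame <- "original"
  pred <- shift_set(truth, 5, -3)
  # same landmarks expressed in the anisotropically resized frame
  truth_r <- map_coordinates(truth, 576, 736, frame = "resized")
  pred_r <- map_coordinates(pred, 576, 736, frame = "resized")
  t1 <- radial_errors(list(pred), list(truth), ceph_calibration())
  t2 <- radial_errors(list(pred_r), list(truth_r), ceph_calibration())
  expect_equal(t1$error_mm, t2$error_mm, tolerance = 1e-9)
})

test_that("MRE reports the arithmetic mean with population SD", {
  tab <- data.frame(image_id = "a", landmark = c("x", "y", "z"),
                    error_mm = c(1, 1, 1), stratum = NA)
  r <- mre(tab)
  expect_equal(r$mre, 1); expect_equal(r$sd, 0)
  tab2 <- data.frame(image_id = "a", landmark = c("x", "y"),
                     error_mm = c(0, 2), stratum = NA)
  r2 <- mre(tab2)
  expect_equal(r2$mre, 1); expect_equal(r2$sd, 1)   # population SD
  set.seed(43)
  e <- runif(1000, 0, 5)
  tab3 <- data.frame(image_id = "a", landmark = "x", error_mm = e,
                     stratum = NA)
  r3 <- mre(tab3)
  expect_equal(r3$mre, sum(e) / 1000, tolerance = 1e-9)
  expect_equal(r3$sd, sqrt(sum((e - mean(e))^2) / 1000), tolerance = 1e-9)
})

test_that("SDR uses a strict boundary and matches a counting oracle", {
  tab <- data.frame(image_id = "a", landmark = "sella", error_mm = 1.5,
                    stratum = NA)
  r <- sdr(tab)
  ov <- r[r$group == "overall", ]
  expect_equal(ov$sdr_1, 0); expect_equal(ov$sdr_2, 100)
  # an error exactly at the threshold does not count as detected
  tabb <- data.frame(image_id = "a", landmark = "sella", error_mm = 2,
                     stratum = NA)
  expect_equal(sdr(tabb)[2, "sdr_2"], 0)
  expect_equal(sdr(tabb, strict = FALSE)[2, "sdr_2"], 100)
  set.seed(44)
  e <- runif(10000, 0, 6)
  tabr <- data.frame(image_id = "a", landmark = "sella", error_mm = e,
                     stratum = NA)
  rr <- sdr(tabr)
  for (t in c(1, 2, 3, 4, 5))
    expect_equal(rr[2, sprintf("sdr_%g", t)], 100 * sum(e < t) / 10000)
  vals <- unlist(rr[2, sprintf("sdr_%g", 1:5)])
  expect_true(all(diff(vals) >= 0))                # monotone in threshold
  expect_error(sdr(tab, thresholds = c(3, 1)), "ascending")
})

test_that("SDR is invariant to row order", {
  set.seed(45)
  e <- runif(200, 0, 6)
  tab <- data.frame(image_id = "a",
                    landmark = sample(ceph_landmark_names(), 200, TRUE),
                    error_mm = e, stratum = NA)
  r1 <- sdr(tab)
  o <- sample(200)
  r2 <- sdr(tab[o, ])
  expect_equal(r1, r2)
})

test_that("cumulative curve is the empirical CDF and ends at 1", {
  tab <- data.frame(image_id = "a", landmark = "x", error_mm = c(1, 2, 3),
                    stratum = NA)
  cc <- cumulative_curve(tab, grid = 2)
  expect_equal(cc$fraction, 2 / 3)
  set.seed(46)
  e <- runif(500, 0, 4)
  tabr <- data.frame(image_id = "a", landmark = "x", error_mm = e,
                     stratum = NA)
  grid <- seq(0, 4, by = 0.5)
  cc2 <- cumulative_curve(tabr, grid)
  ecdf_oracle <- vapply(grid, function(g) sum(sort(e) <= g) / 500, 0)
  expect_equal(cc2$fraction, ecdf_oracle)
  expect_equal(cumulative_curve(tabr, max(e))$fraction, 1)
  expect_true(all(diff(cc2$fraction) >= 0))
})

test_that("stratified reports split by tag and recover the overall MRE", {
  set.seed(47)
  truth <- lapply(1:6, function(i) random_landmark_set(100, 100,
                                                       id = paste0("i", i)))
  pred <- lapply(truth, function(l) shift_set(l, rnorm(1), rnorm(1)))
  strata <- setNames(rep(c("8", "9", "10"), each = 2),
                     vapply(truth, function(l) l$image_id, ""))
  tab <- radial_errors(pred, truth, px_cal(), strata = strata)
  rep <- stratified_report(tab)
  expect_named(rep, c("10", "8", "9", "overall"))
  # single stratum equals the overall report of its subset
  sub <- tab[tab$stratum == "8", ]
  expect_equal(rep[["8"]], sdr(sub))
  # overall MRE is the count-weighted mean of stratum MREs
  per <- vapply(c("8", "9", "10"), function(s)
    mean(tab$error_mm[tab$stratum == s]), 0)
  n_per <- vapply(c("8", "9", "10"), function(s)
    sum(tab$stratum == s), 0)
  expect_equal(sum(per * n_per) / sum(n_per),
               rep$overall[rep$overall$group == "overall", "mre"],
               tolerance = 1e-12)
  expect_error(stratified_report(radial_errors(pred, truth, px_cal())),
               "no stratum")
})

test_that("SDR reports serialise to CSV and JSON", {
  tab <- data.frame(image_id = "a", landmark = "sella",
                    error_mm = c(0.4, 1.7), stratum = NA)
  r <- sdr(tab)
  fc <- tempfile(fileext = ".csv")
  write_sdr_report(r, fc)
  back <- read.csv(fc)
  expect_equal(back$mre, r$mre)
  fj <- tempfile(fileext = ".json")
  write_sdr_report(r, fj)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_identical(js$boundary, "strict")
})
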