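test_that("cross-entropy matches the scalar loop oracle", {
  expect_equal(cel(array(1, c(1, 1, 1, 1)), array(1, c(1, 1, 1, 1))), 0,
               tolerance = 1e-12)
  expect_equal(cel(1, 0.5), log(2), tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:5) {
    y <- array(runif(2 * 3 * 3), c(3, 3, 2, 1))
    p <- array(runif(2 * 3 * 3), c(3, 3, 2, 1))
    expect_equal(cel(y, p), oracle_cel(y, p), tolerance = 1e-10)
  }
  expect_error(cel(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("loss is permutation-invariant and non-negative", {
  set.seed(21)
  y <- runif(50); p <- runif(50)
  o <- sample(50)
  expect_equal(cel(y, p), cel(y[o], p[o]))
  expect_gte(cel(y, p), 0)
})

test_that("deep-supervision loss is exactly the sum of its stage terms", {
  set.seed(22)
  y <- array(runif(24), c(2, 3, 4, 1))
  ps <- lapply(1:3, function(i) array(runif(24), c(2, 3, 4, 1)))
  expect_identical(fcel(y, ps), cel(y, ps[[1]]) + cel(y, ps[[2]]) +
                     cel(y, ps[[3]]))
  expect_equal(fcel(y, list(ps[[1]], ps[[1]], ps[[1]])), 3 * cel(y, ps[[1]]))
  yb <- array(round(runif(24)), c(2, 3, 4, 1))
  expect_equal(fcel(yb, list(yb, ps[[2]], ps[[3]])),
               cel(yb, ps[[2]]) + cel(yb, ps[[3]]), tolerance = 1e-5)
  expect_error(fcel(y, ps[1:2], n_stages = 3), "3 stage")
})

test_that("plateau schedule halves the rate after exactly `patience` flat epochs", {
  ctl <- train_control(plateau_patience = 25L, plateau_factor = 0.5)
  lr <- 1e-4; best <- Inf; since <- 0L
  lrs <- numeric(26)
  for (ep in 1:26) {
    val <- 1.0   # epoch 1 improves over Inf; 2..26 never improve
    ps <- cephmark:::plateau_step(val, best, since, lr, ctl)
    if (ps$improved) best <- val
    lr <- ps$lr; since <- ps$since_improve
    lrs[ep] <- lr
  }
  expect_identical(lrs[25], 1e-4)
  expect_identical(lrs[26], 5e-5)
  expect_identical(sum(lrs < 1e-4), 1L)
})

test_that("identity augmentation draw leaves image and landmarks unchanged", {
  set.seed(30)
  img <- matrix(runif(40 * 32), 40, 32)
  lm <- random_landmark_set(32, 40, margin = 6)
  sp <- augment_spec(rotation_deg = c(0, 0), zoom = c(1, 1),
                     intensity_scale = c(1, 1))
  a <- augment(img, lm, sp)
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_equal(a$landmarks$points, lm$points, tolerance = 1e-12)
})

test_that("point transform matches the closed-form rotation about the centre", {
  pts <- cephmark:::transform_points(cbind(10, 4), 90, 1, 21, 21)
  # 90 degrees about (10, 10) in y-down coordinates: (10, 4) -> (16, 10)
  expect_equal(unname(pts[1, ]), c(16, 10), tolerance = 1e-9)
  # zoom-only scales distances from the centre
  pz <- cephmark:::transform_points(cbind(14, 10), 0, 1.05, 21, 21)
  expect_equal(unname(pz[1, 1]), 10 + 4 * 1.05, tolerance = 1e-12)
})

test_that("augmentation is reproducible and preserves landmark order", {
  img <- matrix(runif(64 * 48), 64, 48)
  lm <- random_landmark_set(48, 64, margin = 10)
  set.seed(99); a1 <- augment(img, lm, augment_spec())
  set.seed(99); a2 <- augment(img, lm, augment_spec())
  expect_identical(a1$image, a2$image)
  expect_identical(a1$landmarks$points, a2$landmarks$points)
  expect_identical(rownames(a1$landmarks$points), ceph_landmark_names())
})

test_that("augmentation gives up after the retry cap when landmarks leave the frame", {
  img <- matrix(0, 20, 20)
  pts <- matrix(c(rep(19.4, 19), rep(10, 19)), 19, 2)  # at the right edge
  lm <- landmark_set(pts, frame = "phantom", width = 20, height = 20)
  sp <- augment_spec(rotation_deg = c(0, 0), zoom = c(1.4, 1.5),
                     intensity_scale = c(1, 1), max_retries = 3L)
  set.seed(1)
  expect_null(augment(img, lm, sp))
})

test_that("one RMSprop step on a fixed batch decreases the training loss", {
  spec <- phantom_spec(image_size = c(64, 64), preset = "easy")
  ds <- phantom_dataset(4, spec, seed = 1)
  cfg <- arch_config(input_size = c(64, 64), encoder_widths = c(4, 8, 16, 32))
  net <- build_network(cfg, seed = 0)
  xb <- ds$images
  yb <- cephmark:::batch_targets(ds$landmarks, 64, 64, heatmap_spec())
  fwd <- cephmark:::net_forward(net, xb, train = TRUE)
  l0 <- fcel(yb, fwd$outputs)
  grads <- cephmark:::net_backward(net, fwd, yb)
  st <- cephmark:::rmsprop_step(net$params, grads, list(), 1e-4, 0.9, 1e-7)
  net$params <- st$params
  l1 <- fcel(yb, cephmark:::net_forward(net, xb, train = TRUE)$outputs)
  expect_lt(l1, l0)
})

test_that("short fits are reproducible and track history and checkpoints", {
  spec <- phantom_spec(image_size = c(64, 64), preset = "easy")
  ds <- phantom_dataset(10, spec, seed = 2)
  tr <- list(images = ds$images[, , , 1:8, drop = FALSE],
             landmarks = ds$landmarks[1:8])
  va <- list(images = ds$images[, , , 9:10, drop = FALSE],
             landmarks = ds$landmarks[9:10])
  cfg <- arch_config(input_size = c(64, 64), encoder_widths = c(2, 4, 8, 16),
                     stage_count = 2)
  ctl <- train_control(epochs = 2, batch_size = 4, seed = 5)
  f1 <- fit(build_network(cfg, seed = 5), tr, va, control = ctl)
  f2 <- fit(build_network(cfg, seed = 5), tr, va, control = ctl)
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), 2L)
  expect_true(all(diff(f1$history$train_loss) <= 0))
  expect_s3_class(f1, "ceph_fit")
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(f1, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(net2$params, f1$network$params)
  mf <- jsonlite::read_json(paste0(ck, ".json"), simplifyVector = TRUE)
  expect_identical(mf$parameter_count, count_parameters(net2))
  preds <- predict(f1, va$images)
  expect_length(preds, 2)
  expect_s3_class(preds[[1]], "landmark_set")
})

test_that("training with augmentation regenerates targets and stays finite", {
  spec <- phantom_spec(image_size = c(64, 64), preset = "easy")
  ds <- phantom_dataset(8, spec, seed = 3)
  tr <- list(images = ds$images, landmarks = ds$landmarks)
  cfg <- arch_config(input_size = c(64, 64), encoder_widths = c(2, 4, 8, 16),
                     stage_count = 1)
  ctl <- train_control(epochs = 1, batch_size = 4, seed = 6)
  f <- fit(build_network(cfg, seed = 6), tr, tr, control = ctl,
           augmentation = augment_spec(rotation_deg = c(-5, 5)))
  expect_true(is.finite(f$history$train_loss))
})
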