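test_that("phase alignment removes the global phase and flags zero input", {
  x <- complex(real = c(2, 0.5, -1), imaginary = c(0, 1, 0.3))
  a0 <- phase_align(x)
  expect_equal(a0, Re(x), ignore_attr = TRUE)    # already aligned
  for (phi in c(0.7, -2.3, pi)) {
    expect_equal(phase_align(exp(1i * phi) * x), a0, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_gte(phase_align(x)[1L], 0)
  z <- phase_align(rep(0 + 0i, 3))
  expect_true(all(z == 0))
  expect_true(attr(z, "flagged"))
  both <- phase_align(x, "realimag")
  expect_length(both, 6L)
})

test_that("aligned dictionary atoms concentrate energy in the real channel", {
  cd <- coarse_dict()
  x <- cd$dict$compressed * exp(1i * 0.9)        # arbitrary acquisition phase
  enc <- phase_align(x, "realimag")
  re <- enc[, 1:10]; im <- enc[, 11:20]
  expect_true(all(rowSums(re^2) >= rowSums(im^2)))
})

test_that("the training split is a seeded disjoint 80/20 partition", {
  cd <- coarse_dict()
  cfg <- training_config(noise_sigma = 0.01, seed = 4L)
  d1 <- make_training_set(cd$dict, cfg)
  n <- nrow(cd$dict$params)
  expect_lte(abs(nrow(d1$train$x) - 0.8 * n), 1)
  expect_equal(nrow(d1$train$x) + nrow(d1$validation$x), n)
  expect_length(intersect(d1$train$index, d1$validation$index), 0L)
  d2 <- make_training_set(cd$dict, cfg)
  expect_identical(d1$train$index, d2$train$index)
  expect_equal(d1$train$x, d2$train$x)           # noise reseeded too
  # inputs are unit norm; targets carry the compressed unit-PD norm
  expect_lt(max(abs(sqrt(rowSums(d1$train$x^2)) - 1)), 1e-9)
  expect_equal(d1$train$y[, "theta3"],
               cd$dict$catom_norms[d1$train$index])
})

test_that("training reduces the loss and returns the best checkpoint", {
  nf <- nn_fixture()
  h <- nf$model$history
  expect_lt(tail(h$train_loss, 1L), h$train_loss[1L])
  expect_equal(nf$model$best_val_loss, min(h$val_loss))
  expect_equal(h$val_loss[nf$model$best_epoch], min(h$val_loss))
})

test_that("the trained network recovers held-out atoms", {
  nf <- nn_fixture()
  cd <- coarse_dict()
  va <- nf$data$validation$index
  clean <- cd$dict$compressed[va, ] * cd$dict$catom_norms[va]
  est <- infer_maps_nn(nf$model, clean)
  ape_t1 <- abs(est$t1_ms - cd$dict$params$t1_ms[va]) / cd$dict$params$t1_ms[va]
  ape_t2 <- abs(est$t2_ms - cd$dict$params$t2_ms[va]) / cd$dict$params$t2_ms[va]
  expect_lt(median(ape_t1), 0.05)
  expect_lt(median(ape_t2), 0.05)
  # percentage errors center on zero: median bias magnitude below 2%
  bias_t1 <- median((est$t1_ms - cd$dict$params$t1_ms[va]) /
                      cd$dict$params$t1_ms[va])
  expect_lt(abs(bias_t1), 0.02)
  # unit-PD atoms recover pd near 1; scaling the atom scales pd
  expect_lt(median(abs(est$pd - 1)), 0.1)
  est3 <- infer_maps_nn(nf$model, 3 * clean)
  expect_equal(est3$pd, 3 * est$pd, tolerance = 1e-9)
})

test_that("inference is phase invariant, masked, and exact in the PD identity", {
  nf <- nn_fixture()
  cd <- coarse_dict()
  x <- cd$dict$compressed[21:30, ] * cd$dict$catom_norms[21:30]
  est <- infer_maps_nn(nf$model, x)
  est_ph <- infer_maps_nn(nf$model, exp(1i * 1.234) * x)
  expect_equal(est, est_ph, tolerance = 1e-12)
  # determinism: bit-identical repeat
  expect_identical(est, infer_maps_nn(nf$model, x))
  # pd * theta3 = ||x||2 exactly (formula, not learning)
  xr <- phase_align(x)
  th <- nn_predict(nf$model, xr / sqrt(rowSums(xr^2)))
  expect_equal(est$pd * th[, "theta3"], sqrt(rowSums(Mod(x)^2)))
  # masked voxels are zeroed
  m <- infer_maps_nn(nf$model, x, mask = rep(c(TRUE, FALSE), 5))
  expect_true(all(m$t1_ms[c(2, 4, 6, 8, 10)] == 0))
  expect_true(all(m$pd[c(2, 4, 6, 8, 10)] == 0))
  # zero-signal voxels are zero even inside the mask
  z <- infer_maps_nn(nf$model, matrix(0 + 0i, 2, 10))
  expect_true(all(unlist(z) == 0))
  expect_error(infer_maps_nn(nf$model, x[, 1:5]), "rank")
})

test_that("network and dictionary matching agree on a clean phantom", {
  nf <- nn_fixture()
  cd <- coarse_dict()
  ph <- make_phantom(c(48L, 48L), seed = 21L)
  co <- phantom_coeffs(ph$maps, cd$schedule, cd$basis)
  mask <- as.vector(ph$labels > 0)
  est_nn <- infer_maps_nn(nf$model, co, mask)
  est_dm <- infer_maps_match(cd$dict, co, mask)
  dt1 <- abs(est_nn$t1_ms[mask] - est_dm$t1_ms[mask])
  grid_step <- 100                               # coarse-grid T1 step
  expect_lt(median(dt1), grid_step)
})

test_that("network checkpoints round-trip through JSON", {
  nf <- nn_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  save_nn(nf$model, f)
  m2 <- load_nn(f)
  x <- matrix(runif(30), 3, 10)
  x <- x / sqrt(rowSums(x^2))
  expect_equal(nn_predict(m2, x), nn_predict(nf$model, x), tolerance = 1e-12)
})
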