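test_that("the sampling operator and its adjoint are an exact adjoint pair", {
  fx <- recon_fixture()
  set.seed(9)
  nvox <- prod(fx$shape)
  rank <- fx$basis$rank
  m <- nrow(fx$traj$kpts[[1L]])
  nrep <- length(fx$traj$kpts)
  cc <- matrix(complex(real = rnorm(nvox * rank),
                       imaginary = rnorm(nvox * rank)), nvox, rank)
  y <- array(complex(real = rnorm(m * 2 * nrep),
                     imaginary = rnorm(m * 2 * nrep)), c(m, 2L, nrep))
  Ax <- qtimap:::sense_forward(cc, fx$basis$vectors, fx$traj, fx$cm, fx$shape)
  Aty <- qtimap:::sense_adjoint(y, fx$basis$vectors, fx$traj, fx$cm, fx$shape)
  ip1 <- sum(Ax * Conj(y))
  ip2 <- sum(cc * Conj(Aty))
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-6)
})

test_that("acquisition is linear and consistent at the k-space origin", {
  fx <- recon_fixture()
  zero <- matrix(0 + 0i, prod(fx$shape), fx$basis$rank)
  attr(zero, "dims") <- fx$shape
  ks0 <- simulate_acquisition(zero, fx$basis, fx$traj, noise_sigma = 0)
  expect_true(all(ks0$data == 0))
  ks1 <- simulate_acquisition(fx$coeffs, fx$basis, fx$traj, noise_sigma = 0)
  co2 <- 2 * fx$coeffs
  attr(co2, "dims") <- fx$shape
  ks2 <- simulate_acquisition(co2, fx$basis, fx$traj, noise_sigma = 0)
  expect_equal(ks2$data, 2 * ks1$data)
  # DC sample of a single uniform coil equals the spatial image sum
  traj0 <- fx$traj
  traj0$kpts[[1L]][1L, ] <- 0
  ksdc <- simulate_acquisition(fx$coeffs, fx$basis, traj0, noise_sigma = 0)
  img1 <- as.vector(fx$coeffs %*% fx$basis$vectors[1L, ])
  expect_lt(Mod(ksdc$data[1L, 1L, 1L] - sum(img1)) / Mod(sum(img1)), 1e-6)
})

test_that("zero k-space reconstructs to zero under all methods", {
  fx <- recon_fixture()
  ks <- simulate_acquisition(
    structure(matrix(0 + 0i, prod(fx$shape), fx$basis$rank),
              dims = fx$shape),
    fx$basis, fx$traj, coil_maps = fx$coil_maps, noise_sigma = 0)
  for (m in c("zero_fill", "view_share"))
    expect_true(all(reconstruct(ks, fx$basis, fx$coil_maps, m)$coeffs == 0))
  lr <- reconstruct(ks, fx$basis, fx$coil_maps, "lrtv",
                    options = list(iterations = 3L))
  expect_true(all(Mod(lr$coeffs) < 1e-12))
})

test_that("density-compensated adjoint recovers a fully sampled acquisition", {
  fx <- recon_fixture()
  traj_full <- make_spiral_trajectory(32, samples_per_interleaf = 4096L,
                                      repetitions = 64L, mode = "2d",
                                      density_exponent = 1)
  ks <- simulate_acquisition(fx$coeffs, fx$basis, traj_full,
                             coil_maps = fx$coil_maps, noise_sigma = 0)
  zf <- reconstruct(ks, fx$basis, fx$coil_maps, "zero_fill")
  nrmse <- sqrt(sum(Mod(zf$coeffs - fx$coeffs)^2) / sum(Mod(fx$coeffs)^2))
  expect_lt(nrmse, 0.05)
})

test_that("reconstruction error ranks lrtv <= view-sharing <= zero-fill", {
  fx <- recon_fixture()
  nr <- function(cc) sqrt(sum(Mod(cc[, 1L] - fx$coeffs[, 1L])^2) /
                            sum(Mod(fx$coeffs[, 1L])^2))
  zf <- reconstruct(fx$kspace, fx$basis, fx$coil_maps, "zero_fill")
  vs <- reconstruct(fx$kspace, fx$basis, fx$coil_maps, "view_share",
                    options = list(window = 8L))
  lr <- reconstruct(fx$kspace, fx$basis, fx$coil_maps, "lrtv",
                    options = list(lambda_tv = 0.01, iterations = 25L))
  expect_lte(nr(lr$coeffs), nr(vs$coeffs))
  expect_lte(nr(vs$coeffs), nr(zf$coeffs))
  # the iterative objective never increases
  expect_true(all(diff(lr$objective) <= 1e-9 * max(lr$objective)))
  expect_error(reconstruct(fx$kspace, fx$basis, fx$coil_maps, "nonsense"))
})

test_that("adaptive coil-map estimation recovers smooth synthetic maps", {
  fx <- recon_fixture()
  # coil images = sensitivity * (first-component magnitude image)
  img <- array(Mod(fx$coeffs[, 1L]), fx$shape)
  ci <- array(0 + 0i, c(fx$shape, 2L))
  for (c_i in 1:2) ci[, , c_i] <- fx$coil_maps[, , c_i] * img
  est <- estimate_coil_maps(ci, block = 5L)
  rss <- sqrt(Mod(est$maps[, , 1L])^2 + Mod(est$maps[, , 2L])^2)
  expect_lt(max(abs(rss - 1)), 1e-9)
  sup <- fx$phantom$labels > 0L
  err <- abs(Mod(est$maps[, , 1L])[sup] - Mod(fx$coil_maps[, , 1L])[sup])
  expect_lt(mean(err), 0.05)
  # a single constant coil gives the constant unit map
  one <- array(1 + 0i, c(8L, 8L, 1L))
  est1 <- estimate_coil_maps(one)
  expect_lt(max(Mod(est1$maps - 1)), 1e-9)
})

test_that("phantom -> acquisition -> lrtv -> matching recovers tissue T1", {
  fx <- recon_fixture()
  lr <- reconstruct(fx$kspace, fx$basis, fx$coil_maps, "lrtv",
                    options = list(lambda_tv = 0.01, iterations = 25L))
  mask <- as.vector(fx$phantom$labels > 0L)
  est <- infer_maps_match(fx$dict, lr$coeffs, mask)
  grid_step <- 100
  for (tissue in c("WM", "GM", "edema")) {
    roi <- as.vector(fx$phantom$roi_masks[[tissue]])
    med_est <- median(est$t1_ms[roi])
    med_true <- median(fx$phantom$maps$t1[fx$phantom$roi_masks[[tissue]]])
    expect_lt(abs(med_est - med_true), 2 * grid_step)
  }
})
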