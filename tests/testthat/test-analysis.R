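test_that("ROI statistics report population moments in mask order", {
  m <- qti_maps(array(c(500, 500, 500, 900, 1100, 0), c(6L, 1L)),
                array(c(50, 50, 50, 60, 80, 0), c(6L, 1L)),
                array(rep(1, 6), c(6L, 1L)))
  masks <- list(const = array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), c(6L, 1L)),
                two = array(c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE), c(6L, 1L)))
  tab <- roi_statistics(m, masks)
  expect_equal(tab$name, c("const", "two"))
  expect_equal(tab$n_voxels, c(3L, 2L))
  expect_equal(tab$t1_std[1L], 0)
  expect_equal(tab$t1_mean[2L], 1000)
  expect_equal(tab$t1_std[2L], 100)              # population, not sample, SD
  # pooling two halves reproduces the full-ROI mean exactly
  full <- masks$const | masks$two
  tab_full <- roi_statistics(m, list(all = full))
  pooled <- sum(tab$n_voxels * tab$t1_mean) / sum(tab$n_voxels)
  expect_equal(tab_full$t1_mean, pooled)
  expect_error(roi_statistics(m, list(none = array(FALSE, c(6L, 1L)))),
               "none")
  expect_error(roi_statistics(m, list(bad = array(TRUE, c(3L, 2L)))), "bad")
})

test_that("a one-component fit reduces to the sample moments", {
  set.seed(2)
  x <- cbind(rnorm(500, 1500, 200), rnorm(500, 90, 30))
  g <- fit_t1t2_gmm(x, k = 1L, seed = 3L)
  expect_equal(as.vector(g$means), colMeans(x), tolerance = 1e-6)
  expect_equal(g$covs[, , 1L], crossprod(sweep(x, 2L, colMeans(x))) / 500,
               tolerance = 1e-5)
  expect_equal(g$weights, 1)
})

test_that("well-separated clusters are recovered within three standard errors", {
  t3 <- table3()
  set.seed(40)
  n <- 2000L
  draw <- function(row) cbind(rnorm(n, t3[row, "t1_mean"], t3[row, "t1_std"]),
                              rnorm(n, t3[row, "t2_mean"], t3[row, "t2_std"]))
  x <- rbind(draw("core_I"), draw("core_II"))
  g <- fit_t1t2_gmm(x, k = 2L, seed = 5L)
  # component ordering invariant: component 2 above component 1 in T1 and T2
  expect_gt(g$means[2L, 1L], g$means[1L, 1L])
  expect_gt(g$means[2L, 2L], g$means[1L, 2L])
  for (j in 1:2) {
    row <- c("core_I", "core_II")[j]
    expect_lt(abs(g$means[j, 1L] - t3[row, "t1_mean"]),
              3 * t3[row, "t1_std"] / sqrt(n))
    expect_lt(abs(g$means[j, 2L] - t3[row, "t2_mean"]),
              3 * t3[row, "t2_std"] / sqrt(n))
  }
  # permutation invariance of the fit
  perm <- sample(nrow(x))
  g2 <- fit_t1t2_gmm(x[perm, ], k = 2L, seed = 5L)
  expect_equal(g2$means, g$means, tolerance = 1e-8)
  expect_equal(g2$weights, g$weights, tolerance = 1e-8)
  expect_error(fit_t1t2_gmm(x[1:15, ], k = 2L), "10 samples")
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  t3 <- table3()
  set.seed(41)
  n <- 1000L
  x <- rbind(cbind(rnorm(n, t3["core_I", "t1_mean"], t3["core_I", "t1_std"]),
                   rnorm(n, t3["core_I", "t2_mean"], t3["core_I", "t2_std"])),
             cbind(rnorm(n, t3["core_II", "t1_mean"], t3["core_II", "t1_std"]),
                   rnorm(n, t3["core_II", "t2_mean"], t3["core_II", "t2_std"])))
  g <- fit_t1t2_gmm(x, k = 2L, seed = 6L)
  ref <- mclust::Mclust(x, G = 2L, modelNames = "VVV", verbose = FALSE)
  ref_means <- t(ref$parameters$mean)
  ord <- order(ref_means[, 1L])
  expect_equal(g$means, ref_means[ord, , drop = FALSE], tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(g$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("voxel classification back-projects the mixture deterministically", {
  ph <- make_phantom(c(64L, 64L), seed = 30L)
  core <- ph$roi_masks$necrotic_nonenhancing
  x <- cbind(ph$maps$t1[core], ph$maps$t2[core])
  g <- fit_t1t2_gmm(x, k = 2L, seed = 7L)
  lab <- classify_voxels(g, ph$maps, core)
  expect_true(all(lab[core] %in% 1:2))
  expect_true(all(lab[!core] == 0L))
  expect_identical(lab, classify_voxels(g, ph$maps, core))
  # a voxel at a component mean belongs to that component
  m2 <- qti_maps(array(g$means[2L, 1L], c(1L, 1L)),
                 array(g$means[2L, 2L], c(1L, 1L)),
                 array(1, c(1L, 1L)))
  expect_equal(as.integer(classify_voxels(g, m2, array(TRUE, c(1L, 1L)))), 2L)
  # against the phantom's ground truth the two classes separate well
  truth <- ifelse(ph$labels[core] == 7L, 2L, 1L)
  acc <- mean(lab[core] == truth)
  expect_gt(acc, 0.9)
})

test_that("mixture models round-trip through JSON", {
  set.seed(11)
  x <- cbind(rnorm(400, 1500, 150), rnorm(400, 100, 20))
  g <- fit_t1t2_gmm(x, k = 2L, seed = 8L)
  f <- withr::local_tempfile(fileext = ".json")
  save_gmm(g, f)
  g2 <- load_gmm(f)
  expect_equal(g2$means, g$means)
  expect_equal(g2$covs, g$covs)
  expect_equal(g2$weights, g$weights)
  p1 <- gmm_posterior(g, x[1:5, ])
  expect_equal(gmm_posterior(g2, x[1:5, ]), p1)
})
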