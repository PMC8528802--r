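test_that("the reference tissue table is ordered and physically sensible", {
  t3 <- table3()
  expect_equal(t3["WM", "t1_mean"], 903)
  expect_equal(t3["WM", "t2_mean"], 46)
  expect_equal(t3["GM", "t1_mean"], 1353)
  # the fluid-like core II sits above the solid-like core I in both T1 and T2
  expect_gt(t3["core_II", "t1_mean"], t3["core_I", "t1_mean"])
  expect_gt(t3["core_II", "t2_mean"], t3["core_I", "t2_mean"])
  expect_true(all(t3$t1_std >= 0) && all(t3$t2_std >= 0))
  expect_equal(nrow(t3), 7L)
})

test_that("labels partition the volume and the draw is seeded", {
  ph <- make_phantom(c(48L, 48L), seed = 5L)
  expect_true(all(ph$labels %in% 0:7))
  # every voxel has exactly one label by construction; masks tile the labels
  lab_from_masks <- Reduce(`+`, lapply(ph$tissues$label, function(l)
    l * (ph$roi_masks[[ph$tissues$name[ph$tissues$label == l]]])))
  expect_equal(array(as.integer(lab_from_masks), dim(ph$labels)), ph$labels)
  ph2 <- make_phantom(c(48L, 48L), seed = 5L)
  expect_identical(ph$maps$t1, ph2$maps$t1)
  expect_identical(ph$labels, ph2$labels)
  ph3 <- make_phantom(c(48L, 48L), seed = 6L)
  expect_false(identical(ph$maps$t1, ph3$maps$t1))
})

test_that("all ROI masks are non-empty and nested in their tissue", {
  ph <- make_phantom(c(64L, 64L), seed = 1L)
  for (nm in ph$tissues$name) {
    expect_gt(sum(ph$roi_masks[[nm]]), 0L)
    expect_true(all(ph$labels[ph$roi_masks[[nm]]] ==
                      ph$tissues$label[ph$tissues$name == nm]))
  }
  expect_equal(ph$roi_masks$necrotic_nonenhancing,
               ph$roi_masks$core_I | ph$roi_masks$core_II)
})

test_that("drawn parameters stay inside the dictionary ranges", {
  ph <- make_phantom(c(48L, 48L), seed = 2L)
  fg <- ph$labels > 0L
  expect_true(all(ph$maps$t1[fg] >= 10 & ph$maps$t1[fg] <= 5000))
  expect_true(all(ph$maps$t2[fg] >= 10 & ph$maps$t2[fg] <= 2000))
  expect_true(all(ph$maps$pd[fg] >= 0))
  expect_true(all(ph$maps$t1[!fg] == 0))
})

test_that("per-tissue sample means respect CLT bounds around the configured values", {
  ph <- make_phantom(c(96L, 96L), seed = 9L)
  t3 <- table3()
  wm <- ph$roi_masks$WM
  n <- sum(wm)
  expect_gte(n, 1000L)
  expect_lt(abs(mean(ph$maps$t1[wm]) - t3["WM", "t1_mean"]),
            3 * t3["WM", "t1_std"] / sqrt(n))
  expect_lt(abs(mean(ph$maps$t2[wm]) - t3["WM", "t2_mean"]),
            3 * t3["WM", "t2_std"] / sqrt(n))
  gm <- ph$roi_masks$GM
  expect_lt(abs(mean(ph$maps$t1[gm]) - t3["GM", "t1_mean"]),
            3 * t3["GM", "t1_std"] / sqrt(sum(gm)))
})

test_that("an oversized tumor complex is rejected", {
  expect_error(make_phantom(c(32L, 32L),
                            geometry = list(core_radius = 0.3)),
               "does not fit")
})

test_that("phantoms round-trip through NIfTI export and import", {
  ph <- make_phantom(c(32L, 32L), seed = 13L)
  dir <- withr::local_tempdir()
  export_phantom(ph, dir)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$seed, 13L)
  ph2 <- import_phantom(dir)
  expect_equal(ph2$labels, ph$labels)
  expect_equal(ph2$maps$t1, ph$maps$t1, tolerance = 1e-6)
  expect_equal(ph2$roi_masks$WM, unname(ph$roi_masks$WM), ignore_attr = TRUE)
  expect_equal(ph2$maps$voxel_size_mm, 1.125, tolerance = 1e-6)
  # missing files are reported by name
  unlink(file.path(dir, "t2.nii"))
  expect_error(import_phantom(dir), "t2.nii")
})
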