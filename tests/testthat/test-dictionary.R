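test_that("the native parameter grid has the stated steps and cardinality", {
  g <- build_grid()
  expect_length(g$t1_values_ms, 230L)
  expect_length(g$t2_values_ms, 229L)
  expect_true(all(seq(10, 2000, by = 10) %in% g$t1_values_ms))
  expect_true(all(seq(2100, 5000, by = 100) %in% g$t1_values_ms))
  expect_true(all(seq(10, 300, by = 5) %in% g$t2_values_ms))
  expect_true(all(seq(310, 2000, by = 10) %in% g$t2_values_ms))
  atoms <- grid_atoms(g)
  expect_equal(nrow(atoms), 230L * 229L)          # 52,670 combinations
  # row-major ordering: T1 outer, T2 inner
  expect_equal(atoms$t1_ms[1:229], rep(10, 229))
  expect_equal(atoms$t2_ms[1:2], c(10, 15))
  g2 <- build_grid(exclude_t2_gt_t1 = TRUE)
  expect_true(all(with(grid_atoms(g2), t2_ms <= t1_ms)))
})

test_that("dictionary atoms are unit norm with positive stored norms", {
  cd <- coarse_dict()
  norms <- sqrt(rowSums(Mod(cd$dict$atoms)^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  expect_true(all(cd$dict$atom_norms > 0))
  expect_equal(nrow(cd$dict$atoms), 30L * 15L)
})

test_that("the temporal basis is orthonormal and residuals shrink with rank", {
  cd <- coarse_dict()
  v <- cd$basis$vectors
  expect_equal(ncol(v), 10L)
  gram <- Conj(t(v)) %*% v
  expect_lt(max(Mod(gram - diag(10))), 1e-9)
  expect_true(all(diff(cd$basis$singular_values) <= 1e-9))
  # mean relative projection residual decreases from rank 5 to rank 10
  a <- dictionary_atoms(cd$dict)
  res_at <- function(r) {
    vr <- v[, seq_len(r), drop = FALSE]
    proj <- (a %*% Conj(vr)) %*% t(vr)
    mean(sqrt(rowSums(Mod(a - proj)^2)))
  }
  expect_lt(res_at(10L), res_at(5L))
})

test_that("compression is the orthonormal projection it claims to be", {
  cd <- coarse_dict()
  v <- cd$basis$vectors
  for (k in c(1L, 4L)) {
    ck <- compress_signal(as.complex(v[, k]), cd$basis)
    ek <- rep(0 + 0i, 10); ek[k] <- 1
    expect_lt(max(Mod(ck - ek)), 1e-9)
  }
  expect_true(all(compress_signal(rep(0 + 0i, 100), cd$basis) == 0))
  # project-then-compress idempotence and the norm contraction
  x <- simulate_signal(qti_tissue(1234, 77), cd$schedule)
  cx <- compress_signal(x, cd$basis)
  expect_lt(max(Mod(compress_signal(expand_signal(cx, cd$basis),
                                    cd$basis) - cx)), 1e-9)
  expect_lte(sqrt(sum(Mod(cx)^2)), sqrt(sum(Mod(x)^2)) + 1e-9)
  expect_error(compress_signal(x[-1], cd$basis), "length")
})

test_that("every atom self-matches with correlation 1 and unit proton density", {
  cd <- coarse_dict()
  d <- cd$dict
  n <- nrow(d$params)
  clean <- d$compressed * d$catom_norms      # compressed unit-PD signals
  m <- match_volume(clean, d)
  expect_equal(m$index, seq_len(n))
  expect_lt(max(abs(m$correlation - 1)), 1e-6)
  expect_lt(max(abs(m$pd - 1)), 1e-6)
  expect_equal(m$t1_ms, d$params$t1_ms)
  expect_equal(m$t2_ms, d$params$t2_ms)
})

test_that("matching is phase invariant and linear in scale", {
  cd <- coarse_dict()
  d <- cd$dict
  x <- compress_signal(simulate_signal(qti_tissue(1500, 90), cd$schedule),
                       cd$basis)
  base <- match_signal(x, d)
  for (phi in c(0.3, 2.1, -1.2)) {
    m <- match_signal(exp(1i * phi) * x, d)
    expect_equal(m$t1_ms, base$t1_ms)
    expect_equal(m$t2_ms, base$t2_ms)
    expect_equal(m$pd, base$pd, tolerance = 1e-9)
  }
  for (s in c(0.5, 3)) {
    m <- match_signal(s * x, d)
    expect_equal(m$pd, s * base$pd, tolerance = 1e-6)
  }
})

test_that("zero-norm inputs are flagged with zero proton density", {
  cd <- coarse_dict()
  m <- match_signal(rep(0 + 0i, 10L), cd$dict)
  expect_true(m$flagged)
  expect_equal(m$pd, 0)
  expect_true(is.na(m$t1_ms) && is.na(m$t2_ms))
})

test_that("compressed matching agrees with brute-force time-domain matching", {
  cd <- coarse_dict()
  d <- cd$dict
  # 10 x 10 sub-grid of off-dictionary signals, matched both ways
  set.seed(33)
  t1s <- runif(10, 150, 2900)
  t2s <- runif(10, 25, 290)
  pairs <- expand.grid(t1_ms = t1s, t2_ms = t2s)
  sig <- simulate_batch(pairs, cd$schedule)
  atoms_c <- dictionary_atoms(d)
  for (i in seq_len(nrow(pairs))) {
    bf <- brute_force_match(sig[i, ], atoms_c, d$params)
    cm <- match_signal(compress_signal(sig[i, ], cd$basis), d)
    expect_equal(cm$index, bf$index)
  }
})

test_that("dictionary containers round-trip through disk", {
  cd <- coarse_dict()
  f <- withr::local_tempfile(fileext = ".rds")
  save_dictionary(cd$dict, f)
  expect_true(file.exists(sub("\\.rds$", "_grid.csv", f)))
  d2 <- load_dictionary(f)
  expect_equal(d2$atoms, cd$dict$atoms)
  expect_equal(d2$atom_norms, cd$dict$atom_norms)
  expect_equal(d2$basis$vectors, cd$basis$vectors)
  expect_error(load_dictionary(file.path(tempdir(), "none.rds")), "not found")
})
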