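test_that("signal is exactly linear in proton density", {
  sched <- short_schedule(120L)
  t0 <- qti_tissue(1000, 100, 0)
  expect_true(all(simulate_signal(t0, sched) == 0 + 0i))
  s1 <- simulate_signal(qti_tissue(800, 60, 1), sched)
  s2 <- simulate_signal(qti_tissue(800, 60, 2), sched)
  expect_equal(s2, 2 * s1)
})

test_that("batch simulation matches single calls and is deterministic", {
  sched <- short_schedule(80L)
  tissues <- list(qti_tissue(900, 50), qti_tissue(1400, 80),
                  qti_tissue(3000, 250, pd = 0.7))
  b1 <- simulate_batch(tissues, sched)
  expect_equal(dim(b1), c(3L, 80L))
  for (i in 1:3)
    expect_identical(b1[i, ], simulate_signal(tissues[[i]], sched))
  expect_identical(b1, simulate_batch(tissues, sched))
})

test_that("EPG agrees with the isochromat-ensemble oracle across the grid range", {
  sched <- default_schedule()
  # the stated reference point plus seeded pairs spanning the grid range
  set.seed(101)
  t1s <- c(1000, exp(runif(10, log(100), log(5000))))
  t2s <- c(100, exp(runif(10, log(20), log(2000))))
  t2s <- pmin(t2s, t1s)                # physically plausible pairs
  epg <- simulate_batch(data.frame(t1_ms = t1s, t2_ms = t2s), sched)
  for (i in seq_along(t1s)) {
    oracle <- iso_simulate(t1s[i], t2s[i], 1, sched, nspins = 1000L)
    expect_lt(rel_l2(epg[i, ], oracle), 1e-3)
  }
})

test_that("small constant flips show monotone inversion recovery", {
  sched <- qti_schedule(rep(5, 300), tr_ms = 7.8, te_ms = 1e-3, ti_ms = 18)
  for (t1 in c(500, 1000, 2000)) {
    s <- suppressMessages(simulate_signal(qti_tissue(t1, 80), sched))
    # align the global phase on the last (recovered) sample so the curve runs
    # from negative (inverted) towards the positive plateau
    ph <- s[length(s)]
    sr <- Re(s * Conj(ph) / Mod(ph))
    expect_true(all(diff(sr[1:50]) >= -1e-12))
  }
})

test_that("truncating the configuration states is stable beyond the default order", {
  sched <- default_schedule()
  tis <- qti_tissue(1000, 100)
  s100 <- suppressMessages(simulate_signal(tis, sched, max_epg_order = 100L))
  s200 <- suppressMessages(simulate_signal(tis, sched, max_epg_order = 200L))
  expect_lt(rel_l2(s100, s200), 1e-6)
})

test_that("invalid tissue parameters are rejected with the offending index", {
  sched <- short_schedule(20L)
  expect_error(simulate_batch(data.frame(t1_ms = c(100, -1),
                                         t2_ms = c(50, 50)), sched),
               "index 2")
  expect_error(qti_tissue(NA, 100))
  expect_error(simulate_signal(qti_tissue(100, 50), sched,
                               max_epg_order = 1L), "max_epg_order")
})

test_that("signals export to CSV with real and imaginary parts", {
  s <- simulate_signal(qti_tissue(900, 60), short_schedule(30L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 30L)
  expect_equal(complex(real = tab$real, imaginary = tab$imag), unname(s))
})
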