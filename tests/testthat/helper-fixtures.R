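# Shared fixtures, built once per test run and memoized. Sizes are desk-scale
# (coarse grids, decimated schedules, 32^2 images) so the whole suite runs in
# minutes; every property they exercise is scale-free.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default timing with a ramp decimated to n repetitions
short_schedule <- function(n = 100L) {
  fa <- default_schedule()$flip_angles[round(seq(1, 880, length.out = n))]
  qti_schedule(fa, tr_ms = 7.8, te_ms = 1.8, ti_ms = 18)
}

# coarse test dictionary: 30 x 15 grid, 100 repetitions, rank 10
coarse_dict <- function() memo("coarse_dict", function() {
  sched <- short_schedule(100L)
  grid <- build_grid(t1_values_ms = seq(100, 3000, by = 100),
                     t2_values_ms = seq(20, 300, by = 20))
  dict <- build_dictionary(grid, sched)
  basis <- compute_subspace(dict, rank = 10L)
  dict <- compress_dictionary(dict, basis)
  list(schedule = sched, dict = dict, basis = basis)
})

# seeded 2D acquisition fixture: band-limited phantom, 2 coils, 64 reps
recon_fixture <- function() memo("recon_fixture", function() {
  shape <- c(32L, 32L)
  sched <- short_schedule(64L)
  grid <- build_grid(t1_values_ms = seq(100, 3000, by = 100),
                     t2_values_ms = seq(20, 300, by = 20))
  dict <- build_dictionary(grid, sched)
  basis <- compute_subspace(dict, rank = 6L)
  dict <- compress_dictionary(dict, basis)
  phantom <- make_phantom(shape, seed = 3L, smooth_sigma = 1)
  coeffs <- phantom_coeffs(phantom$maps, sched, basis)
  coil_maps <- make_coil_maps(shape, n_coils = 2L)
  cm <- matrix(coil_maps, nrow = prod(shape))
  traj <- make_spiral_trajectory(32, samples_per_interleaf = 256L,
                                 repetitions = 64L, mode = "2d")
  y0 <- qtimap:::sense_forward(coeffs, basis$vectors, traj, cm, shape)
  noisy <- simulate_acquisition(coeffs, basis, traj, coil_maps = coil_maps,
                                noise_sigma = 0.02 * stats::sd(Mod(y0)),
                                seed = 7L)
  list(shape = shape, schedule = sched, dict = dict, basis = basis,
       phantom = phantom, coeffs = coeffs, coil_maps = coil_maps,
       cm = cm, traj = traj, kspace = noisy)
})

# seeded trained network on the coarse dictionary (noiseless training set)
nn_fixture <- function() memo("nn_fixture", function() {
  cd <- coarse_dict()
  cfg <- training_config(noise_sigma = 0, max_epochs = 400L,
                         learning_rate = 0.1, dropout = 0,
                         batch_size = 64L, momentum = 0.9, seed = 11L)
  spec <- network_spec(input_rank = 10L)
  dat <- make_training_set(cd$dict, cfg, spec)
  model <- train_nn(spec, dat, cfg)
  list(model = model, data = dat, cfg = cfg, spec = spec)
})

# acceptance-scale dictionary: full T1 grid, T2 up to 300 ms at native step
# (both Table-3 tissues checked against it have T2 well below 300 ms)
acceptance_dict <- function() memo("acceptance_dict", function() {
  sched <- default_schedule()
  grid <- build_grid(t2_values_ms = seq(10, 300, by = 5))
  dict <- build_dictionary(grid, sched)
  basis <- compute_subspace(dict, rank = 10L)
  dict <- compress_dictionary(dict, basis)
  list(schedule = sched, dict = dict, basis = basis)
})

table3 <- function() {
  t <- default_tissues()
  rownames(t) <- t$name
  t
}
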