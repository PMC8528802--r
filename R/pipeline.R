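#' Default run configuration for the end-to-end pipeline
#'
#' A desk-scale 2D demonstration configuration: coarse dictionary grid,
#' 64x64 phantom, 200-repetition schedule, 4 coils, undersampled spiral
#' acquisition and LRTV reconstruction with dictionary-matching inference.
#' Every stochastic stage carries an explicit seed.
#'
#' @param seed global seed; the per-stage seeds are derived from it.
#' @return nested named list (the run configuration).
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    schedule = list(source = "default", repetitions = 200L),
    dictionary = list(
      t1_values_ms = c(seq(100, 2000, by = 50), seq(2100, 5000, by = 100)),
      t2_values_ms = c(seq(10, 300, by = 10), seq(320, 2000, by = 40)),
      max_epg_order = 100L),
    subspace = list(rank = 10L),
    phantom = list(shape = c(64L, 64L), seed = seed + 1L,
                   voxel_size_mm = 1.125),
    acquisition = list(samples_per_interleaf = 1024L, interleaves = 1L,
                       n_coils = 4L, noise_sigma_rel = 0.02,
                       seed = seed + 2L),
    reconstruction = list(method = "lrtv",
                          options = list(lambda_tv = 1e-3,
                                         iterations = 15L)),
    inference = list(mode = "match",
                     nn = list(noise_sigma = 0.02, max_epochs = 150L,
                               learning_rate = 0.05, dropout = 0,
                               batch_size = 256L, seed = seed + 3L)),
    synthesis = list(contrasts = c("t1w", "t2w", "flair")),
    analysis = list(gmm_seed = seed + 4L),
    stages = c("phantom", "dictionary", "acquire", "recon", "infer",
               "synthesize", "analyze"))
}

#' Validate a run configuration
#'
#' Returns a character vector of problems (empty when [qti_run()] would pass
#' its precondition checks); never mutates state.
#'
#' @param config a configuration list as from [default_config()] (possibly
#'   with a `schedule$path` pointing at a flip-angle CSV).
#' @return character vector of problems, `character(0)` if valid.
#' @export
qti_validate <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$seed)) add("missing global seed")
  if (!is.null(config$schedule$source) &&
      identical(config$schedule$source, "file")) {
    if (is.null(config$schedule$path))
      add("schedule stage: source 'file' without a path")
    else if (!file.exists(config$schedule$path))
      add(paste0("schedule stage: dangling path ", config$schedule$path))
  }
  if ("phantom" %in% config$stages && is.null(config$phantom$seed))
    add("phantom stage: missing seed")
  if ("acquire" %in% config$stages && is.null(config$acquisition$seed))
    add("acquire stage: missing seed")
  if ("infer" %in% config$stages &&
      identical(config$inference$mode, "nn") &&
      is.null(config$inference$nn$seed))
    add("infer stage (nn): missing seed")
  if (!is.null(config$reconstruction$method) &&
      !config$reconstruction$method %in% c("zero_fill", "view_share", "lrtv"))
    add(paste0("recon stage: unknown method ", config$reconstruction$method))
  if (!is.null(config$subspace$rank) && config$subspace$rank < 1)
    add("subspace rank must be >= 1")
  problems
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — phantom, dictionary + subspace,
#' acquisition, reconstruction, inference (dictionary matching or neural
#' network), contrast synthesis, ROI analysis with T1-T2 mixture
#' subclassification — and writes all products (NIfTI volumes, CSV tables,
#' JSON models) plus a `manifest.json` with the configuration, seeds, package
#' version, per-stage wall times and per-product checksums into `out_dir`.
#' Rerunning the same configuration reproduces every product bit-identically.
#'
#' @param config configuration list ([default_config()] is the template).
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
qti_run <- function(config, out_dir, verbose = FALSE) {
  problems <- qti_validate(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- list()
  products <- character(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    on.exit(timings[[stage]] <<- proc.time()[["elapsed"]] - t0)
    tryCatch(expr, error = function(e) {
      writeLines("FAILED", file.path(out_dir, paste0("FAILED_", stage)))
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # schedule (always needed)
  schedule <- if (identical(config$schedule$source, "file"))
    load_schedule(config$schedule$path)
  else default_schedule()
  nrep <- config$schedule$repetitions
  if (!is.null(nrep) && nrep < length(schedule$flip_angles))
    schedule <- qti_schedule(schedule$flip_angles[seq_len(nrep)],
                             schedule$tr_ms, schedule$te_ms, schedule$ti_ms,
                             schedule$inversion_flip_deg)
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))
  products <- c(products, "schedule.csv")

  phantom <- NULL
  if ("phantom" %in% stages) {
    say("stage phantom")
    tick("phantom", {
      phantom <- make_phantom(shape = config$phantom$shape,
                              seed = config$phantom$seed,
                              voxel_size_mm = config$phantom$voxel_size_mm %||% 1.125)
      export_phantom(phantom, file.path(out_dir, "phantom"))
    })
    products <- c(products, "phantom/manifest.json")
  }

  dict <- NULL; basis <- NULL
  if ("dictionary" %in% stages) {
    say("stage dictionary")
    tick("dictionary", {
      grid <- build_grid(config$dictionary$t1_values_ms,
                         config$dictionary$t2_values_ms)
      dict <- build_dictionary(grid, schedule,
                               max_epg_order = config$dictionary$max_epg_order %||% 100L)
      basis <- compute_subspace(dict, rank = config$subspace$rank %||% 10L)
      dict <- compress_dictionary(dict, basis)
      save_dictionary(dict, file.path(out_dir, "dictionary.rds"))
    })
    products <- c(products, "dictionary.rds", "dictionary_grid.csv")
  }

  kspace <- NULL; coil_maps <- NULL; coeffs_true <- NULL
  if ("acquire" %in% stages) {
    if (is.null(phantom) || is.null(basis))
      stop("acquire stage needs the phantom and dictionary stages")
    say("stage acquire")
    tick("acquire", {
      dims <- dim(phantom$labels)
      acq <- config$acquisition
      traj <- make_spiral_trajectory(
        matrix_size = dims[1L], fov_mm = dims[1L] * phantom$maps$voxel_size_mm,
        interleaves = acq$interleaves %||% 1L,
        samples_per_interleaf = acq$samples_per_interleaf %||% 1024L,
        repetitions = length(schedule$flip_angles),
        mode = if (length(dims) == 2L) "2d" else "3d")
      coil_maps <- make_coil_maps(dims, n_coils = acq$n_coils %||% 4L)
      coeffs_true <- phantom_coeffs(phantom$maps, schedule, basis)
      y0 <- sense_forward(coeffs_true, basis$vectors, traj,
                          matrix(coil_maps, nrow = prod(dims)), dims)
      sigma <- (acq$noise_sigma_rel %||% 0) * stats::sd(Mod(y0))
      kspace <- simulate_acquisition(coeffs_true, basis, traj,
                                     coil_maps = coil_maps,
                                     noise_sigma = sigma,
                                     seed = acq$seed)
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
      saveRDS(kspace, file.path(out_dir, "kspace.rds"))
    })
    products <- c(products, "trajectory.csv", "kspace.rds")
  }

  recon <- NULL
  if ("recon" %in% stages) {
    if (is.null(kspace)) stop("recon stage needs the acquire stage")
    say("stage recon (%s)", config$reconstruction$method)
    tick("recon", {
      recon <- reconstruct(kspace, basis, coil_maps,
                           method = config$reconstruction$method,
                           options = config$reconstruction$options %||% list())
      saveRDS(recon, file.path(out_dir, "svd_images.rds"))
    })
    products <- c(products, "svd_images.rds")
  }

  maps <- NULL
  if ("infer" %in% stages) {
    if (is.null(recon) || is.null(dict))
      stop("infer stage needs the recon and dictionary stages")
    say("stage infer (%s)", config$inference$mode)
    tick("infer", {
      mask <- as.vector(phantom$labels > 0L)
      vs <- phantom$maps$voxel_size_mm
      if (identical(config$inference$mode, "nn")) {
        nncfg <- config$inference$nn
        cfg <- training_config(noise_sigma = nncfg$noise_sigma %||% 0.02,
                               max_epochs = nncfg$max_epochs %||% 150L,
                               learning_rate = nncfg$learning_rate %||% 0.05,
                               dropout = nncfg$dropout %||% 0,
                               batch_size = nncfg$batch_size %||% 256L,
                               seed = nncfg$seed)
        spec <- network_spec(input_rank = basis$rank)
        dat <- make_training_set(dict, cfg, spec)
        model <- train_nn(spec, dat, cfg)
        save_nn(model, file.path(out_dir, "nn_model.json"))
        utils::write.csv(model$history,
                         file.path(out_dir, "nn_history.csv"),
                         row.names = FALSE)
        maps <- infer_maps_nn(model, recon$coeffs, mask,
                              dims = recon$dims, voxel_size_mm = vs)
      } else {
        maps <- infer_maps_match(dict, recon$coeffs, mask,
                                 dims = recon$dims, voxel_size_mm = vs)
      }
      write_maps(maps, file.path(out_dir, "maps"))
    })
    products <- c(products, "maps/t1.nii", "maps/t2.nii",
                  "maps/pd.nii")
  }

  if ("synthesize" %in% stages) {
    if (is.null(maps)) stop("synthesize stage needs the infer stage")
    say("stage synthesize")
    tick("synthesize", {
      specs <- default_contrasts()[config$synthesis$contrasts]
      for (nm in names(specs)) {
        img <- synthesize(maps, specs[[nm]])
        write_volume(img, file.path(out_dir, paste0("synthetic_", nm, ".nii")),
                     maps$voxel_size_mm)
        products <- c(products, paste0("synthetic_", nm, ".nii"))
      }
    })
  }

  if ("analyze" %in% stages) {
    if (is.null(maps) || is.null(phantom))
      stop("analyze stage needs the infer and phantom stages")
    say("stage analyze")
    tick("analyze", {
      roi_order <- c("enhancing", "core_I", "core_II", "edema", "WM", "GM")
      stats_tab <- roi_statistics(maps, phantom$roi_masks[roi_order])
      utils::write.csv(stats_tab, file.path(out_dir, "roi_statistics.csv"),
                       row.names = FALSE)
      core <- phantom$roi_masks$necrotic_nonenhancing
      s <- cbind(maps$t1[core], maps$t2[core])
      gmm <- fit_t1t2_gmm(s, k = 2L, seed = config$analysis$gmm_seed %||% 1L)
      save_gmm(gmm, file.path(out_dir, "gmm_model.json"))
      labels <- classify_voxels(gmm, maps, core)
      write_volume(labels, file.path(out_dir, "core_subclasses.nii"),
                   maps$voxel_size_mm)
      products <- c(products, "roi_statistics.csv", "gmm_model.json",
                    "core_subclasses.nii")
    })
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  checksums <- vapply(products, function(p) {
    f <- file.path(out_dir, p)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("qtimap")),
    r_version = as.character(getRversion()),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stage_seconds = timings,
    products = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
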