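#' Network architecture for voxelwise parameter inference
#'
#' The compact multi-path architecture: the phase-aligned, L2-normalized
#' subspace signal feeds three separate pathways (one per output, T1, T2 and
#' the PD-related scale theta3), each a fully connected stack of three
#' ReLU-activated hidden layers with 200, 100 and 1 node.
#'
#' @param input_rank number of subspace components (default 10).
#' @param hidden_widths widths of the three layers per pathway.
#' @param input_encoding `"real"` keeps only the real parts after phase
#'   alignment (length = rank); `"realimag"` concatenates real and imaginary
#'   parts (length = 2 * rank).
#' @return object of class `qti_nnspec`.
#' @export
network_spec <- function(input_rank = 10L, hidden_widths = c(200L, 100L, 1L),
                         input_encoding = c("real", "realimag")) {
  input_encoding <- match.arg(input_encoding)
  stopifnot(length(hidden_widths) == 3L, hidden_widths[3L] == 1L,
            input_rank >= 1L)
  structure(list(input_rank = as.integer(input_rank),
                 pathways = 3L,
                 hidden_widths = as.integer(hidden_widths),
                 input_encoding = input_encoding),
            class = "qti_nnspec")
}

#' Training configuration
#'
#' @param noise_sigma standard deviation of the white complex Gaussian noise
#'   added to the training signals, expressed as a fraction of the mean atom
#'   norm (total expected noise energy, spread over the time series); default
#'   0.02.
#' @param split_fraction training share of the atom set (default 0.8).
#' @param max_epochs maximum training epochs (default 1000).
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param dropout drop probability in the hidden layers during training
#'   (default 0.8, taken literally as the drop probability).
#' @param batch_size minibatch size (default 256).
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param seed RNG seed for the split, noise, init and shuffling.
#' @return object of class `qti_traincfg`.
#' @export
training_config <- function(noise_sigma = 0.02, split_fraction = 0.8,
                            max_epochs = 1000L, learning_rate = 1e-4,
                            dropout = 0.8, batch_size = 256L,
                            momentum = 0, seed = 1L) {
  stopifnot(noise_sigma >= 0, split_fraction > 0, split_fraction < 1,
            max_epochs >= 1, learning_rate > 0, dropout >= 0, dropout < 1,
            batch_size >= 1, momentum >= 0, momentum < 1)
  structure(list(noise_sigma = noise_sigma, split_fraction = split_fraction,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, dropout = dropout,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "qti_traincfg")
}

#' Phase-align a complex subspace signal
#'
#' Multiplies the signal by the unit conjugate phase of its first coefficient,
#' removing the arbitrary global acquisition phase, and returns the requested
#' real encoding. The first returned coefficient is always >= 0; a zero input
#' returns a zero vector flagged with `attr(, "flagged")`.
#'
#' @param x complex vector, or a complex matrix with one signal per row.
#' @param encoding `"real"` or `"realimag"` (see [network_spec()]).
#' @return real vector (or matrix, signals x encoded length).
#' @export
phase_align <- function(x, encoding = c("real", "realimag")) {
  encoding <- match.arg(encoding)
  if (!is.matrix(x)) {
    out <- phase_align(matrix(x, nrow = 1L), encoding)
    res <- out[1L, ]
    attr(res, "flagged") <- attr(out, "flagged")
    return(res)
  }
  first <- x[, 1L]
  a <- Mod(first)
  ph <- ifelse(a > 0, Conj(first) / a, 1 + 0i)
  y <- x * ph
  out <- if (encoding == "real") Re(y) else cbind(Re(y), Im(y))
  attr(out, "flagged") <- a <= 0
  out
}

#' Build the training and validation sets from a dictionary
#'
#' Adds white complex Gaussian noise to the compressed unit-PD signals (the
#' orthonormal projection of time-domain white noise is again white in the
#' coefficients), phase-aligns and L2-normalizes the inputs, and pairs them
#' with targets (T1, T2, theta3), where theta3 is the compressed unit-PD
#' signal norm, so that PD = ||x||2 / theta3 holds exactly on clean atoms.
#' The split is a seeded random partition of the atoms into disjoint train
#' and validation sets with sizes within one of the requested fractions.
#'
#' @param dict a compressed dictionary ([compress_dictionary()]).
#' @param cfg a [training_config()].
#' @param spec a [network_spec()] (for the input encoding).
#' @return list with `train` and `validation`, each holding `x` (real input
#'   matrix), `y` (targets, columns t1_ms/t2_ms/theta3) and `index` (atom
#'   indices).
#' @export
make_training_set <- function(dict, cfg, spec = network_spec(rank_of(dict))) {
  stopifnot(inherits(dict, "qti_dictionary"), inherits(cfg, "qti_traincfg"))
  if (is.null(dict$compressed)) stop("dictionary must be compressed first")
  n <- nrow(dict$compressed)
  nrep <- ncol(dict$atoms)
  set.seed(cfg$seed)
  ntrain <- round(cfg$split_fraction * n)
  perm <- sample.int(n)
  tr_idx <- sort(perm[seq_len(ntrain)])
  va_idx <- sort(perm[-seq_len(ntrain)])

  # unit-PD compressed signals + complex white noise; per-coefficient std is
  # chosen so the expected total (time-domain) noise norm is
  # noise_sigma * mean atom norm
  clean <- dict$compressed * dict$catom_norms
  sig_per <- cfg$noise_sigma * mean(dict$atom_norms) / sqrt(nrep)
  encode <- function(idx) {
    x <- clean[idx, , drop = FALSE]
    if (sig_per > 0) {
      m <- length(x)
      x <- x + complex(real = stats::rnorm(m, 0, sig_per),
                       imaginary = stats::rnorm(m, 0, sig_per))
    }
    xr <- phase_align(x, spec$input_encoding)
    nn <- sqrt(rowSums(xr^2))       # norm of the encoded (real) input
    list(x = xr / pmax(nn, .Machine$double.eps),
         y = cbind(t1_ms = dict$params$t1_ms[idx],
                   t2_ms = dict$params$t2_ms[idx],
                   theta3 = dict$catom_norms[idx]),
         index = idx)
  }
  list(train = encode(tr_idx), validation = encode(va_idx))
}

rank_of <- function(dict) {
  if (is.null(dict$basis)) stop("dictionary has no basis attached")
  dict$basis$rank
}

# ---- internal MLP machinery ------------------------------------------------

init_pathway <- function(d_in, widths) {
  w <- list(); b <- list()
  dims <- c(d_in, widths)
  for (l in seq_along(widths)) {
    w[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     nrow = dims[l])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(w = w, b = b)
}

# forward pass of one pathway; returns activations for backprop
pathway_forward <- function(pw, x, dropout = 0, training = FALSE) {
  a <- list(x)
  masks <- list()
  nl <- length(pw$w)
  for (l in seq_len(nl)) {
    z <- sweep(a[[l]] %*% pw$w[[l]], 2L, pw$b[[l]], `+`)
    h <- if (l < nl) pmax(z, 0) else z     # ReLU hidden, linear output
    if (training && dropout > 0 && l < nl) {
      m <- matrix(stats::runif(length(h)) >= dropout, nrow = nrow(h))
      h <- h * m / (1 - dropout)
      masks[[l]] <- m
    }
    a[[l + 1L]] <- h
  }
  list(a = a, masks = masks)
}

# backprop of one pathway given dL/d(output); returns gradients
pathway_backward <- function(pw, fwd, dout, dropout = 0) {
  nl <- length(pw$w)
  gw <- vector("list", nl); gb <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    gw[[l]] <- crossprod(fwd$a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(pw$w[[l]])
      act <- fwd$a[[l]]
      if (length(fwd$masks) >= l - 1L && !is.null(fwd$masks[[l - 1L]]))
        delta <- delta * fwd$masks[[l - 1L]] / (1 - dropout)
      delta <- delta * (act > 0)
    }
  }
  list(w = gw, b = gb)
}

#' Train the parameter-inference network
#'
#' Minimizes the mean absolute percentage error (MAPE), averaged without
#' weighting over the three outputs, by minibatch stochastic gradient descent
#' at the configured learning rate, with dropout active in the hidden layers
#' during training only. Targets are internally scaled by their training-set
#' means (MAPE is invariant to this); the scales are stored in the model. The
#' returned model is the checkpoint with the best validation loss.
#'
#' @param spec a [network_spec()].
#' @param data result of [make_training_set()].
#' @param cfg a [training_config()].
#' @param verbose print the loss every few epochs.
#' @return object of class `qti_nn` with the trained weights, target scales
#'   and a per-epoch `history` (train/validation loss).
#' @export
train_nn <- function(spec, data, cfg, verbose = FALSE) {
  stopifnot(inherits(spec, "qti_nnspec"), inherits(cfg, "qti_traincfg"))
  xt <- data$train$x; yt <- data$train$y
  xv <- data$validation$x; yv <- data$validation$y
  d_in <- ncol(xt)
  scales <- colMeans(yt)
  ytn <- sweep(yt, 2L, scales, `/`)
  yvn <- sweep(yv, 2L, scales, `/`)

  set.seed(cfg$seed + 1L)
  paths <- lapply(1:3, function(o) init_pathway(d_in, spec$hidden_widths))
  vel <- lapply(paths, function(p)
    list(w = lapply(p$w, function(m) m * 0), b = lapply(p$b, function(v) v * 0)))

  eps <- 1e-6
  mape <- function(pred, targ) mean(abs(pred - targ) / pmax(abs(targ), eps))
  predict_all <- function(x) {
    vapply(1:3, function(o) pathway_forward(paths[[o]], x)$a[[4L]][, 1L],
           numeric(nrow(x)))
  }
  full_loss <- function(x, yn) {
    p <- predict_all(x)
    mean(vapply(1:3, function(o) mape(p[, o], yn[, o]), numeric(1)))
  }

  n <- nrow(xt)
  hist_tr <- numeric(0); hist_va <- numeric(0)
  best <- list(loss = Inf, paths = paths, epoch = 0L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      xb <- xt[idx, , drop = FALSE]
      nb <- length(idx)
      for (o in 1:3) {
        fwd <- pathway_forward(paths[[o]], xb, cfg$dropout, training = TRUE)
        pred <- fwd$a[[4L]][, 1L]
        targ <- ytn[idx, o]
        dout <- matrix(sign(pred - targ) / pmax(abs(targ), eps) / (nb * 3),
                       ncol = 1L)
        g <- pathway_backward(paths[[o]], fwd, dout, cfg$dropout)
        for (l in seq_along(paths[[o]]$w)) {
          vel[[o]]$w[[l]] <- cfg$momentum * vel[[o]]$w[[l]] -
            cfg$learning_rate * g$w[[l]]
          vel[[o]]$b[[l]] <- cfg$momentum * vel[[o]]$b[[l]] -
            cfg$learning_rate * g$b[[l]]
          paths[[o]]$w[[l]] <- paths[[o]]$w[[l]] + vel[[o]]$w[[l]]
          paths[[o]]$b[[l]] <- paths[[o]]$b[[l]] + vel[[o]]$b[[l]]
        }
      }
    }
    ltr <- full_loss(xt, ytn)
    lva <- full_loss(xv, yvn)
    if (!is.finite(ltr) || !is.finite(lva))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    hist_tr <- c(hist_tr, ltr); hist_va <- c(hist_va, lva)
    if (lva < best$loss) best <- list(loss = lva, paths = paths, epoch = epoch)
    if (verbose && (epoch %% 20L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  train %.4f  val %.4f", epoch, ltr, lva))
  }
  structure(list(spec = spec, paths = best$paths, target_scales = scales,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_loss = hist_tr,
                                      val_loss = hist_va)),
            class = "qti_nn")
}

#' @export
print.qti_nn <- function(x, ...) {
  cat(sprintf(paste0("QTI inference network: 3 pathways (%s), input %d, ",
                     "best epoch %d (val loss %.4g)\n"),
              paste(x$spec$hidden_widths, collapse = "/"),
              x$spec$input_rank, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict (T1, T2, theta3) for encoded inputs
#'
#' @param model a trained `qti_nn`.
#' @param x real input matrix (phase-aligned, normalized), one row per signal.
#' @return matrix with columns `t1_ms`, `t2_ms`, `theta3`.
#' @export
nn_predict <- function(model, x) {
  stopifnot(inherits(model, "qti_nn"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  p <- vapply(1:3, function(o)
    pathway_forward(model$paths[[o]], x)$a[[4L]][, 1L], numeric(nrow(x)))
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  p <- sweep(p, 2L, model$target_scales, `*`)
  colnames(p) <- c("t1_ms", "t2_ms", "theta3")
  p
}

#' Voxelwise parameter inference from subspace coefficient images
#'
#' Applies the network to every in-mask voxel of a subspace coefficient image
#' set and derives PD = ||x||2 / theta3 from the voxel's pre-normalization
#' coefficient norm; the formula, not the network, guarantees
#' `pd * theta3 = ||x||2` exactly. Voxels outside the mask (or with zero
#' signal) get T1 = T2 = PD = 0.
#'
#' @param model a trained `qti_nn`.
#' @param coeffs complex matrix (voxels x rank) of subspace coefficients.
#' @param mask logical vector of length voxels (default: all in).
#' @param dims optional spatial dimensions used to shape the output maps.
#' @param voxel_size_mm voxel size recorded in the output maps.
#' @return a [qti_maps()] object (if `dims` given) or a data.frame with
#'   columns `t1_ms`, `t2_ms`, `pd`.
#' @export
infer_maps_nn <- function(model, coeffs, mask = NULL, dims = NULL,
                          voxel_size_mm = 1.125) {
  stopifnot(inherits(model, "qti_nn"))
  if (!is.matrix(coeffs)) coeffs <- matrix(coeffs, nrow = 1L)
  if (ncol(coeffs) != model$spec$input_rank)
    stop("coefficient rank does not match the model's input rank")
  nvox <- nrow(coeffs)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  norms <- sqrt(rowSums(Mod(coeffs)^2))
  use <- mask & norms > 0
  t1 <- t2 <- pd <- numeric(nvox)
  if (any(use)) {
    xr <- phase_align(coeffs[use, , drop = FALSE], model$spec$input_encoding)
    xr <- xr / pmax(sqrt(rowSums(xr^2)), .Machine$double.eps)
    th <- nn_predict(model, xr)
    t1[use] <- pmax(th[, "t1_ms"], 0)
    t2[use] <- pmax(th[, "t2_ms"], 0)
    pd[use] <- norms[use] / pmax(th[, "theta3"], .Machine$double.eps)
  }
  if (is.null(dims))
    return(data.frame(t1_ms = t1, t2_ms = t2, pd = pd))
  qti_maps(array(t1, dims), array(t2, dims), array(pd, dims),
           voxel_size_mm = voxel_size_mm, mask = array(mask, dims))
}

#' Voxelwise dictionary matching from subspace coefficient images
#'
#' The dictionary-matching counterpart of [infer_maps_nn()].
#'
#' @param dict compressed dictionary.
#' @inheritParams infer_maps_nn
#' @return same as [infer_maps_nn()].
#' @export
infer_maps_match <- function(dict, coeffs, mask = NULL, dims = NULL,
                             voxel_size_mm = 1.125) {
  if (!is.matrix(coeffs)) coeffs <- matrix(coeffs, nrow = 1L)
  nvox <- nrow(coeffs)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  t1 <- t2 <- pd <- numeric(nvox)
  if (any(mask)) {
    m <- match_volume(coeffs[mask, , drop = FALSE], dict)
    ok <- !m$flagged
    t1[mask][ok] <- m$t1_ms[ok]
    t2[mask][ok] <- m$t2_ms[ok]
    pd[mask][ok] <- m$pd[ok]
  }
  if (is.null(dims))
    return(data.frame(t1_ms = t1, t2_ms = t2, pd = pd))
  qti_maps(array(t1, dims), array(t2, dims), array(pd, dims),
           voxel_size_mm = voxel_size_mm, mask = array(mask, dims))
}

#' Save / load a trained network as a portable JSON checkpoint
#'
#' Weights, biases, target scales and the architecture are stored in a single
#' JSON file, readable outside R.
#'
#' @param model a `qti_nn`.
#' @param path checkpoint path.
#' @return `path` / the restored `qti_nn`.
#' @export
save_nn <- function(model, path) {
  stopifnot(inherits(model, "qti_nn"))
  obj <- list(spec = unclass(model$spec),
              target_scales = model$target_scales,
              best_epoch = model$best_epoch,
              best_val_loss = model$best_val_loss,
              paths = lapply(model$paths, function(p)
                list(w = lapply(p$w, identity), b = p$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_nn
#' @export
load_nn <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  spec <- structure(list(input_rank = as.integer(obj$spec$input_rank),
                         pathways = 3L,
                         hidden_widths = as.integer(obj$spec$hidden_widths),
                         input_encoding = obj$spec$input_encoding),
                    class = "qti_nnspec")
  paths <- lapply(obj$paths, function(p)
    list(w = lapply(p$w, function(m) {
           m <- as.matrix(m)
           storage.mode(m) <- "double"
           m
         }),
         b = lapply(p$b, as.numeric)))
  structure(list(spec = spec, paths = paths,
                 target_scales = as.numeric(obj$target_scales),
                 best_epoch = obj$best_epoch,
                 best_val_loss = obj$best_val_loss,
                 history = NULL),
            class = "qti_nn")
}
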