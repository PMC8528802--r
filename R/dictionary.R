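#' The (T1, T2) dictionary parameter grid
#'
#' Builds the simulation grid used for dictionary generation and matching:
#' T1 sampled every 10 ms from 10 to 2000 ms and every 100 ms from 2100 to
#' 5000 ms (230 values); T2 sampled every 5 ms from 10 to 300 ms and every
#' 10 ms from 310 to 2000 ms (229 values). All (T1, T2) combinations are kept,
#' including T2 > T1; set `exclude_t2_gt_t1 = TRUE` to drop the unphysical
#' combinations.
#'
#' @param t1_values_ms,t2_values_ms optional custom grid vectors (strictly
#'   ascending, within [10, 5000] ms for T1 and [10, 2000] ms for T2).
#' @param exclude_t2_gt_t1 drop grid combinations with T2 > T1 when expanding
#'   the grid to atoms (default FALSE).
#' @return an object of class `qti_grid`.
#' @export
build_grid <- function(t1_values_ms = NULL, t2_values_ms = NULL,
                       exclude_t2_gt_t1 = FALSE) {
  if (is.null(t1_values_ms))
    t1_values_ms <- c(seq(10, 2000, by = 10), seq(2100, 5000, by = 100))
  if (is.null(t2_values_ms))
    t2_values_ms <- c(seq(10, 300, by = 5), seq(310, 2000, by = 10))
  t1_values_ms <- as.numeric(t1_values_ms)
  t2_values_ms <- as.numeric(t2_values_ms)
  stopifnot(all(diff(t1_values_ms) > 0), all(diff(t2_values_ms) > 0),
            min(t1_values_ms) >= 10, max(t1_values_ms) <= 5000,
            min(t2_values_ms) >= 10, max(t2_values_ms) <= 2000)
  structure(list(t1_values_ms = t1_values_ms, t2_values_ms = t2_values_ms,
                 exclude_t2_gt_t1 = isTRUE(exclude_t2_gt_t1)),
            class = "qti_grid")
}

#' Expand a grid to the per-atom (T1, T2) table
#'
#' Atoms are ordered row-major, T1 outer and T2 inner (T2 varies fastest), the
#' order used for deterministic tie-breaking in matching.
#'
#' @param grid a `qti_grid`.
#' @return data.frame with columns `t1_ms`, `t2_ms`.
#' @export
grid_atoms <- function(grid) {
  stopifnot(inherits(grid, "qti_grid"))
  g <- expand.grid(t2_ms = grid$t2_values_ms, t1_ms = grid$t1_values_ms,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("t1_ms", "t2_ms")]
  if (grid$exclude_t2_gt_t1) g <- g[g$t2_ms <= g$t1_ms, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Build the signal dictionary on a (T1, T2) grid
#'
#' Simulates one unit-PD EPG signal per grid combination, L2-normalizes each
#' atom and stores the pre-normalization norm. The stored norms define the
#' unit-PD signal scale used for proton-density estimation: a measured signal
#' with subspace norm \eqn{\|x\|_2} matched to atom a has
#' \eqn{PD = \|x\|_2 / \nu_a} with \eqn{\nu_a} the atom's stored norm.
#'
#' @param grid a [build_grid()] result.
#' @param schedule a [qti_schedule()].
#' @param max_epg_order EPG truncation order (see [simulate_signal()]).
#' @return object of class `qti_dictionary` with fields `grid`, `params`
#'   (per-atom T1/T2 table), `atoms` (complex matrix, atoms x repetitions,
#'   unit L2 norm rows), `atom_norms`, `schedule`.
#' @export
build_dictionary <- function(grid, schedule, max_epg_order = 100L) {
  stopifnot(inherits(grid, "qti_grid"), inherits(schedule, "qti_schedule"))
  params <- grid_atoms(grid)
  sig <- epg_fisp_batch_cpp(params$t1_ms, params$t2_ms,
                            rep(1, nrow(params)),
                            schedule$flip_angles * pi / 180,
                            schedule$tr_ms, schedule$te_ms, schedule$ti_ms,
                            schedule$inversion_flip_deg * pi / 180,
                            as.integer(max_epg_order))
  norms <- sqrt(rowSums(sig^2))
  if (any(norms <= 0))
    stop("zero-norm dictionary atom at grid point ",
         which(norms <= 0)[1L])
  sig <- sig / norms
  structure(list(grid = grid, params = params,
                 atoms = sig,            # real-valued by phase convention
                 atom_norms = norms,
                 schedule = schedule),
            class = "qti_dictionary")
}

#' Complex view of the dictionary atoms
#'
#' Atoms are stored in the package's constant-RF-phase convention (zero
#' imaginary part); this accessor returns them as a complex matrix.
#' @param dict a `qti_dictionary`.
#' @return complex matrix (atoms x repetitions).
#' @export
dictionary_atoms <- function(dict) {
  a <- dict$atoms
  if (is.complex(a)) a else matrix(complex(real = a, imaginary = 0),
                                   nrow = nrow(a))
}

#' @export
print.qti_dictionary <- function(x, ...) {
  cat(sprintf("QTI dictionary: %d atoms (%d T1 x %d T2) x %d repetitions\n",
              nrow(x$params), length(x$grid$t1_values_ms),
              length(x$grid$t2_values_ms), ncol(x$atoms)))
  if (!is.null(x$basis))
    cat(sprintf("  compressed at rank %d\n", ncol(x$basis$vectors)))
  invisible(x)
}

#' Temporal SVD subspace of a dictionary
#'
#' Computes the top right singular vectors of the (normalized) atom matrix,
#' i.e. the orthonormal temporal basis whose first `rank` components capture
#' the signal manifold; reconstructed images per retained component are the
#' "singular images" of the subspace reconstruction. The default rank is 10.
#'
#' @param dict a [build_dictionary()] result.
#' @param rank number of retained components (default 10).
#' @param verbose print the retained singular values.
#' @return object of class `qti_basis` with `vectors` (repetitions x rank,
#'   orthonormal columns) and `singular_values` (all, descending).
#' @export
compute_subspace <- function(dict, rank = 10L, verbose = FALSE) {
  stopifnot(inherits(dict, "qti_dictionary"))
  rank <- as.integer(rank)
  a <- dict$atoms
  nrep <- ncol(a)
  if (rank < 1L || rank > min(nrow(a), nrep)) stop("rank out of range")
  s <- if (is.complex(a)) crossprod(Conj(a), a) else crossprod(a)
  e <- eigen(if (is.complex(s)) (s + Conj(t(s))) / 2 else (s + t(s)) / 2,
             symmetric = TRUE)
  sv <- sqrt(pmax(Re(e$values), 0))
  v <- e$vectors[, seq_len(rank), drop = FALSE]
  # fix sign/phase so the basis is reproducible: largest |entry| real-positive
  for (j in seq_len(rank)) {
    i <- which.max(abs(v[, j]))
    ph <- v[i, j] / abs(v[i, j])
    v[, j] <- v[, j] / ph
  }
  if (verbose)
    message("retained singular values: ",
            paste(signif(sv[seq_len(rank)], 6), collapse = ", "))
  structure(list(vectors = v, rank = rank, singular_values = sv),
            class = "qti_basis")
}

#' Project a signal onto the temporal subspace
#'
#' Coefficients are the conjugate inner products with the basis vectors. For
#' an orthonormal basis the coefficient norm never exceeds the signal norm.
#'
#' @param signal complex (or real) vector of length = repetitions, or a matrix
#'   with one signal per row.
#' @param basis a [compute_subspace()] result.
#' @return complex coefficient vector of length `basis$rank` (or a matrix,
#'   signals x rank).
#' @export
compress_signal <- function(signal, basis) {
  stopifnot(inherits(basis, "qti_basis"))
  v <- basis$vectors
  if (is.matrix(signal)) {
    if (ncol(signal) != nrow(v)) stop("signal length does not match basis")
    return(signal %*% Conj(v))
  }
  if (length(signal) != nrow(v)) stop("signal length does not match basis")
  as.vector(t(Conj(v)) %*% signal)
}

#' Expand subspace coefficients back to the time domain
#' @param coeffs coefficient vector (or matrix, signals x rank).
#' @param basis a `qti_basis`.
#' @return time-domain signal(s).
#' @export
expand_signal <- function(coeffs, basis) {
  v <- basis$vectors
  if (is.matrix(coeffs)) coeffs %*% t(v) else as.vector(v %*% coeffs)
}

#' Cache compressed atoms for matching
#'
#' Projects every (unit-norm) atom onto the basis, renormalizes the projected
#' atoms to unit norm in the compressed domain, and stores alongside them the
#' compressed-domain norm of each unit-PD signal. Matching then runs entirely
#' in the rank-10 domain, where self-matches score a correlation of exactly 1
#' and proton density is recovered exactly for clean (noiseless) signals.
#'
#' @param dict a `qti_dictionary`.
#' @param basis a `qti_basis` computed from the same dictionary.
#' @return the dictionary with `$compressed` (unit-norm compressed atoms,
#'   atoms x rank, complex), `$proj_norms` (norm retained by the rank-`r`
#'   projection of each unit atom, close to 1), `$catom_norms` (compressed
#'   unit-PD signal norms, the PD scale), and `$basis` attached.
#' @export
compress_dictionary <- function(dict, basis) {
  stopifnot(inherits(dict, "qti_dictionary"), inherits(basis, "qti_basis"))
  a <- dict$atoms
  comp <- if (is.complex(a)) a %*% Conj(basis$vectors) else a %*% Re(basis$vectors)
  if (!is.complex(comp)) comp <- matrix(complex(real = comp, imaginary = 0),
                                        nrow = nrow(comp))
  pn <- sqrt(rowSums(Mod(comp)^2))
  if (any(pn <= 0)) stop("atom with zero subspace projection")
  dict$compressed <- comp / pn
  dict$proj_norms <- pn
  dict$catom_norms <- dict$atom_norms * pn
  dict$basis <- basis
  dict
}

#' Dictionary matching of a compressed signal
#'
#' Returns the grid point whose (unit-norm, compressed) atom maximizes the
#' phase-invariant normalized inner product with the input, plus the
#' proton-density estimate `pd = |<x, atom>| / atom_norm`. Ties are broken
#' deterministically by the lowest atom index (row-major T1-then-T2 order).
#' Zero-norm inputs return a flagged result with `pd = 0` and `NA` relaxation
#' times.
#'
#' @param x complex coefficient vector (length = basis rank).
#' @param dict a dictionary with cached compression ([compress_dictionary()]).
#' @return list with `t1_ms`, `t2_ms`, `pd`, `correlation`, `index`,
#'   `flagged`.
#' @export
match_signal <- function(x, dict) {
  m <- match_volume(matrix(x, nrow = 1L), dict)
  list(t1_ms = m$t1_ms[1L], t2_ms = m$t2_ms[1L], pd = m$pd[1L],
       correlation = m$correlation[1L], index = m$index[1L],
       flagged = m$flagged[1L])
}

#' Dictionary matching of many compressed signals
#'
#' @param x complex matrix, one compressed signal per row (columns = rank).
#' @param dict a dictionary with cached compression.
#' @param chunk number of signals matched per block (bounds memory use).
#' @return data.frame with one row per input signal: `t1_ms`, `t2_ms`, `pd`,
#'   `correlation`, `index`, `flagged`.
#' @export
match_volume <- function(x, dict, chunk = 256L) {
  stopifnot(inherits(dict, "qti_dictionary"))
  if (is.null(dict$compressed))
    stop("dictionary has no cached compression; call compress_dictionary() first")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(dict$compressed))
    stop("signal rank does not match the dictionary's basis rank")
  n <- nrow(x)
  d <- dict$compressed
  xn <- sqrt(rowSums(Mod(x)^2))
  idx <- integer(n); corr <- numeric(n); ip <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- x[s:e, , drop = FALSE]
    sc <- Mod(block %*% Conj(t(d)))          # |<x, atom>| per (voxel, atom)
    j <- max.col(sc, ties.method = "first")
    idx[s:e] <- j
    ip[s:e] <- sc[cbind(seq_len(nrow(sc)), j)]
  }
  flagged <- xn <= 0
  corr <- ifelse(flagged, NA_real_, ip / xn)
  pd <- ifelse(flagged, 0, ip / dict$catom_norms[idx])
  data.frame(
    t1_ms = ifelse(flagged, NA_real_, dict$params$t1_ms[idx]),
    t2_ms = ifelse(flagged, NA_real_, dict$params$t2_ms[idx]),
    pd = pd, correlation = corr, index = ifelse(flagged, NA_integer_, idx),
    flagged = flagged)
}

#' Persist / restore a dictionary with its subspace
#'
#' The dictionary (grid, atoms, norms, schedule, cached compression) is stored
#' as a single self-describing RDS container; the grid is additionally
#' exported as CSV next to it for interoperability.
#'
#' @param dict a `qti_dictionary`.
#' @param path path of the container file (e.g. `dict.rds`).
#' @return `path` (`save_dictionary`) or the restored dictionary
#'   (`load_dictionary`).
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "qti_dictionary"))
  saveRDS(dict, path)
  grid_csv <- paste0(sub("\\.rds$", "", path), "_grid.csv")
  utils::write.csv(dict$params, grid_csv, row.names = FALSE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary container not found: ", path)
  dict <- readRDS(path)
  if (!inherits(dict, "qti_dictionary")) stop("not a dictionary container: ", path)
  dict
}
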