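# Independent oracles, built before (and kept independent of) the EPG and
# matching implementations they check.

# Isochromat-ensemble brute-force simulator: nspins spins uniformly spanning
# 2*pi of intra-voxel dephasing per TR (lumped spoiler at the end of each
# repetition), full Bloch rotations in the complex (M+, Mz) representation
# with the same constant-RF-phase convention (phase 90 degrees).
iso_simulate <- function(t1, t2, pd, sched, nspins = 1000L) {
  a <- sched$flip_angles * pi / 180
  n <- length(a)
  th <- 2 * pi * (seq_len(nspins) - 1) / nspins
  rot <- function(Mp, Mz, al, phi = pi / 2) {
    c2 <- cos(al / 2)^2; s2 <- sin(al / 2)^2
    sa <- sin(al); ca <- cos(al)
    list(Mp = c2 * Mp + exp(2i * phi) * s2 * Conj(Mp) -
           1i * exp(1i * phi) * sa * Mz,
         Mz = sa * Im(exp(-1i * phi) * Mp) + ca * Mz)
  }
  Mp <- complex(real = rep(0, nspins))
  Mz <- rep(1, nspins)
  r <- rot(Mp, Mz, sched$inversion_flip_deg * pi / 180)
  Mp <- r$Mp; Mz <- r$Mz
  Mp <- Mp * exp(-sched$ti_ms / t2)
  Mz <- 1 + (Mz - 1) * exp(-sched$ti_ms / t1)
  e1 <- exp(-sched$tr_ms / t1); e2 <- exp(-sched$tr_ms / t2)
  ete <- exp(-sched$te_ms / t2)
  spoil <- exp(1i * th)
  sig <- complex(length.out = n)
  for (i in seq_len(n)) {
    r <- rot(Mp, Mz, a[i])
    Mp <- r$Mp; Mz <- r$Mz
    sig[i] <- pd * mean(Mp) * ete
    Mp <- Mp * e2 * spoil
    Mz <- 1 + (Mz - 1) * e1
  }
  sig
}

# brute-force full-time-domain dictionary matching by maximum normalized
# modulus correlation (no subspace), for cross-checking compressed matching
brute_force_match <- function(signal, atoms_complex, params) {
  scores <- Mod(atoms_complex %*% Conj(signal)) / sqrt(sum(Mod(signal)^2))
  j <- which.max(scores)
  list(t1_ms = params$t1_ms[j], t2_ms = params$t2_ms[j], index = j)
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
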