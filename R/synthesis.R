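#' Specification of a synthesized contrast-weighted image
#'
#' Defines the virtual sequence whose steady-state signal equation is applied
#' voxelwise to the quantitative maps: a spoiled gradient echo for
#' T1-weighting (`spgr_t1w`), a spin echo for T2-weighting (`se_t2w`), and an
#' inversion-recovery spin echo for FLAIR (`flair`).
#'
#' @param kind `"spgr_t1w"`, `"se_t2w"` or `"flair"`.
#' @param tr_ms,te_ms sequence timing in ms (0 < TE < TR).
#' @param ti_ms inversion time in ms (flair only; TI < TR).
#' @param flip_deg excitation flip angle in degrees (spgr only).
#' @return object of class `qti_contrast`.
#' @export
contrast_spec <- function(kind = c("spgr_t1w", "se_t2w", "flair"),
                          tr_ms, te_ms, ti_ms = NULL, flip_deg = NULL) {
  kind <- match.arg(kind)
  stopifnot(tr_ms > 0, te_ms > 0, te_ms < tr_ms)
  if (kind == "flair") {
    if (is.null(ti_ms) || ti_ms <= 0 || ti_ms >= tr_ms)
      stop("flair needs 0 < ti_ms < tr_ms")
  }
  if (kind == "spgr_t1w") {
    if (is.null(flip_deg) || flip_deg <= 0 || flip_deg > 90)
      stop("spgr_t1w needs a flip angle in (0, 90]")
  }
  structure(list(kind = kind, tr_ms = tr_ms, te_ms = te_ms,
                 ti_ms = ti_ms, flip_deg = flip_deg),
            class = "qti_contrast")
}

#' Default synthesis parameters of the three clinical contrasts
#'
#' T1-weighted spoiled gradient echo (TR 4.6 ms, TE 2.1 ms, flip 12 deg),
#' T2-weighted spin echo (TR 5751 ms, TE 120.7 ms) and FLAIR (TR 5002 ms,
#' TE 92 ms, TI 1701 ms), matching the clinical protocol the synthetic images
#' are compared against. All parameters are overridable.
#'
#' @return named list of [contrast_spec()] objects: `t1w`, `t2w`, `flair`.
#' @export
default_contrasts <- function() {
  list(t1w = contrast_spec("spgr_t1w", tr_ms = 4.6, te_ms = 2.1,
                           flip_deg = 12),
       t2w = contrast_spec("se_t2w", tr_ms = 5751, te_ms = 120.7),
       flair = contrast_spec("flair", tr_ms = 5002, te_ms = 92,
                             ti_ms = 1701))
}

#' Synthesize a contrast-weighted image from quantitative maps
#'
#' Applies the voxelwise steady-state signal equation of the requested
#' contrast to the T1/T2/PD maps:
#' \describe{
#'   \item{spgr_t1w}{\eqn{S = PD \sin\alpha (1 - E_1)/(1 - \cos\alpha E_1)
#'     e^{-TE/T2}}, \eqn{E_1 = e^{-TR/T1}} (T2 standing in for T2*, which this
#'     pipeline does not map).}
#'   \item{se_t2w}{\eqn{S = PD (1 - e^{-TR/T1}) e^{-TE/T2}}.}
#'   \item{flair}{\eqn{S = PD |1 - 2 e^{-TI/T1} + e^{-TR/T1}| e^{-TE/T2}}
#'     (magnitude convention of inversion-recovery display); fluid with
#'     T1 = TI/ln 2 is nulled in the long-TR limit.}
#' }
#' Voxels with T1 = 0 or T2 = 0 are background and map to exactly 0; the
#' output is non-negative and exactly linear in PD.
#'
#' @param maps a [qti_maps()] object.
#' @param spec a [contrast_spec()].
#' @param scale_display if TRUE, scale the returned image to `[0, 1]` by its
#'   99th-percentile intensity (for display export); raw signal otherwise.
#' @return numeric array of the maps' shape.
#' @export
synthesize <- function(maps, spec, scale_display = FALSE) {
  stopifnot(inherits(maps, "qti_maps"), inherits(spec, "qti_contrast"))
  t1 <- maps$t1; t2 <- maps$t2; pd <- maps$pd
  fg <- maps$mask & t1 > 0 & t2 > 0
  s <- array(0, dim(t1))
  if (any(fg)) {
    T1 <- t1[fg]; T2 <- t2[fg]; PD <- pd[fg]
    e1 <- exp(-spec$tr_ms / T1)
    ete <- exp(-spec$te_ms / T2)
    s[fg] <- switch(spec$kind,
      spgr_t1w = {
        a <- spec$flip_deg * pi / 180
        PD * sin(a) * (1 - e1) / (1 - cos(a) * e1) * ete
      },
      se_t2w = PD * (1 - e1) * ete,
      flair = PD * abs(1 - 2 * exp(-spec$ti_ms / T1) + e1) * ete)
  }
  if (scale_display) {
    q <- stats::quantile(s[fg], 0.99, names = FALSE)
    if (q > 0) s <- pmin(s / q, 1)
  }
  s
}
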