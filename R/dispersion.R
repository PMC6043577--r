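#' Numerical two-state CPMG dispersion model
#'
#' Effective transverse relaxation rate of the observed (ground-state)
#' resonance during a constant-time CPMG element, computed by numerical
#' propagation of the two-state Bloch-McConnell equations. Transverse
#' magnetization of the two exchanging states evolves under free precession
#' (exchange matrix with off-diagonal rates \code{k_ab}/\code{k_ba}, the
#' shift difference \code{dw_rad} on the minor-state diagonal, and a shared
#' intrinsic rate \code{r20} on both diagonals) interleaved with ideal,
#' instantaneous 180-degree pulses applied as complex conjugation. Blocks
#' are paired palindromically. The number of echo blocks is the nearest
#' integer to \code{2 * t_relax * nu_cpmg}; the effective CPMG frequency
#' actually simulated is that integer over \code{2 * t_relax}.
#'
#' Starting from equilibrium populations, the returned rate is
#' \code{-(1/t_relax) * log(|M_A(t_relax)| / |M_A(0)|)}. The intrinsic rate
#' enters additively, and longitudinal relaxation cancels in the intensity
#' ratio of constant-time experiments, so it is not modelled.
#'
#' @param k_ab,k_ba forward/backward exchange rates, 1/s (both > 0)
#' @param dw_rad shift difference between states, rad/s
#' @param r20 intrinsic transverse relaxation rate shared by both states, 1/s
#' @param nu_cpmg CPMG refocusing frequency, Hz (vectorized)
#' @param t_relax constant relaxation delay, s (default 0.030)
#' @return R2,eff in 1/s, one value per element of \code{nu_cpmg}
#' @seealso [carver_richards_r2eff()] for the closed-form oracle
#' @export
bm_r2eff <- function(k_ab, k_ba, dw_rad, r20, nu_cpmg, t_relax = 0.030) {
  stopifnot(all(k_ab > 0), all(k_ba > 0), all(r20 >= 0),
            all(nu_cpmg > 0), t_relax > 0)
  out <- .bm_r2eff_cpp(as.numeric(k_ab), as.numeric(k_ba),
                       as.numeric(dw_rad), as.numeric(r20),
                       as.numeric(nu_cpmg), t_relax)
  if (anyNA(out))
    stop("Bloch-McConnell propagation over/underflowed (k_ab=",
         k_ab[1], ", k_ba=", k_ba[1], ", dw=", dw_rad[1], " rad/s)")
  out
}

#' Carver-Richards closed-form CPMG dispersion
#'
#' Analytic two-state single-quantum expression for R2,eff, used as an
#' independent cross-check of the numerical propagator. Intrinsic rates of
#' the two states are taken equal.
#'
#' @inheritParams bm_r2eff
#' @return R2,eff in 1/s, vectorized over \code{nu_cpmg}
#' @export
carver_richards_r2eff <- function(k_ab, k_ba, dw_rad, r20, nu_cpmg) {
  stopifnot(k_ab > 0, k_ba > 0, all(nu_cpmg > 0))
  kex <- k_ab + k_ba
  pB <- k_ab / kex
  pA <- 1 - pB
  if (dw_rad == 0) return(rep(r20, length(nu_cpmg)))
  tt <- kex * (pB - pA)            # equal intrinsic rates
  psi <- tt^2 - dw_rad^2 + 4 * pA * pB * kex^2
  zeta <- 2 * dw_rad * tt
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw_rad^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw_rad^2) / root)
  etap <- sqrt(pmax(psi + root, 0) / 2) / (2 * nu_cpmg)
  etam <- sqrt(pmax(-psi + root, 0) / 2) / (2 * nu_cpmg)
  arg <- Dp * cosh(etap) - Dm * cos(etam)
  r20 + 0.5 * kex - nu_cpmg * acosh(pmax(arg, 1))
}

#' Luz-Meiboom fast-exchange dispersion limit
#'
#' Valid when \code{k_ex} is much larger than \code{dw_rad}; used as a
#' second analytic check of the numerical model.
#'
#' @inheritParams bm_r2eff
#' @return R2,eff in 1/s
#' @export
luz_meiboom_r2eff <- function(k_ab, k_ba, dw_rad, r20, nu_cpmg) {
  kex <- k_ab + k_ba
  pB <- k_ab / kex
  pA <- 1 - pB
  rex <- pA * pB * dw_rad^2 / kex
  r20 + rex * (1 - (4 * nu_cpmg / kex) * tanh(kex / (4 * nu_cpmg)))
}

#' Experimental R2,eff uncertainty
#'
#' Error propagated from the spectral noise through the intensity of the
#' point at (or nearest to) a 500 Hz CPMG frequency,
#' \code{sigma / (t_relax * i_ref500)}, floored at a minimum of 3 percent of
#' the R2,eff value itself.
#'
#' @param noise_sd spectral noise standard deviation (intensity units)
#' @param i_ref500 peak intensity at the 500 Hz reference frequency
#' @param t_relax relaxation delay, s
#' @param r2eff the R2,eff value the error belongs to, 1/s
#' @param floor_frac minimum relative error (default 0.03)
#' @return error in 1/s
#' @export
r2eff_error <- function(noise_sd, i_ref500, t_relax, r2eff,
                        floor_frac = 0.03) {
  stopifnot(i_ref500 > 0, t_relax > 0, noise_sd >= 0)
  pmax(noise_sd / (t_relax * i_ref500), floor_frac * abs(r2eff))
}

#' Convert CPMG peak intensities to dispersion curves
#'
#' Applies \code{R2,eff = -(1/t_relax) * log(I_cpmg / I0)} per point, where
#' I0 is the reference intensity recorded with no relaxation delay. Errors
#' follow [r2eff_error()] using the intensity of the point nearest 500 Hz in
#' each curve (a message notes the substitution when no exact 500 Hz point
#' exists).
#'
#' @param table a peak-intensity table (see [peak_intensity_table()]):
#'   columns residue_id, field_mhz, temp_k, condition, nu_cpmg_hz,
#'   intensity, with one \code{condition == "reference"} row per
#'   residue/field/temperature group
#' @param t_relax relaxation delay, s (default 0.030 as in the
#'   relaxation-compensated experiment)
#' @param noise_sd spectral noise standard deviation; default 0 (the 3
#'   percent floor then sets all errors)
#' @return a \code{dispersion_dataset}: data frame with columns residue_id,
#'   field_mhz, temp_k, nu_cpmg_hz, r2eff, r2eff_err and attributes
#'   \code{excluded} (data frame of residue_id, reason) and counts n_R,
#'   n_T, n_B. Non-positive CPMG intensities are flagged invalid (NA rate)
#'   and reported; groups missing a reference row raise an error naming the
#'   group.
#' @export
r2eff_from_intensities <- function(table, t_relax = 0.030, noise_sd = 0) {
  stopifnot(t_relax > 0)
  table <- validate_peak_table(table)
  grp <- interaction(table$residue_id, table$field_mhz, table$temp_k,
                     drop = TRUE)
  pieces <- lapply(split(table, grp), function(gd) {
    ref <- gd[gd$condition == "reference", , drop = FALSE]
    if (nrow(ref) != 1L)
      stop("group residue ", gd$residue_id[1], " / ", gd$field_mhz[1],
           " MHz / ", gd$temp_k[1], " K has ", nrow(ref),
           " reference (I0) rows; exactly one required")
    i0 <- ref$intensity
    if (i0 <= 0) stop("non-positive reference intensity in group residue ",
                      gd$residue_id[1])
    pts <- gd[gd$condition != "reference", , drop = FALSE]
    pts <- pts[order(pts$nu_cpmg_hz), , drop = FALSE]
    bad <- pts$intensity <= 0
    r2 <- rep(NA_real_, nrow(pts))
    r2[!bad] <- -log(pts$intensity[!bad] / i0) / t_relax
    if (any(bad))
      warning("non-positive CPMG intensity for residue ", pts$residue_id[1],
              " at nu = ", paste(pts$nu_cpmg_hz[bad], collapse = ", "),
              " Hz; point(s) flagged invalid", call. = FALSE)
    iref_idx <- which.min(abs(pts$nu_cpmg_hz - 500))
    err <- r2eff_error(noise_sd, pts$intensity[iref_idx], t_relax, r2)
    data.frame(residue_id = pts$residue_id, field_mhz = pts$field_mhz,
               temp_k = pts$temp_k, nu_cpmg_hz = pts$nu_cpmg_hz,
               r2eff = r2, r2eff_err = err)
  })
  curves <- do.call(rbind, pieces)
  rownames(curves) <- NULL
  dispersion_dataset(curves)
}

#' Construct a dispersion dataset
#'
#' @param curves data frame with columns residue_id, field_mhz, temp_k,
#'   nu_cpmg_hz, r2eff, r2eff_err
#' @param excluded optional data frame (residue_id, reason) of residues
#'   dropped before analysis; reason one of "overlap", "low_quality", "flat"
#' @return object of class \code{dispersion_dataset}
#' @export
dispersion_dataset <- function(curves,
                               excluded = data.frame(residue_id = character(),
                                                     reason = character())) {
  need <- c("residue_id", "field_mhz", "temp_k", "nu_cpmg_hz",
            "r2eff", "r2eff_err")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("curves missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(curves$residue_id %in% excluded$residue_id))
    curves <- curves[!curves$residue_id %in% excluded$residue_id, ,
                     drop = FALSE]
  ok <- is.finite(curves$r2eff)
  if (any(curves$r2eff_err[ok] <= 0)) stop("non-positive r2eff errors")
  structure(curves,
            excluded = excluded,
            n_R = length(unique(curves$residue_id)),
            n_T = length(unique(curves$temp_k)),
            n_B = length(unique(curves$field_mhz)),
            class = c("dispersion_dataset", "data.frame"))
}

#' @export
print.dispersion_dataset <- function(x, ...) {
  cat("CPMG dispersion dataset: n_R =", attr(x, "n_R"),
      "residues, n_T =", attr(x, "n_T"), "temperatures, n_B =",
      attr(x, "n_B"), "fields,", nrow(x), "points\n")
  excl <- attr(x, "excluded")
  if (nrow(excl)) cat("excluded residues:",
                      paste(excl$residue_id, collapse = ", "), "\n")
  invisible(x)
}

#' Identify exchange-active residues
#'
#' A residue is retained when the drop in R2,eff between the lowest and the
#' highest CPMG frequency exceeds the threshold (5 1/s by default) in at
#' least one field/temperature condition. Residues tagged as overlapped or
#' low quality in the dataset's exclusion list are never retained.
#'
#' @param dataset a \code{dispersion_dataset}
#' @param threshold minimum \code{R2,eff(nu_low) - R2,eff(nu_high)} in 1/s
#' @param nu_low,nu_high probe frequencies, Hz; the nearest measured points
#'   are used
#' @return list with \code{retained} (residue ids), \code{delta_table}
#'   (per residue x condition delta R2,eff) and the threshold used
#' @export
select_exchange_residues <- function(dataset, threshold = 5,
                                     nu_low = 66.7, nu_high = 1000) {
  excl <- attr(dataset, "excluded")
  grp <- interaction(dataset$residue_id, dataset$field_mhz, dataset$temp_k,
                     drop = TRUE)
  rows <- lapply(split(as.data.frame(dataset), grp), function(gd) {
    ilo <- which.min(abs(gd$nu_cpmg_hz - nu_low))
    ihi <- which.min(abs(gd$nu_cpmg_hz - nu_high))
    data.frame(residue_id = gd$residue_id[1], field_mhz = gd$field_mhz[1],
               temp_k = gd$temp_k[1],
               delta_r2eff = gd$r2eff[ilo] - gd$r2eff[ihi])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  hit <- tapply(tab$delta_r2eff, tab$residue_id,
                function(d) any(d > threshold, na.rm = TRUE))
  retained <- names(hit)[hit]
  retained <- setdiff(retained, excl$residue_id)
  list(retained = retained, delta_table = tab, threshold = threshold)
}

#' Keep only selected residues of a dispersion dataset
#'
#' @param dataset a \code{dispersion_dataset}
#' @param residue_ids ids to keep
#' @return filtered \code{dispersion_dataset}
#' @export
subset_residues <- function(dataset, residue_ids) {
  dispersion_dataset(
    as.data.frame(dataset)[dataset$residue_id %in% residue_ids, ,
                           drop = FALSE],
    excluded = attr(dataset, "excluded"))
}
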