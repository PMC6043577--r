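#' Fit a single-exponential intensity decay
#'
#' Relative (proportional-error) nonlinear least squares of
#' \code{I(t) = I0 * exp(-R t)} on a delay series, started from the
#' log-linear regression. Weighting each residual by the inverse observed
#' intensity is the maximum-likelihood choice when intensity uncertainties
#' scale with the intensity, and is equivalent to the classical log-linear
#' fit at low noise while remaining defined for non-positive points.
#' Non-decaying series are returned flagged rather than dropped.
#'
#' @param series data frame with columns delay_s and intensity (one
#'   residue), e.g. from [generate_relaxation_series()]
#' @return list with rate (1/s), rate_se, i0, converged, decaying
#' @export
fit_exponential_decay <- function(series) {
  stopifnot(all(c("delay_s", "intensity") %in% names(series)))
  if (nrow(series) < 4) stop("need at least 4 delay points")
  t <- series$delay_s
  y <- series$intensity
  pos <- y > 0
  slope <- if (sum(pos) >= 2) coef(lm(log(y[pos]) ~ t[pos]))[[2]] else -1
  decaying <- slope < 0
  start <- list(i0 = max(y), r = max(-slope, 1e-3))
  w <- 1 / pmax(abs(y), max(abs(y)) * 1e-6)^2
  fit <- try(minpack.lm::nlsLM(
    y ~ i0 * exp(-r * t), start = start, weights = w,
    lower = c(i0 = 0, r = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(rate = NA_real_, rate_se = NA_real_, i0 = NA_real_,
                converged = FALSE, decaying = decaying))
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["r"]], error = function(e) NA_real_)
  list(rate = co[["r"]], rate_se = se, i0 = co[["i0"]],
       converged = TRUE, decaying = decaying)
}

#' Steady-state heteronuclear NOE
#'
#' Ratio of peak intensities with and without proton saturation; the error
#' is propagated from the spectral noise. Residues with values below the
#' cut (default 0.65) are flagged as flexible on the fast timescale.
#'
#' @param i_saturated,i_reference peak intensities
#' @param noise_sd spectral noise standard deviation
#' @param flexible_cut threshold below which a residue counts as flexible
#' @return list with noe, noe_se, flexible
#' @export
het_noe <- function(i_saturated, i_reference, noise_sd = 0,
                    flexible_cut = 0.65) {
  stopifnot(i_reference > 0)
  noe <- i_saturated / i_reference
  se <- abs(noe) * sqrt((noise_sd / i_saturated)^2 +
                          (noise_sd / i_reference)^2)
  list(noe = noe, noe_se = se, flexible = noe < flexible_cut)
}

# reduced spectral density of an isotropic rotor, J(w) = 2/5 tc/(1+(w tc)^2)
.jw <- function(w, tc) 0.4 * tc / (1 + (w * tc)^2)

#' 15N relaxation rates of an isotropic rotor
#'
#' Forward model for backbone amide R1, R2 and heteronuclear NOE given an
#' overall rotational correlation time, assuming rigid isotropic tumbling
#' (no internal motion), dipolar coupling to the attached proton (N-H bond
#' 1.02 Angstrom) and an axially symmetric 15N CSA of -160 ppm.
#'
#' @param tau_c rotational correlation time, s
#' @param field_mhz 1H spectrometer frequency, MHz
#' @return list with r1, r2 (1/s) and noe (dimensionless)
#' @export
iso_rotor_rates <- function(tau_c, field_mhz) {
  b0 <- 2 * pi * field_mhz * 1e6 / .const$gamma_h # Tesla
  wh <- .const$gamma_h * b0
  wn <- .const$gamma_n * b0
  mu0_4pi <- 1e-7
  hbar <- .const$h / (2 * pi)
  d <- mu0_4pi * hbar * .const$gamma_h * .const$gamma_n / .const$r_nh^3
  c <- wn * .const$csa_n / sqrt(3)
  jh_n <- .jw(wh - wn, tau_c)
  jn <- .jw(wn, tau_c)
  jhn <- .jw(wh + wn, tau_c)
  j0 <- .jw(0, tau_c)
  jh <- .jw(wh, tau_c)
  r1 <- d^2 / 4 * (3 * jn + jh_n + 6 * jhn) + c^2 * jn
  r2 <- d^2 / 8 * (4 * j0 + 3 * jn + jh_n + 6 * jh + 6 * jhn) +
    c^2 / 6 * (4 * j0 + 3 * jn)
  noe <- 1 + (.const$gamma_h / .const$gamma_n) * (d^2 / 4) *
    (6 * jhn - jh_n) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Overall rotational correlation time from R2/R1
#'
#' Inverts the isotropic-rotor spectral-density expressions for the
#' trimmed-mean R2/R1 ratio of rigid residues (heteronuclear NOE at or
#' above the flexibility cut, and optionally not exchange-active, since
#' exchange inflates R2). The R2/R1 ratio of an isotropic rotor increases
#' monotonically with the correlation time, so the inversion is a
#' one-dimensional root find.
#'
#' @param records data frame with columns residue_id, r1, r2, het_noe
#' @param field_mhz 1H spectrometer frequency, MHz
#' @param noe_cut rigidity threshold on the heteronuclear NOE
#' @param exclude_ids residues to drop (e.g. exchange-active ones)
#' @param trim trimmed-mean fraction for the R2/R1 ratio
#' @param interval search interval for tau_c, s
#' @return list with tau_c (s), ratio used, and the residues entering the
#'   estimate
#' @export
estimate_tau_c <- function(records, field_mhz, noe_cut = 0.65,
                           exclude_ids = character(), trim = 0.1,
                           interval = c(0.5e-9, 50e-9)) {
  stopifnot(all(c("residue_id", "r1", "r2", "het_noe") %in% names(records)))
  rigid <- records[records$het_noe >= noe_cut &
                     !(records$residue_id %in% exclude_ids), , drop = FALSE]
  if (nrow(rigid) < 5)
    stop("need at least 5 rigid residues for the correlation-time ",
         "estimate; have ", nrow(rigid))
  ratio <- mean(rigid$r2 / rigid$r1, trim = trim)
  f <- function(tc) {
    r <- iso_rotor_rates(tc, field_mhz)
    r$r2 / r$r1 - ratio
  }
  root <- uniroot(f, interval, tol = 1e-13)
  list(tau_c = root$root, ratio = ratio,
       residues_used = rigid$residue_id)
}
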