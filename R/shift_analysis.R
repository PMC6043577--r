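#' Amide-proton temperature coefficient and hydrogen-bond classification
#'
#' Linear regression of the 1H shift (in ppb) on temperature. Coefficients
#' more positive than -5 ppb/K indicate an intramolecular hydrogen bond;
#' the inequality is strict, so a slope of exactly -5 ppb/K is classified
#' as not hydrogen-bonded. Adding a constant to all shifts leaves the
#' slope, and hence the classification, unchanged.
#'
#' @param series data frame with columns temp_k and h_ppm (1H shift, ppm)
#' @param cut classification threshold, ppb/K (default -5)
#' @return list with slope_ppb_k, slope_se, h_bonded (logical)
#' @export
temperature_coefficient <- function(series, cut = -5) {
  stopifnot(all(c("temp_k", "h_ppm") %in% names(series)))
  if (nrow(series) < 3) stop("need at least 3 temperatures")
  fit <- lm(I(h_ppm * 1000) ~ temp_k, data = series)
  slope <- coef(fit)[["temp_k"]]
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[["temp_k"]])
  list(slope_ppb_k = slope, slope_se = se, h_bonded = slope > cut)
}

#' Combined chemical-shift perturbation index
#'
#' Weighted 1H/15N displacement per residue between a free and a bound
#' spectrum, \code{sqrt(ddH^2 + (alpha * ddN)^2)} with the standard amide
#' nitrogen weighting alpha = 0.14, plus the mean-plus-one-standard-
#' deviation significance threshold used to call binding-site residues.
#'
#' @param free_shifts,bound_shifts data frames with columns residue_id,
#'   h_ppm, n_ppm; matched on residue_id
#' @param alpha nitrogen weighting factor
#' @return list with table (residue_id, csp_ppm, significant), threshold
#' @export
csp_index <- function(free_shifts, bound_shifts, alpha = 0.14) {
  need <- c("residue_id", "h_ppm", "n_ppm")
  stopifnot(all(need %in% names(free_shifts)),
            all(need %in% names(bound_shifts)))
  m <- merge(free_shifts[need], bound_shifts[need], by = "residue_id",
             suffixes = c("_free", "_bound"))
  if (!nrow(m)) stop("no overlapping residues between the two spectra")
  csp <- sqrt((m$h_ppm_bound - m$h_ppm_free)^2 +
                (alpha * (m$n_ppm_bound - m$n_ppm_free))^2)
  thr <- mean(csp) + sd(csp)
  list(table = data.frame(residue_id = m$residue_id, csp_ppm = csp,
                          significant = csp > thr),
       threshold = thr)
}

#' Fit the quadratic single-site binding isotherm to a titration
#'
#' Nonlinear least squares of the exact one-site isotherm
#' ([binding_isotherm()]) for the dissociation constant and the
#' full-saturation shift change, at known total protein concentration.
#' Series whose peaks disappeared during the titration are refused (their
#' shifts are not observable), and fits where the largest ligand
#' concentration does not reach the fitted KD are flagged as poorly
#' determined.
#'
#' @param series a \code{titration_series}
#' @return list with kd (M), kd_se, dw_max (ppm), dw_max_se, converged,
#'   poorly_determined, residue_id
#' @export
fit_binding_quadratic <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (isTRUE(attr(series, "disappeared")))
    stop("peak disappeared during titration; shifts cannot be fitted")
  pts <- series[series$l0_m > 0, , drop = FALSE]
  if (nrow(pts) < 4) stop("need at least 4 non-zero concentration points")
  p0 <- attr(series, "p_total")
  l0 <- pts$l0_m
  dw <- pts$dw_obs_ppm
  start <- list(kd = max(median(l0), 1e-9), dwmax = max(dw) * 1.2)
  fit <- try(minpack.lm::nlsLM(
    dw ~ binding_isotherm(l0, kd, dwmax, p0), start = start,
    lower = c(kd = 1e-12, dwmax = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(kd = NA_real_, kd_se = NA_real_, dw_max = NA_real_,
                dw_max_se = NA_real_, converged = FALSE,
                poorly_determined = TRUE,
                residue_id = attr(series, "residue_id")))
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(kd = NA_real_, dwmax = NA_real_))
  # non-saturating data leave (KD, dw_max) nearly collinear: flag fits
  # where the titration never approaches the fitted plateau, or where the
  # fitted KD lies beyond the sampled concentrations
  sat_frac <- if (co[["dwmax"]] > 0) max(dw) / co[["dwmax"]] else 0
  list(kd = co[["kd"]], kd_se = se[["kd"]], dw_max = co[["dwmax"]],
       dw_max_se = se[["dwmax"]], converged = TRUE,
       poorly_determined = max(l0) < co[["kd"]] || sat_frac < 0.5,
       residue_id = attr(series, "residue_id"))
}

#' Compare titration-derived and dispersion-derived shift differences
#'
#' Residue-by-residue comparison of the 15N shift difference between the
#' free/ground and bound/excited states obtained by the two independent
#' routes. Agreement indicates structural similarity between the excited
#' conformation probed by dispersion and the ligand-bound state probed by
#' titration; residues whose absolute difference exceeds the cutoff are
#' flagged as outliers.
#'
#' @param titration_dw named numeric vector, residue id -> ppm
#' @param dispersion_dw named numeric vector, residue id -> ppm
#' @param cutoff outlier threshold, ppm (default 0.5)
#' @return list with table (residue_id, dw_titration, dw_dispersion,
#'   abs_diff, outlier), outliers (ids) and the Pearson correlation
#' @export
compare_dw <- function(titration_dw, dispersion_dw, cutoff = 0.5) {
  common <- intersect(names(titration_dw), names(dispersion_dw))
  if (!length(common)) stop("no overlapping residues")
  tab <- data.frame(residue_id = common,
                    dw_titration = as.numeric(titration_dw[common]),
                    dw_dispersion = as.numeric(dispersion_dw[common]))
  tab$abs_diff <- abs(tab$dw_titration - tab$dw_dispersion)
  tab$outlier <- tab$abs_diff > cutoff
  corr <- if (nrow(tab) >= 3) cor(tab$dw_titration, tab$dw_dispersion)
    else NA_real_
  list(table = tab, outliers = tab$residue_id[tab$outlier],
       correlation = corr, cutoff = cutoff)
}
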