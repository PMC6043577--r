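#' Construct the two-state global parameter set
#'
#' The shared exchange model fitted to a dispersion dataset: one
#' (p_B, k_AB) pair per temperature (all residues share the exchange
#' process), one temperature- and field-independent shift difference (ppm)
#' per residue, and one intrinsic rate per residue and field, shared by the
#' two states and across temperatures. Derived quantities follow as
#' \code{k_BA = k_AB (1 - p_B) / p_B}, \code{k_ex = k_AB + k_BA},
#' \code{Ke = p_B / (1 - p_B)}.
#'
#' @param per_temperature data frame with columns temp_k, p_b, k_ab
#' @param dw_ppm named numeric vector, residue id -> |shift difference| ppm
#' @param r20 numeric matrix, rows = residue ids, columns = field (MHz as
#'   character), intrinsic rates 1/s
#' @return object of class \code{two_state_params}
#' @export
two_state_params <- function(per_temperature, dw_ppm, r20) {
  stopifnot(all(c("temp_k", "p_b", "k_ab") %in% names(per_temperature)),
            !is.null(names(dw_ppm)), is.matrix(r20))
  if (any(per_temperature$p_b <= 0 | per_temperature$p_b >= 0.5))
    stop("p_b must lie in (0, 0.5)")
  if (any(per_temperature$k_ab <= 0)) stop("k_ab must be positive")
  pt <- per_temperature
  pt$k_ba <- pt$k_ab * (1 - pt$p_b) / pt$p_b
  pt$k_ex <- pt$k_ab + pt$k_ba
  pt$ke <- pt$p_b / (1 - pt$p_b)
  structure(list(per_temperature = pt, dw_ppm = dw_ppm, r20 = r20),
            class = "two_state_params")
}

#' Extract the generating parameters of a synthetic truth
#' @param truth a \code{synthetic_truth}
#' @return the corresponding \code{two_state_params}
#' @export
params_from_truth <- function(truth) {
  two_state_params(truth$kinetics[c("temp_k", "p_b", "k_ab")],
                   truth$dw_ppm, truth$r20)
}

# precompute per-point indices used by the model/residual functions
.index_dataset <- function(dataset) {
  d <- as.data.frame(dataset)
  d <- d[is.finite(d$r2eff), , drop = FALSE]
  ids <- sort(unique(d$residue_id))
  temps <- sort(unique(d$temp_k))
  fields <- sort(unique(d$field_mhz))
  list(d = d, ids = ids, temps = temps, fields = fields,
       i_res = match(d$residue_id, ids),
       i_temp = match(d$temp_k, temps),
       i_field = match(d$field_mhz, fields),
       i_rf = (match(d$field_mhz, fields) - 1L) * length(ids) +
         match(d$residue_id, ids),
       hz_per_ppm = 2 * pi * .const$larmor_ratio_15n * d$field_mhz)
}

# model R2,eff for all points of an indexed dataset
.predict_indexed <- function(idx, kab_t, kba_t, dw_ppm_r, r20_rf, t_relax) {
  rex <- .bm_r2eff_cpp(kab_t[idx$i_temp], kba_t[idx$i_temp],
                       dw_ppm_r[idx$i_res] * idx$hz_per_ppm,
                       rep(0, nrow(idx$d)), idx$d$nu_cpmg_hz, t_relax)
  rex + r20_rf[idx$i_rf]
}

#' Chi-square target function of the global fit
#'
#' Sum over all points of squared, error-weighted differences between the
#' Bloch-McConnell model and the experimental R2,eff.
#'
#' @param params a \code{two_state_params}
#' @param dataset a \code{dispersion_dataset}
#' @param t_relax relaxation delay used in the experiment, s
#' @return the chi-square value
#' @export
chi_square <- function(params, dataset, t_relax = 0.030) {
  idx <- .index_dataset(dataset)
  miss <- setdiff(idx$ids, names(params$dw_ppm))
  if (length(miss))
    stop("no dw entry for residue(s): ", paste(miss, collapse = ", "))
  missr <- setdiff(idx$ids, rownames(params$r20))
  missf <- setdiff(as.character(idx$fields), colnames(params$r20))
  if (length(missr) || length(missf))
    stop("no R2,0 entry for ", paste(c(missr, missf), collapse = ", "))
  pt <- params$per_temperature
  it <- match(idx$temps, pt$temp_k)
  if (anyNA(it)) stop("no kinetics for temperature(s): ",
                      paste(idx$temps[is.na(it)], collapse = ", "))
  r20_rf <- as.vector(params$r20[idx$ids, as.character(idx$fields),
                                 drop = FALSE])
  calc <- .predict_indexed(idx, pt$k_ab[it], pt$k_ba[it],
                           params$dw_ppm[idx$ids], r20_rf, t_relax)
  sum(((calc - idx$d$r2eff) / idx$d$r2eff_err)^2)
}

# theta layout: [qlogis(pB_1..nT), log(kAB_1..nT), log(dw_1..nR)]
.theta_pack <- function(pb, kab, dw) c(qlogis(pb * 2) , log(kab), log(dw))
.theta_unpack <- function(theta, nT, nR) {
  list(pb = plogis(theta[seq_len(nT)]) / 2,      # maps to (0, 0.5)
       kab = exp(theta[nT + seq_len(nT)]),
       dw = exp(theta[2 * nT + seq_len(nR)]))
}

# residuals with the intrinsic rates profiled out analytically: for fixed
# kinetics and shifts the chi-square is quadratic in each (residue, field)
# R2,0, whose weighted least-squares solution is substituted directly
.make_residual_fn <- function(idx, t_relax) {
  nT <- length(idx$temps)
  nR <- length(idx$ids)
  w <- 1 / idx$d$r2eff_err^2
  sw_rf <- tapply(w, idx$i_rf, sum)
  function(theta) {
    p <- .theta_unpack(theta, nT, nR)
    kba <- p$kab * (1 - p$pb) / p$pb
    rex <- .bm_r2eff_cpp(p$kab[idx$i_temp], kba[idx$i_temp],
                         p$dw[idx$i_res] * idx$hz_per_ppm,
                         rep(0, nrow(idx$d)), idx$d$nu_cpmg_hz, t_relax)
    resid0 <- idx$d$r2eff - rex
    r20 <- tapply(w * resid0, idx$i_rf, sum) / sw_rf
    (rex + r20[as.character(idx$i_rf)] - idx$d$r2eff) /
      idx$d$r2eff_err
  }
}

.profiled_r20 <- function(idx, t_relax, theta) {
  nT <- length(idx$temps); nR <- length(idx$ids)
  p <- .theta_unpack(theta, nT, nR)
  kba <- p$kab * (1 - p$pb) / p$pb
  rex <- .bm_r2eff_cpp(p$kab[idx$i_temp], kba[idx$i_temp],
                       p$dw[idx$i_res] * idx$hz_per_ppm,
                       rep(0, nrow(idx$d)), idx$d$nu_cpmg_hz, t_relax)
  w <- 1 / idx$d$r2eff_err^2
  r20v <- tapply(w * (idx$d$r2eff - rex), idx$i_rf, sum) /
    tapply(w, idx$i_rf, sum)
  full <- rep(NA_real_, nR * length(idx$fields))
  full[as.integer(names(r20v))] <- r20v
  matrix(full, nrow = nR,
         dimnames = list(idx$ids, as.character(idx$fields)))
}

# crude fast-exchange initialization of the shift differences
.auto_init <- function(idx, pb0 = 0.05, kex0 = 1000) {
  nR <- length(idx$ids)
  dw <- numeric(nR)
  for (r in seq_len(nR)) {
    sel <- idx$i_res == r
    d <- idx$d[sel, , drop = FALSE]
    grp <- interaction(d$field_mhz, d$temp_k, drop = TRUE)
    rex <- vapply(split(seq_len(nrow(d)), grp), function(ii) {
      lo <- ii[which.min(d$nu_cpmg_hz[ii])]
      hi <- ii[which.max(d$nu_cpmg_hz[ii])]
      max(d$r2eff[lo] - d$r2eff[hi], 0.3)
    }, numeric(1))
    hz_ppm <- vapply(split(idx$hz_per_ppm[sel], grp), mean, numeric(1))
    dw_rad <- sqrt(rex * kex0 / (pb0 * (1 - pb0)))
    dw[r] <- min(max(median(dw_rad / hz_ppm), 0.2), 8)
  }
  nT <- length(idx$temps)
  .theta_pack(rep(pb0, nT), rep(pb0 * kex0, nT), dw)
}

#' Global two-state fit of a dispersion dataset
#'
#' Least-squares fit of the numerical Bloch-McConnell model to all
#' residues, fields and temperatures simultaneously, minimizing the
#' error-weighted chi-square. Fitted parameters: per-temperature
#' (p_B, k_AB), one shift difference (ppm) per residue shared across
#' temperatures and fields, and one intrinsic rate per residue and field
#' (shared between states and across temperatures). Rates are fitted on a
#' log scale and populations through a logit mapped onto (0, 0.5);
#' intrinsic rates are profiled out analytically at every step, which
#' reduces the nonlinear search space without changing the optimum.
#' Levenberg-Marquardt with multi-start: the automatic (or supplied)
#' initialization plus randomly perturbed restarts, keeping the best
#' chi-square.
#'
#' @param dataset a \code{dispersion_dataset}
#' @param init "auto" or a \code{two_state_params} to start from
#' @param t_relax relaxation delay, s
#' @param n_starts number of starts (>= 1; default 5)
#' @param seed integer seed for the restart perturbations
#' @param per_temperature logical; TRUE fits every temperature as an
#'   independent dataset (its own p_B, k_AB, shifts and intrinsic rates)
#'   instead of the joint model, for comparison
#' @param maxiter Levenberg-Marquardt iteration cap per start
#' @param ftol relative chi-square convergence tolerance
#' @return object of class \code{global_fit_result}: params
#'   (\code{two_state_params}), chi2, n_data, n_par, reduced_chi2,
#'   converged, seed; for the per-temperature mode, a list of such results
#' @export
fit_global <- function(dataset, init = "auto", t_relax = 0.030,
                       n_starts = 5, seed = 1L, per_temperature = FALSE,
                       maxiter = 200, ftol = 1e-10) {
  if (per_temperature) {
    temps <- sort(unique(dataset$temp_k))
    fits <- lapply(temps, function(tk) {
      sub <- dispersion_dataset(
        as.data.frame(dataset)[dataset$temp_k == tk, , drop = FALSE],
        excluded = attr(dataset, "excluded"))
      fit_global(sub, init = init, t_relax = t_relax, n_starts = n_starts,
                 seed = seed, per_temperature = FALSE, maxiter = maxiter,
                 ftol = ftol)
    })
    names(fits) <- as.character(temps)
    return(structure(list(per_temperature_fits = fits),
                     class = "global_fit_per_temperature"))
  }
  idx <- .index_dataset(dataset)
  nT <- length(idx$temps); nR <- length(idx$ids); nB <- length(idx$fields)
  n_data <- nrow(idx$d)
  n_par <- 2 * nT + nR + nR * nB
  if (n_data <= n_par)
    stop("underdetermined fit: ", n_data, " points for ", n_par,
         " parameters")
  resid_fn <- .make_residual_fn(idx, t_relax)

  if (identical(init, "auto")) {
    theta0 <- .auto_init(idx)
  } else {
    stopifnot(inherits(init, "two_state_params"))
    pt <- init$per_temperature[match(idx$temps, init$per_temperature$temp_k), ]
    theta0 <- .theta_pack(pt$p_b, pt$k_ab, init$dw_ppm[idx$ids])
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th <- if (s == 1L) theta0 else
      theta0 + rnorm(length(theta0), 0, c(rep(0.5, nT), rep(0.4, nT),
                                          rep(0.3, nR)))
    # exploratory starts get a reduced iteration budget; the winner is
    # polished below
    fit <- try(minpack.lm::nls.lm(
      par = th, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = if (s == 1L) maxiter else ceiling(maxiter / 4),
        ftol = ftol, ptol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  polish <- try(minpack.lm::nls.lm(
    par = best$par, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = 1e-10)), silent = TRUE)
  if (!inherits(polish, "try-error") && polish$deviance <= best$deviance)
    best <- polish

  p <- .theta_unpack(best$par, nT, nR)
  if (any(p$pb > 0.49))
    warning("p_B near the 0.5 identifiability bound; ",
            "state assignment is ill-determined", call. = FALSE)
  r20 <- .profiled_r20(idx, t_relax, best$par)
  params <- two_state_params(
    data.frame(temp_k = idx$temps, p_b = p$pb, k_ab = p$kab),
    setNames(p$dw, idx$ids), r20)
  converged <- best$info %in% 1:4
  if (!converged)
    warning("fit did not formally converge (info = ", best$info,
            "); best-so-far parameters returned", call. = FALSE)
  structure(list(params = params, chi2 = best$deviance, n_data = n_data,
                 n_par = n_par,
                 reduced_chi2 = best$deviance / (n_data - n_par),
                 converged = converged, seed = seed, theta = best$par,
                 hessian = best$hessian, idx_meta = list(
                   ids = idx$ids, temps = idx$temps, fields = idx$fields),
                 t_relax = t_relax),
            class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  pt <- x$params$per_temperature
  cat("global two-state fit:", x$n_data, "points,", x$n_par,
      "parameters, chi2 =", signif(x$chi2, 5),
      "(reduced", signif(x$reduced_chi2, 4), ")\n")
  cat(sprintf("  %s K: p_B = %.3f, k_ex = %.0f /s\n", pt$temp_k, pt$p_b,
              pt$k_ex), sep = "")
  if (!x$converged) cat("  [not converged]\n")
  invisible(x)
}

#' Parameter uncertainties of a global fit
#'
#' Covariance method: inverts the Gauss-Newton (J'J) approximation of the
#' chi-square curvature at the optimum and propagates to the natural scale
#' by the delta method; intrinsic-rate uncertainties are the conditional
#' weighted-least-squares errors. Bootstrap method: resamples the
#' error-scaled residuals, rebuilds synthetic rate sets and refits (single
#' start from the optimum).
#'
#' @param result a converged \code{global_fit_result}
#' @param dataset the dataset it was fitted to
#' @param method "covariance" or "bootstrap"
#' @param n_boot bootstrap replicates
#' @param seed integer RNG seed (bootstrap)
#' @return list with per_temperature (data frame of se of p_b, k_ab, k_ex),
#'   dw_ppm (named vector of se) and r20 (matrix of se)
#' @export
estimate_uncertainties <- function(result, dataset,
                                   method = c("covariance", "bootstrap"),
                                   n_boot = 200, seed = 1L) {
  method <- match.arg(method)
  idx <- .index_dataset(dataset)
  nT <- length(idx$temps); nR <- length(idx$ids)
  if (method == "covariance") {
    cv <- try(solve(result$hessian), silent = TRUE)
    if (inherits(cv, "try-error")) {
      ridge <- result$hessian +
        diag(1e-10 * max(diag(result$hessian)), nrow(result$hessian))
      cv <- solve(ridge)
    }
    # scale by the reduced chi-square so over- or under-stated data errors
    # (e.g. the 3 percent floor on noiseless synthetic data) do not bias
    # the parameter uncertainties
    se_th <- sqrt(pmax(diag(cv), 0) * result$reduced_chi2)
    p <- .theta_unpack(result$theta, nT, nR)
    # delta method through the link functions
    se_pb <- se_th[seq_len(nT)] * p$pb * (1 - 2 * p$pb)
    se_kab <- se_th[nT + seq_len(nT)] * p$kab
    se_dw <- se_th[2 * nT + seq_len(nR)] * p$dw
    kba <- p$kab * (1 - p$pb) / p$pb
    # first-order combination for k_ex = k_ab / p_b
    kex <- p$kab + kba
    se_kex <- kex * sqrt((se_kab / p$kab)^2 + (se_pb / p$pb)^2)
    w <- 1 / idx$d$r2eff_err^2
    se_r20v <- sqrt(result$reduced_chi2 / tapply(w, idx$i_rf, sum))
    se_r20 <- matrix(NA_real_, nR, length(idx$fields),
                     dimnames = list(idx$ids, as.character(idx$fields)))
    se_r20[as.integer(names(se_r20v))] <- se_r20v
    return(list(per_temperature = data.frame(
      temp_k = idx$temps, se_p_b = se_pb, se_k_ab = se_kab,
      se_k_ex = se_kex),
      dw_ppm = setNames(se_dw, idx$ids), r20 = se_r20))
  }
  # bootstrap on error-scaled residuals
  resid_fn <- .make_residual_fn(idx, result$t_relax)
  base_scaled <- resid_fn(result$theta)
  fitted_r2 <- idx$d$r2eff - base_scaled * idx$d$r2eff_err
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 2 * nT + nR)
  for (b in seq_len(n_boot)) {
    d2 <- idx
    d2$d$r2eff <- fitted_r2 +
      sample(base_scaled, length(base_scaled), replace = TRUE) *
      idx$d$r2eff_err
    rf <- .make_residual_fn(d2, result$t_relax)
    fb <- try(minpack.lm::nls.lm(
      par = result$theta, fn = rf,
      control = minpack.lm::nls.lm.control(maxiter = 50)), silent = TRUE)
    if (!inherits(fb, "try-error")) draws[b, ] <- fb$par
  }
  ok <- complete.cases(draws)
  p_list <- apply(draws[ok, , drop = FALSE], 1, function(th) {
    p <- .theta_unpack(th, nT, nR)
    c(p$pb, p$kab / p$pb, p$dw) # pb, kex, dw
  })
  sds <- apply(p_list, 1, sd)
  list(per_temperature = data.frame(
    temp_k = idx$temps, se_p_b = sds[seq_len(nT)],
    se_k_ex = sds[nT + seq_len(nT)]),
    dw_ppm = setNames(sds[2 * nT + seq_len(nR)], idx$ids),
    n_ok = sum(ok))
}
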