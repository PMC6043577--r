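#' Van't Hoff analysis of the excited-state equilibrium
#'
#' Linear regression of \code{ln(Ke)} on \code{1/T}: the slope is
#' \code{-dH_BA / R} and the intercept \code{dS_BA / R}. Unweighted by
#' default; optional weights (e.g. from global-fit uncertainties) are
#' applied as \code{lm} weights.
#'
#' @param ke_by_temperature data frame with columns temp_k and ke
#'   (equilibrium constant p_B / p_A, dimensionless, > 0)
#' @param weights optional regression weights
#' @return list with dh (J/mol), ds (J/(mol K)), their standard errors,
#'   and the underlying \code{lm} fit
#' @export
vant_hoff_fit <- function(ke_by_temperature, weights = NULL) {
  kt <- ke_by_temperature
  stopifnot(all(c("temp_k", "ke") %in% names(kt)))
  if (nrow(kt) < 3) stop("Van't Hoff fit needs at least 3 temperatures")
  if (any(kt$ke <= 0)) stop("equilibrium constants must be positive")
  R <- .const$R_gas
  df <- data.frame(y = log(kt$ke), x = 1 / kt$temp_k)
  fit <- if (is.null(weights)) lm(y ~ x, data = df) else
    lm(y ~ x, data = df, weights = weights)
  co <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  list(dh = -R * co[["x"]], ds = R * co[["(Intercept)"]],
       dh_se = R * se[["x"]], ds_se = R * se[["(Intercept)"]],
       fit = fit)
}

#' Eyring analysis of the transition state
#'
#' Linear regression of \code{ln(k_AB / T) - ln(kappa * k_B / h)} on
#' \code{1/T}: the slope is \code{-dH_act / R} and the intercept
#' \code{dS_act / R}. The transmission coefficient \code{kappa} rescales
#' the intercept only, so it shifts the activation entropy (by
#' \code{R * ln kappa}) and leaves the activation enthalpy untouched.
#'
#' @param kab_by_temperature data frame with columns temp_k and k_ab (1/s)
#' @param kappa transmission coefficient (default 1.6e-7, the fraction of
#'   transition-state molecules that proceed to product)
#' @param weights optional regression weights
#' @return list with dh (J/mol), ds (J/(mol K)), standard errors, kappa
#'   and the underlying \code{lm} fit
#' @export
eyring_fit <- function(kab_by_temperature, kappa = 1.6e-7,
                       weights = NULL) {
  kt <- kab_by_temperature
  stopifnot(all(c("temp_k", "k_ab") %in% names(kt)), kappa > 0)
  if (nrow(kt) < 3) stop("Eyring fit needs at least 3 temperatures")
  if (any(kt$k_ab <= 0)) stop("forward rates must be positive")
  R <- .const$R_gas
  df <- data.frame(
    y = log(kt$k_ab / kt$temp_k) - log(kappa * .const$k_B / .const$h),
    x = 1 / kt$temp_k)
  fit <- if (is.null(weights)) lm(y ~ x, data = df) else
    lm(y ~ x, data = df, weights = weights)
  co <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  list(dh = -R * co[["x"]], ds = R * co[["(Intercept)"]],
       dh_se = R * se[["x"]], ds_se = R * se[["(Intercept)"]],
       kappa = kappa, fit = fit)
}

#' Free-energy difference from a minor-state population
#'
#' \code{dG = -R T ln(p_B / (1 - p_B))}, the free energy of the excited
#' state relative to the ground state implied by its population.
#'
#' @param p_b minor-state population, in (0, 1)
#' @param temperature K
#' @return free-energy difference in J/mol
#' @export
delta_g_from_population <- function(p_b, temperature) {
  stopifnot(all(p_b > 0), all(p_b < 1), all(temperature > 0))
  -.const$R_gas * temperature * log(p_b / (1 - p_b))
}

#' Assemble excited- and transition-state thermodynamics
#'
#' Combines a Van't Hoff fit of the per-temperature equilibrium constants
#' with an Eyring fit of the forward rates into a single result that can
#' evaluate dG = dH - T dS for both state pairs at any temperature.
#'
#' @param kinetics data frame with columns temp_k, ke, k_ab (as produced by
#'   the global fit's per-temperature table)
#' @param kappa Eyring transmission coefficient
#' @param weights optional regression weights (applied to both fits)
#' @return object of class \code{thermo_result}: dh_ba, ds_ba, dh_act,
#'   ds_act (J/mol, J/(mol K)), their standard errors, kappa and the two lm
#'   fits
#' @export
thermo_analysis <- function(kinetics, kappa = 1.6e-7, weights = NULL) {
  vh <- vant_hoff_fit(kinetics, weights = weights)
  ey <- eyring_fit(kinetics, kappa = kappa, weights = weights)
  structure(list(dh_ba = vh$dh, ds_ba = vh$ds,
                 dh_ba_se = vh$dh_se, ds_ba_se = vh$ds_se,
                 dh_act = ey$dh, ds_act = ey$ds,
                 dh_act_se = ey$dh_se, ds_act_se = ey$ds_se,
                 kappa = kappa, vant_hoff = vh$fit, eyring = ey$fit),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("two-state thermodynamics (kJ/mol, J/(mol K)):\n")
  cat(sprintf("  excited state:    dH = %.1f, dS = %.1f\n",
              x$dh_ba / 1e3, x$ds_ba))
  cat(sprintf("  transition state: dH* = %.1f, dS* = %.1f (kappa = %g)\n",
              x$dh_act / 1e3, x$ds_act, x$kappa))
  invisible(x)
}

#' Evaluate dG, dH and T dS of a thermo result at a temperature
#' @param thermo a \code{thermo_result}
#' @param temperature K
#' @return data frame with rows "BA" and "act": dh, tds, dg (J/mol)
#' @export
thermo_at <- function(thermo, temperature) {
  data.frame(
    level = c("BA", "act"),
    dh = c(thermo$dh_ba, thermo$dh_act),
    tds = temperature * c(thermo$ds_ba, thermo$ds_act),
    dg = c(thermo$dh_ba - temperature * thermo$ds_ba,
           thermo$dh_act - temperature * thermo$ds_act))
}

#' Reaction-coordinate diagram data
#'
#' Three-level (ground state A, transition state, excited state B) energy
#' diagram at a temperature, relative to the ground state. The identity
#' dG = dH - T dS holds for every level by construction.
#'
#' @param thermo a \code{thermo_result}
#' @param temperature K
#' @return data frame: level (A, TS, B), dg, dh, tds (J/mol, relative to A)
#' @export
reaction_coordinate_diagram <- function(thermo, temperature) {
  at <- thermo_at(thermo, temperature)
  data.frame(
    level = c("A", "TS", "B"),
    dg = c(0, at$dg[at$level == "act"], at$dg[at$level == "BA"]),
    dh = c(0, at$dh[at$level == "act"], at$dh[at$level == "BA"]),
    tds = c(0, at$tds[at$level == "act"], at$tds[at$level == "BA"]))
}

#' Export thermodynamics as CSV and a plot-ready diagram JSON
#' @param thermo a \code{thermo_result}
#' @param temperature K for the diagram
#' @param csv_path,json_path output paths (NULL to skip)
#' @return the diagram data frame, invisibly
#' @export
write_thermo <- function(thermo, temperature = 298,
                         csv_path = NULL, json_path = NULL) {
  diag <- reaction_coordinate_diagram(thermo, temperature)
  if (!is.null(csv_path)) {
    tab <- data.frame(
      quantity = c("dh_ba", "ds_ba", "dh_act", "ds_act"),
      value = c(thermo$dh_ba, thermo$ds_ba, thermo$dh_act, thermo$ds_act),
      se = c(thermo$dh_ba_se, thermo$ds_ba_se, thermo$dh_act_se,
             thermo$ds_act_se),
      unit = c("J/mol", "J/(mol K)", "J/mol", "J/(mol K)"))
    write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(temperature_k = temperature, levels = diag),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(diag)
}
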