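#' Default thermodynamic truth for the synthetic two-state system
#'
#' Anchored so that at 298 K the minor-state population is 8.5 percent and
#' the exchange rate 812 1/s, with an excited-state enthalpy of -37 kJ/mol
#' (entropy follows from the population anchor, giving T*dS of about
#' -43 kJ/mol at 298 K) and an activation enthalpy of 50 kJ/mol (activation
#' entropy follows from the rate anchor given the transmission coefficient).
#'
#' @param pb_298 minor-state population at 298 K
#' @param kex_298 exchange rate at 298 K, 1/s
#' @param dh_ba excited-state enthalpy, J/mol
#' @param dh_act activation enthalpy, J/mol
#' @param kappa transmission coefficient of the Eyring relation
#' @return list with dh_ba, ds_ba, dh_act, ds_act (J/mol and J/(mol K)) and
#'   kappa
#' @export
default_thermo_truth <- function(pb_298 = 0.085, kex_298 = 812,
                                 dh_ba = -37e3, dh_act = 50e3,
                                 kappa = 1.6e-7) {
  R <- .const$R_gas
  T0 <- 298
  ke <- pb_298 / (1 - pb_298)
  ds_ba <- R * log(ke) + dh_ba / T0
  kab <- pb_298 * kex_298
  # ln(kab/T) = ln(kappa kB/h) + dS*/R - dH*/(R T)
  ds_act <- R * (log(kab / T0) - log(kappa * .const$k_B / .const$h)) +
    dh_act / T0
  list(dh_ba = dh_ba, ds_ba = ds_ba, dh_act = dh_act, ds_act = ds_act,
       kappa = kappa)
}

#' Kinetics implied by a thermodynamic truth at given temperatures
#'
#' Equilibrium constants follow the Van't Hoff relation and forward rates
#' the Eyring relation, so ln(Ke) and ln(k_AB/T) are exactly linear in 1/T.
#'
#' @param thermo_truth list as from [default_thermo_truth()]
#' @param temperatures K
#' @return data frame temp_k, k_ab, k_ba, p_b, k_ex, ke
#' @export
kinetics_from_thermo <- function(thermo_truth, temperatures) {
  R <- .const$R_gas
  tt <- thermo_truth
  ke <- exp(tt$ds_ba / R - tt$dh_ba / (R * temperatures))
  kab <- tt$kappa * (.const$k_B * temperatures / .const$h) *
    exp(tt$ds_act / R - tt$dh_act / (R * temperatures))
  kba <- kab / ke
  pb <- ke / (1 + ke)
  data.frame(temp_k = temperatures, k_ab = kab, k_ba = kba,
             p_b = pb, k_ex = kab + kba, ke = ke)
}

#' Generate a synthetic two-state exchange system
#'
#' Builds the ground truth for a relaxation-dispersion study: per-residue
#' 15N shift differences and per-residue-per-field intrinsic rates drawn
#' uniformly from the given intervals, and per-temperature kinetics derived
#' exactly from the thermodynamic truth, so the generated system is
#' thermodynamically self-consistent by construction.
#'
#' @param n_residues number of amide groups (default 22)
#' @param thermo_truth list as from [default_thermo_truth()]
#' @param temperatures K (default the five-temperature series 298.0 to
#'   308.0 K)
#' @param fields 1H spectrometer frequencies in MHz (default 500 and 700)
#' @param dw_range interval (ppm) for per-residue shift differences;
#'   generated positive since the single-quantum model depends only on the
#'   magnitude
#' @param r20_range interval (1/s) for intrinsic rates
#' @param noise_fraction intensity noise as a fraction of I0 (default 0.03)
#' @param seed integer RNG seed; same seed, same system
#' @return object of class \code{synthetic_truth}
#' @export
generate_two_state_system <- function(n_residues = 22,
                                      thermo_truth = default_thermo_truth(),
                                      temperatures = c(298.0, 300.5, 303.0,
                                                       305.5, 308.0),
                                      fields = c(500, 700),
                                      dw_range = c(0.5, 4),
                                      r20_range = c(8, 20),
                                      noise_fraction = 0.03,
                                      seed = 1L) {
  stopifnot(n_residues >= 1, length(temperatures) >= 1, length(fields) >= 1)
  if (any(temperatures < 250 | temperatures > 350))
    stop("temperatures outside the physically sensible 250-350 K range")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  kin <- kinetics_from_thermo(thermo_truth, temperatures)
  if (any(kin$p_b >= 0.5))
    stop("thermo_truth implies p_B >= 0.5 at ",
         paste(kin$temp_k[kin$p_b >= 0.5], collapse = ", "),
         " K; the minor state must stay minor for identifiability")
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n_residues))
  dw <- setNames(runif(n_residues, dw_range[1], dw_range[2]), ids)
  r20 <- matrix(runif(n_residues * length(fields), r20_range[1],
                      r20_range[2]),
                nrow = n_residues,
                dimnames = list(ids, as.character(fields)))
  structure(list(kinetics = kin, dw_ppm = dw, r20 = r20, fields = fields,
                 thermo_truth = thermo_truth,
                 noise_fraction = noise_fraction, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic two-state system:", length(x$dw_ppm), "residues,",
      nrow(x$kinetics), "temperatures,", length(x$fields), "fields\n")
  cat(sprintf("  p_B(%.1f K) = %.3f, k_ex = %.0f /s\n",
              x$kinetics$temp_k[1], x$kinetics$p_b[1], x$kinetics$k_ex[1]))
  invisible(x)
}

#' Default CPMG frequency series
#'
#' Twelve refocusing frequencies from 66.7 to 1000 Hz compatible with an
#' integer number of echo blocks in a 30 ms constant-time element.
#' @return numeric vector, Hz
#' @export
default_nu_cpmg <- function() {
  c(66.7, 133.3, 200, 266.7, 333.3, 400, 466.7, 533.3, 600, 666.7,
    866.7, 1000)
}

.check_nu_echo <- function(nu_cpmg, t_relax, tol = 0.05) {
  n <- 2 * t_relax * nu_cpmg
  bad <- abs(n - round(n)) > tol | round(n) < 1
  if (any(bad)) {
    closest <- pmax(round(n[bad]), 1) / (2 * t_relax)
    stop("nu_cpmg = ", paste(nu_cpmg[bad], collapse = ", "),
         " Hz incompatible with an integer echo-block count in t_relax = ",
         t_relax, " s; closest valid: ",
         paste(signif(closest, 6), collapse = ", "), " Hz")
  }
  invisible(TRUE)
}

#' Simulate CPMG peak intensities from a synthetic truth
#'
#' For every residue, field, temperature and CPMG frequency the intensity
#' is \code{I0 * exp(-R2eff * t_relax)} with R2,eff from the forward
#' Bloch-McConnell model, plus Gaussian noise with standard deviation
#' \code{noise_fraction * I0}. A reference (zero relaxation delay) row is
#' included per curve.
#'
#' @param truth a \code{synthetic_truth}
#' @param nu_cpmg CPMG frequencies, Hz (default [default_nu_cpmg()])
#' @param t_relax relaxation delay, s
#' @param i0 reference intensity (arbitrary units)
#' @param seed integer RNG seed for the noise draws
#' @return a peak-intensity table (see [peak_intensity_table()])
#' @export
generate_dispersion_intensities <- function(truth,
                                            nu_cpmg = default_nu_cpmg(),
                                            t_relax = 0.030, i0 = 1e6,
                                            seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), all(nu_cpmg > 0),
            t_relax > 0)
  .check_nu_echo(nu_cpmg, t_relax)
  ids <- names(truth$dw_ppm)
  design <- expand.grid(residue_id = ids, field_mhz = truth$fields,
                        temp_k = truth$kinetics$temp_k,
                        stringsAsFactors = FALSE)
  set.seed(seed)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    res <- design$residue_id[i]
    fld <- design$field_mhz[i]
    tk <- design$temp_k[i]
    kin <- truth$kinetics[truth$kinetics$temp_k == tk, ]
    r2 <- bm_r2eff(kin$k_ab, kin$k_ba, ppm_to_rad(truth$dw_ppm[res], fld),
                   truth$r20[res, as.character(fld)], nu_cpmg, t_relax)
    ints <- i0 * exp(-r2 * t_relax)
    noise <- truth$noise_fraction * i0
    if (noise > 0) {
      ints <- ints + rnorm(length(ints), 0, noise)
      iref <- i0 + rnorm(1, 0, noise)
    } else iref <- i0
    rows[[i]] <- data.frame(
      residue_id = res, field_mhz = fld, temp_k = tk,
      condition = c("reference", rep("cpmg", length(nu_cpmg))),
      nu_cpmg_hz = c(NA_real_, nu_cpmg),
      intensity = c(iref, ints))
  }
  peak_intensity_table(do.call(rbind, rows))
}

#' Simulate a single-exponential relaxation decay
#'
#' Intensities follow \code{i0 * exp(-rate * delay)} plus Gaussian noise
#' whose standard deviation is \code{noise_fraction} times the model
#' intensity at each delay (relative intensity noise).
#'
#' @param rate decay rate, 1/s (> 0)
#' @param delays relaxation delays, s (non-negative)
#' @param i0 intensity at zero delay
#' @param noise_fraction relative noise level (e.g. 0.02 for 2 percent)
#' @param seed integer RNG seed
#' @param residue_id label for the generated series
#' @return data frame residue_id, delay_s, intensity
#' @export
generate_relaxation_series <- function(rate, delays, i0 = 1e6,
                                       noise_fraction = 0, seed = 1L,
                                       residue_id = "R01") {
  stopifnot(rate > 0, all(delays >= 0))
  set.seed(seed)
  ints <- i0 * exp(-rate * delays)
  if (noise_fraction > 0)
    ints <- ints + rnorm(length(ints), 0, noise_fraction * ints)
  data.frame(residue_id = residue_id, delay_s = delays, intensity = ints)
}

#' Single-site binding curve (quadratic isotherm)
#'
#' Observed 15N shift change of a residue at total protein concentration
#' \code{p_total} and total ligand \code{l_total}, for dissociation constant
#' \code{kd} and full-saturation change \code{dw_max}:
#' \deqn{\Delta\omega_{obs} = \Delta\omega_{max}
#'   \frac{(K_D + L_0 + P_0) - \sqrt{(K_D + L_0 + P_0)^2 - 4 P_0 L_0}}
#'        {2 P_0}}
#'
#' @param l_total total ligand concentration(s), M
#' @param kd dissociation constant, M
#' @param dw_max shift change at full saturation, ppm
#' @param p_total total protein concentration, M
#' @return observed shift change, ppm
#' @export
binding_isotherm <- function(l_total, kd, dw_max, p_total) {
  s <- kd + l_total + p_total
  dw_max * (s - sqrt(pmax(s^2 - 4 * p_total * l_total, 0))) / (2 * p_total)
}

#' Simulate a ligand-titration shift series
#'
#' Shift changes follow the quadratic single-site isotherm
#' ([binding_isotherm()]) exactly before noise.
#'
#' @param kd dissociation constant, M
#' @param dw_max saturation shift change, ppm
#' @param p_total total protein concentration, M (default 80e-6)
#' @param ligand_concs total ligand concentrations, M
#' @param noise_sd Gaussian noise on the observed shifts, ppm
#' @param seed integer RNG seed
#' @param residue_id label
#' @return object of class \code{titration_series}: data frame l0_m,
#'   dw_obs_ppm with attributes residue_id, p_total, disappeared
#' @export
generate_titration_shifts <- function(kd, dw_max, p_total = 80e-6,
                                      ligand_concs = c(5, 10, 20, 40, 80,
                                                       120, 180, 250, 350,
                                                       500) * 1e-6,
                                      noise_sd = 0, seed = 1L,
                                      residue_id = "R01") {
  stopifnot(kd > 0, p_total > 0, all(ligand_concs >= 0))
  set.seed(seed)
  dw <- binding_isotherm(ligand_concs, kd, dw_max, p_total)
  if (noise_sd > 0) dw <- dw + rnorm(length(dw), 0, noise_sd)
  titration_series(data.frame(l0_m = ligand_concs, dw_obs_ppm = dw),
                   residue_id = residue_id, p_total = p_total)
}

#' Construct a titration series
#' @param points data frame l0_m, dw_obs_ppm
#' @param residue_id label
#' @param p_total total protein concentration, M
#' @param disappeared logical; peak vanished during the titration
#' @return object of class \code{titration_series}
#' @export
titration_series <- function(points, residue_id, p_total,
                             disappeared = FALSE) {
  stopifnot(all(c("l0_m", "dw_obs_ppm") %in% names(points)), p_total > 0)
  points <- points[order(points$l0_m), , drop = FALSE]
  structure(points, residue_id = residue_id, p_total = p_total,
            disappeared = disappeared,
            class = c("titration_series", "data.frame"))
}

#' Simulate an amide-shift-versus-temperature series
#'
#' @param slope temperature coefficient, ppb/K
#' @param temperatures K (at least 3)
#' @param intercept shift at 0 K, ppb (arbitrary reference)
#' @param noise_sd Gaussian noise, ppb
#' @param seed integer RNG seed
#' @param residue_id label
#' @return data frame residue_id, temp_k, h_ppm (1H shift in ppm)
#' @export
generate_temp_shift_series <- function(slope, temperatures,
                                       intercept = 8500, noise_sd = 0,
                                       seed = 1L, residue_id = "R01") {
  stopifnot(length(temperatures) >= 3)
  set.seed(seed)
  ppb <- intercept + slope * temperatures
  if (noise_sd > 0) ppb <- ppb + rnorm(length(ppb), 0, noise_sd)
  data.frame(residue_id = residue_id, temp_k = temperatures,
             h_ppm = ppb / 1000)
}

#' Generate a hollow atomic shell with analytically known cavity volume
#'
#' Atoms are placed on concentric spherical Fibonacci lattices (uniform
#' angular coverage) between \code{inner_radius + atom_radius} and
#' \code{outer_radius - atom_radius}, spaced by \code{packing_spacing}
#' both radially and on each sphere. The enclosed empty sphere has the
#' analytic volume \code{4/3 * pi * inner_radius^3}, recorded as ground
#' truth. A ray test from the cavity centre verifies the shell is
#' solvent-tight to the given probe; leaky shells are rejected.
#'
#' @param inner_radius cavity radius, Angstrom
#' @param outer_radius outer shell radius, Angstrom; must exceed
#'   \code{inner_radius + 2 * atom_radius}
#' @param atom_radius van der Waals radius assigned to every shell atom
#' @param packing_spacing centre-to-centre atom spacing, Angstrom
#' @param probe_radius probe the shell must be tight to (default 1.3)
#' @return a \code{structure_coords} object with attribute
#'   \code{true_cavity_volume}
#' @export
generate_hollow_structure <- function(inner_radius, outer_radius = NULL,
                                      atom_radius = 1.7,
                                      packing_spacing = 1.0,
                                      probe_radius = 1.3) {
  if (is.null(outer_radius))
    outer_radius <- inner_radius + 2 * atom_radius + 2
  stopifnot(inner_radius >= 0, packing_spacing > 0)
  if (outer_radius <= inner_radius + 2 * atom_radius)
    stop("outer_radius must exceed inner_radius + 2*atom_radius")
  r_lo <- inner_radius + atom_radius
  r_hi <- outer_radius - atom_radius
  radii <- unique(c(seq(r_lo, r_hi, by = packing_spacing), r_hi))
  pts <- do.call(rbind, lapply(radii, function(r) {
    n <- max(12L, ceiling(4 * pi * r^2 / packing_spacing^2 * 1.2))
    .fibonacci_sphere(n) * r
  }))
  atoms <- data.frame(element = "C", x = pts[, 1], y = pts[, 2],
                      z = pts[, 3], radius = atom_radius)
  sc <- structure_coords(atoms, source = "synthetic hollow shell")
  if (inner_radius > 0 &&
      .shell_leaky(pts, atom_radius, probe_radius))
    stop("shell is leaky to a ", probe_radius,
         " Angstrom probe; reduce packing_spacing")
  attr(sc, "true_cavity_volume") <- 4 / 3 * pi * inner_radius^3
  sc
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  th <- phi * i
  cbind(r * cos(th), r * sin(th), z)
}

# ray test: cast rays from the origin; the shell leaks if along some ray
# every atom stays further than atom_radius + probe_radius clearance from
# the ray line (a straight escape path of probe width exists)
.shell_leaky <- function(pts, atom_radius, probe_radius) {
  dirs <- .fibonacci_sphere(400L)
  block_r <- atom_radius + probe_radius
  for (d in seq_len(nrow(dirs))) {
    u <- dirs[d, ]
    tproj <- pts %*% u
    ahead <- tproj > 0
    if (!any(ahead)) return(TRUE)
    perp2 <- rowSums(pts[ahead, , drop = FALSE]^2) - tproj[ahead]^2
    if (min(perp2) > block_r^2) return(TRUE)
  }
  FALSE
}
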