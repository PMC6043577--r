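#' Run configuration with all analysis defaults
#'
#' Aggregates every numeric default of the pipeline in one validated list:
#' relaxation delay 0.030 s, 3 percent R2,eff error floor, 5 1/s exchange
#' filter, 0.65 heteronuclear-NOE flexibility cut, -5 ppb/K
#' temperature-coefficient cut, Eyring transmission coefficient 1.6e-7,
#' 1.3/3.0 Angstrom cavity probes with 0.5 Angstrom grid, and 0.14 CSP
#' nitrogen weighting. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above
#' @return a \code{run_config} list
#' @export
run_config <- function(...) {
  defaults <- list(
    t_relax = 0.030,          # s
    error_floor = 0.03,       # fraction of R2,eff
    delta_r2eff_threshold = 5,# 1/s
    nu_low = 66.7,            # Hz
    nu_high = 1000,           # Hz
    het_noe_cut = 0.65,
    tci_cut = -5,             # ppb/K
    kappa = 1.6e-7,
    small_probe = 1.3,        # Angstrom
    large_probe = 3.0,        # Angstrom
    grid_spacing = 0.5,       # Angstrom
    csp_alpha = 0.14,
    dw_outlier_cutoff = 0.5,  # ppm
    n_starts = 5,
    per_temperature = FALSE,
    seed = 1L,
    # inputs: either a peak-table CSV or a synthetic design
    peak_table = NULL,
    simulate = TRUE,
    n_residues = 22,
    noise_fraction = 0.03,
    pdb = NULL,               # optional structure for the cavity stage
    titration_kd = 50e-6,     # M, synthetic titration design
    titration_dwmax = 2,      # ppm
    p_total = 80e-6,          # M
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nknown keys: ", paste(names(defaults), collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: peak intensities (read or
#' simulated) -> R2,eff conversion -> exchange filter -> global two-state
#' fit -> Van't Hoff / Eyring thermodynamics, plus the independent
#' titration stage; the cavity stage runs when a structure is supplied.
#' Failure of one stage aborts its dependents but not independent stages.
#' Outputs (CSV per stage and a JSON report echoing every effective
#' parameter, the seeds and all warnings) are written to
#' \code{config$out_dir} when set.
#'
#' @param config a \code{run_config}
#' @return the run report, a list
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config"))
    stop("config must be created by run_config(); see ?run_config ",
         "for the schema")
  warnings_log <- character()
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  report <- list(package_version = as.character(
    utils::packageVersion("cpmgdyn")),
    config = unclass(config), seed = config$seed)

  truth <- NULL
  table <- NULL
  if (!is.null(config$peak_table)) {
    table <- read_peak_table(config$peak_table)
  } else if (isTRUE(config$simulate)) {
    truth <- generate_two_state_system(
      n_residues = config$n_residues,
      noise_fraction = config$noise_fraction, seed = config$seed)
    table <- generate_dispersion_intensities(
      truth, t_relax = config$t_relax, seed = config$seed)
    report$truth_kinetics <- truth$kinetics
  }

  disp <- fit <- thermo <- NULL
  if (!is.null(table)) {
    noise_sd <- if (!is.null(truth))
      truth$noise_fraction * max(table$intensity) else 0
    disp <- r2eff_from_intensities(table, t_relax = config$t_relax,
                                   noise_sd = noise_sd)
    sel <- select_exchange_residues(disp,
                                    threshold = config$delta_r2eff_threshold,
                                    nu_low = config$nu_low,
                                    nu_high = config$nu_high)
    report$exchange_residues <- sel$retained
    if (length(sel$retained) >= 2) {
      sub <- subset_residues(disp, sel$retained)
      fit <- tryCatch(
        fit_global(sub, t_relax = config$t_relax,
                   n_starts = config$n_starts, seed = config$seed,
                   per_temperature = config$per_temperature),
        error = function(e) { note("global fit failed: ",
                                   conditionMessage(e)); NULL })
    } else note("fewer than 2 exchange-active residues; fit skipped")
    if (!is.null(fit) && inherits(fit, "global_fit_result")) {
      report$fit <- list(chi2 = fit$chi2, n_data = fit$n_data,
                         n_par = fit$n_par,
                         reduced_chi2 = fit$reduced_chi2,
                         converged = fit$converged,
                         per_temperature = fit$params$per_temperature,
                         dw_ppm = as.list(fit$params$dw_ppm))
      thermo <- tryCatch(
        thermo_analysis(fit$params$per_temperature, kappa = config$kappa),
        error = function(e) { note("thermodynamic fits failed: ",
                                   conditionMessage(e)); NULL })
      if (!is.null(thermo))
        report$thermo <- list(
          dh_ba = thermo$dh_ba, ds_ba = thermo$ds_ba,
          dh_act = thermo$dh_act, ds_act = thermo$ds_act,
          diagram_298 = reaction_coordinate_diagram(thermo, 298))
    }
  }

  # titration stage (independent of the dispersion branch)
  tit <- generate_titration_shifts(
    kd = config$titration_kd, dw_max = config$titration_dwmax,
    p_total = config$p_total, seed = config$seed)
  bind_fit <- tryCatch(fit_binding_quadratic(tit),
                       error = function(e) { note("binding fit failed: ",
                                                  conditionMessage(e)); NULL })
  if (!is.null(bind_fit))
    report$binding <- bind_fit[c("kd", "kd_se", "dw_max", "dw_max_se",
                                 "poorly_determined")]

  if (!is.null(config$pdb)) {
    cav <- tryCatch(
      rolling_probe_volume(read_structure(config$pdb),
                           small_probe = config$small_probe,
                           large_probe = config$large_probe,
                           grid_spacing = config$grid_spacing),
      error = function(e) { note("cavity stage failed: ",
                                 conditionMessage(e)); NULL })
    if (!is.null(cav))
      report$cavity <- cav[c("cavity_volume", "component_volumes",
                             "small_probe", "large_probe", "grid_spacing")]
  }

  report$warnings <- warnings_log
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(disp))
      write_dispersion_csv(disp, file.path(config$out_dir,
                                           "dispersion_curves.csv"))
    if (!is.null(fit) && inherits(fit, "global_fit_result")) {
      pt <- fit$params$per_temperature
      flat <- rbind(
        data.frame(parameter = paste0("p_b_", pt$temp_k), value = pt$p_b),
        data.frame(parameter = paste0("k_ex_", pt$temp_k), value = pt$k_ex),
        data.frame(parameter = paste0("dw_", names(fit$params$dw_ppm)),
                   value = as.numeric(fit$params$dw_ppm)))
      write.csv(flat, file.path(config$out_dir, "fit_parameters.csv"),
                row.names = FALSE)
    }
    if (!is.null(thermo))
      write_thermo(thermo, 298,
                   csv_path = file.path(config$out_dir, "thermo.csv"),
                   json_path = file.path(config$out_dir, "diagram.json"))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(report)
}
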