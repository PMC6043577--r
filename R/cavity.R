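#' Construct structure coordinates for cavity analysis
#'
#' @param atoms data frame with columns element, x, y, z, radius (Angstrom)
#' @param model model number the coordinates came from
#' @param source free-text provenance tag
#' @return object of class \code{structure_coords}
#' @export
structure_coords <- function(atoms, model = 1L, source = "") {
  need <- c("element", "x", "y", "z", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("structure has no atoms")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$radius <= 0)) stop("radii must be positive")
  structure(list(atoms = atoms, model = model, source = source),
            class = "structure_coords")
}

#' @export
print.structure_coords <- function(x, ...) {
  cat("structure:", nrow(x$atoms), "atoms (model", x$model, ")",
      if (nzchar(x$source)) paste0("[", x$source, "]"), "\n")
  invisible(x)
}

#' Read a PDB structure for cavity analysis
#'
#' Parses ATOM/HETATM records (via bio3d), selects one model of a
#' multi-model (e.g. NMR ensemble) file, drops waters and hetero ligands
#' by default, and assigns Bondi van der Waals radii by element (H 1.20,
#' C 1.70, N 1.55, O 1.52, S 1.80 Angstrom; unknown elements fall back to
#' 1.70 with a warning). Hydrogens are kept when present.
#'
#' @param path PDB file path
#' @param model model number to extract (default 1)
#' @param keep_hetero keep non-water HETATM records (default FALSE)
#' @return a \code{structure_coords}
#' @export
read_structure <- function(path, model = 1L, keep_hetero = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model > nmod) stop("model ", model, " requested but file has ",
                         nmod, " model(s)")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  keep <- at$resid != "HOH"
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  if (!any(keep)) stop("no atoms left after filtering")
  elem <- at$elesy[keep]
  blank <- is.na(elem) | !nzchar(trimws(elem))
  # fall back on the first letter of the atom name when the element
  # column is absent
  elem[blank] <- substr(gsub("[^A-Za-z].*", "", at$elety[keep][blank]), 1, 1)
  elem <- toupper(trimws(elem))
  rad <- unname(.vdw_radii[elem])
  unknown <- is.na(rad)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(elem[unknown]), collapse = ", "),
            "; using fallback radius ", .vdw_fallback, " Angstrom",
            call. = FALSE)
    rad[unknown] <- .vdw_fallback
  }
  structure_coords(
    data.frame(element = elem, x = xyz[keep, 1], y = xyz[keep, 2],
               z = xyz[keep, 3], radius = rad),
    model = model, source = path)
}

#' Write structure coordinates as a minimal PDB file
#'
#' ATOM records only, occupancy 1.00 and B-factor 0.00; useful for
#' exporting synthetic structures and cavity grid points for inspection.
#'
#' @param coords a \code{structure_coords}, or a 3-column matrix of points
#'   (written as pseudo-atoms)
#' @param path output file
#' @export
write_structure_pdb <- function(coords, path) {
  if (inherits(coords, "structure_coords")) {
    a <- coords$atoms
    xyz <- as.numeric(t(as.matrix(a[c("x", "y", "z")])))
    elems <- a$element
  } else {
    xyz <- as.numeric(t(coords))
    elems <- rep("C", nrow(coords))
  }
  n <- length(xyz) / 3
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = elems, resid = rep("DUM", n),
                   chain = rep("A", n), resno = seq_len(n),
                   o = rep(1, n), b = rep(0, n), elesy = elems)
  invisible(path)
}

#' Internal-cavity volume by the two-probe rolling-probe method
#'
#' Grid-based difference method with a small (solvent-sized) and a large
#' probe. The solvent-excluded region of the large probe is computed with
#' accessibility: probe centres are flood-filled from the box boundary, so
#' interior voids and channels too narrow for the large probe stay
#' excluded. The molecular solid is computed with the small probe placed
#' anywhere it fits (no connectivity), so a cavity large enough to hold
#' the small probe is carved out of it whether or not it is connected to
#' bulk solvent. The cavity is the difference of the two regions,
#' decomposed into 6-connected components; components touching the box
#' boundary are bulk solvent artefacts and are discarded.
#'
#' @param coords a \code{structure_coords}
#' @param small_probe small probe radius, Angstrom (default 1.3,
#'   solvent-sized)
#' @param large_probe large probe radius, Angstrom (default 3.0)
#' @param grid_spacing grid step, Angstrom (default 0.5; must not exceed
#'   half the small probe radius)
#' @return object of class \code{cavity_result}: cavity_volume (A^3),
#'   component_volumes, small_probe, large_probe, grid_spacing,
#'   excluded volumes for both probes and the cavity grid points
#' @export
rolling_probe_volume <- function(coords, small_probe = 1.3,
                                 large_probe = 3.0, grid_spacing = 0.5) {
  stopifnot(inherits(coords, "structure_coords"),
            small_probe > 0, large_probe > small_probe)
  if (grid_spacing > small_probe / 2)
    stop("grid_spacing must be <= small_probe / 2 (",
         small_probe / 2, " Angstrom) for a reliable volume")
  a <- coords$atoms
  ext <- max(a$x) - min(a$x)
  res <- .cavity_grid_cpp(as.matrix(a[c("x", "y", "z")]), a$radius,
                          small_probe, large_probe, grid_spacing)
  if (ext < 2 * large_probe && res$cavity_volume == 0)
    warning("structure smaller than the large probe; zero cavity",
            call. = FALSE)
  structure(list(cavity_volume = res$cavity_volume,
                 component_volumes = sort(res$component_volumes,
                                          decreasing = TRUE),
                 small_probe = small_probe, large_probe = large_probe,
                 grid_spacing = grid_spacing,
                 excluded_volume_large = res$excluded_volume_large,
                 excluded_volume_small = res$excluded_volume_small,
                 cavity_points = res$cavity_points),
            class = "cavity_result")
}

#' @export
print.cavity_result <- function(x, ...) {
  cat(sprintf(
    "cavity volume: %.0f A^3 (%d component%s; probes %.1f/%.1f A, grid %.2f A)\n",
    x$cavity_volume, length(x$component_volumes),
    if (length(x$component_volumes) == 1) "" else "s",
    x$small_probe, x$large_probe, x$grid_spacing))
  invisible(x)
}

#' Export a cavity result as JSON
#' @param result a \code{cavity_result}
#' @param path output file
#' @param points_pdb optional path for a cavity-points pseudo-PDB
#' @export
write_cavity_json <- function(result, path, points_pdb = NULL) {
  out <- result[c("cavity_volume", "component_volumes", "small_probe",
                  "large_probe", "grid_spacing",
                  "excluded_volume_large", "excluded_volume_small")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(points_pdb) && nrow(result$cavity_points))
    write_structure_pdb(result$cavity_points, points_pdb)
  invisible(path)
}
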