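#' Configuration of the synthetic ensemble generator
#'
#' Collects and validates every parameter of the synthetic neutral/cation
#' trajectory generator. The defaults define the reference study conditions
#' used throughout the package tests: 200 snapshots per trajectory, three
#' conformational basins, guanine as the most easily oxidized base, and a
#' stacking enhancement of hole sharing between same-strand purines. See the
#' methods vignette for the rationale behind each default.
#'
#' @param n_frames Number of snapshots per trajectory (default 200).
#' @param n_basins Number of conformational basins M (default 3).
#' @param basin_weights Basin occupation probabilities, length `n_basins`,
#'   summing to 1 (default `c(0.5, 0.3, 0.2)`).
#' @param basin_energy_shifts Per-basin vertical-energy offsets (eV),
#'   default `c(-0.2, 0, 0.3)`.
#' @param mu_vie,mu_vae Basin-free mean vertical ionization / attachment
#'   energies (eV) before the system-dependent hole-stabilization shift
#'   (defaults 5.5 and 4.7).
#' @param sigma_within Within-basin spread of the vertical energies (eV,
#'   default 0.15).
#' @param site_energies Named vector of relative hole site energies per base
#'   type (eV); lower is easier to oxidize. Default orders G < A < C = T.
#' @param stacking_bonus Energy (eV) subtracted from the effective site
#'   energy of each base participating in a same-strand adjacent
#'   purine-purine pair (default 0.05).
#' @param t_eff Boltzmann-like smearing scale (eV) converting site energies
#'   into hole occupation weights (default 0.12).
#' @param charge_noise Dimensionless scale of the geometry-independent
#'   per-base log-weight noise; the per-base energetic noise has standard
#'   deviation `charge_noise * t_eff` (default 0.12).
#' @param leakage Fraction of the unit hole charge absorbed outside the
#'   8-base analysis region (backbone/outer layer); the emitted charge
#'   differences sum to `1 - leakage` (default 0.05).
#' @param stack_mixing Fraction of hole population symmetrically shared
#'   within each same-strand stacked purine-purine pair (doubly stochastic
#'   mixing; default 0.15).
#' @param trap_kappa Slope (eV per base-pair step) of the basin-specific
#'   hole-trapping potential along the helix (default 0.75).
#' @param trap_foci Focal base-pair position of the hole trap in each basin;
#'   `NULL` (default) picks fixed non-degenerate positions inside the
#'   analysis region.
#' @param trap_strand_penalty Energy (eV) disfavouring the strand opposite
#'   the basin's preferred strand (default 0.22).
#' @param trap_drift How far (base pairs per unit of the collective
#'   coordinate) the trap focus drifts with the within-basin conformational
#'   coordinate (default 0; the hole pattern is then basin-determined).
#' @param basin_displacement Spacing (length units) of the per-basin helix
#'   rise offsets; basins are internal axial-stretch deformations of the
#'   ideal helix (default 0.6).
#' @param rise_jitter Amplitude (length units) of the within-basin
#'   collective stretch mode driven by the coordinate `u` (default 0.1).
#' @param coord_noise Isotropic per-pseudo-atom coordinate jitter
#'   (length units, default 0.05).
#' @param geom_coupling Fraction of the within-basin energy variance carried
#'   by the collective coordinate `u` (hence visible to RMSD clustering);
#'   the remainder is environment noise (default 0.98).
#' @param seed Integer seed; every random draw in the generator derives from
#'   it (default 1).
#'
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_frames = 200L,
                             n_basins = 3L,
                             basin_weights = c(0.5, 0.3, 0.2),
                             basin_energy_shifts = c(-0.2, 0, 0.3),
                             mu_vie = 5.5,
                             mu_vae = 4.7,
                             sigma_within = 0.15,
                             site_energies = c(A = 0.25, C = 0.55, G = 0, T = 0.55),
                             stacking_bonus = 0.05,
                             t_eff = 0.12,
                             charge_noise = 0.12,
                             leakage = 0.05,
                             stack_mixing = 0.15,
                             trap_kappa = 0.75,
                             trap_foci = NULL,
                             trap_strand_penalty = 0.22,
                             trap_drift = 0,
                             basin_displacement = 0.6,
                             rise_jitter = 0.1,
                             coord_noise = 0.05,
                             geom_coupling = 0.98,
                             seed = 1L) {
  if (!is_count(n_frames, min = 2L)) stopf("n_frames must be an integer >= 2")
  if (!is_count(n_basins, min = 1L)) stopf("n_basins must be a positive integer")
  if (length(basin_weights) != n_basins) stopf("basin_weights must have length n_basins")
  if (any(basin_weights < 0) || any(basin_weights > 1)) {
    stopf("basin weights must lie in [0, 1]")
  }
  if (abs(sum(basin_weights) - 1) > 1e-12) stopf("basin weights must sum to 1 (within 1e-12)")
  if (length(basin_energy_shifts) != n_basins) {
    stopf("basin_energy_shifts must have length n_basins")
  }
  for (nm in c("mu_vie", "mu_vae", "stacking_bonus", "trap_kappa",
               "trap_strand_penalty", "trap_drift", "basin_displacement")) {
    if (!is_number(get(nm))) stopf("%s must be a finite number", nm)
  }
  for (nm in c("sigma_within", "charge_noise", "coord_noise", "rise_jitter")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stopf("%s must be a non-negative number", nm)
  }
  if (!is_number(t_eff) || t_eff <= 0) stopf("t_eff must be > 0")
  if (!is_number(leakage) || leakage < 0 || leakage >= 1) stopf("leakage must be in [0, 1)")
  if (!is_number(stack_mixing) || stack_mixing < 0 || stack_mixing > 0.5) {
    stopf("stack_mixing must be in [0, 0.5]")
  }
  if (!is_number(geom_coupling) || geom_coupling < 0 || geom_coupling > 1) {
    stopf("geom_coupling must be in [0, 1]")
  }
  if (!all(DNA_BASES %in% names(site_energies))) {
    stopf("site_energies must name all of %s", paste(DNA_BASES, collapse = ", "))
  }
  if (is.null(trap_foci)) {
    trap_foci <- if (n_basins == 3L) c(5.3, 7.6, 6.4) else
      seq(5.2, 7.8, length.out = max(n_basins, 2L))[seq_len(n_basins)]
  }
  if (length(trap_foci) != n_basins) stopf("trap_foci must have length n_basins")
  if (!is_count(seed, min = 0L)) stopf("seed must be a non-negative integer")

  structure(
    list(n_frames = as.integer(n_frames), n_basins = as.integer(n_basins),
         basin_weights = as.numeric(basin_weights),
         basin_energy_shifts = as.numeric(basin_energy_shifts),
         mu_vie = mu_vie, mu_vae = mu_vae, sigma_within = sigma_within,
         site_energies = site_energies[DNA_BASES],
         stacking_bonus = stacking_bonus, t_eff = t_eff,
         charge_noise = charge_noise, leakage = leakage,
         stack_mixing = stack_mixing, trap_kappa = trap_kappa,
         trap_foci = as.numeric(trap_foci),
         trap_strand_penalty = trap_strand_penalty, trap_drift = trap_drift,
         basin_displacement = basin_displacement, rise_jitter = rise_jitter,
         coord_noise = coord_noise, geom_coupling = geom_coupling,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic ensemble generator configuration\n")
  cat(sprintf("  %d frames, %d basins (weights %s; energy shifts %s eV)\n",
              x$n_frames, x$n_basins,
              paste(x$basin_weights, collapse = "/"),
              paste(x$basin_energy_shifts, collapse = "/")))
  cat(sprintf("  mu_VIE %.2f eV, mu_VAE %.2f eV, sigma_within %.2f eV\n",
              x$mu_vie, x$mu_vae, x$sigma_within))
  cat(sprintf("  site energies (eV): %s; stacking bonus %.2f; t_eff %.2f\n",
              paste(names(x$site_energies), x$site_energies, sep = "=",
                    collapse = " "), x$stacking_bonus, x$t_eff))
  cat(sprintf("  charge noise %.2f, leakage %.2f, stack mixing %.2f\n",
              x$charge_noise, x$leakage, x$stack_mixing))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
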