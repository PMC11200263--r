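# Marcus linear-response redox statistics from VIE/VAE ensembles.
#
# Within linear response, the Gibbs free energy of one-electron oxidation is
# the mean of the two vertical energy gaps sampled on the neutral and the
# oxidized ensemble,
#     dG_ox = (<VIE> + <VAE>) / 2,
# and the oxidation potential on the experimental scale is obtained by
# referencing against the absolute potential of the standard hydrogen
# electrode (whose literature value already contains the gas-phase free
# energy of the electron),
#     E_ox = dG_ox / e - E_SHE.
# The reorganization energy diagnostic is lambda = (<VIE> - <VAE>) / 2.
# Both vertical energies are stored in the same cation-minus-neutral
# orientation, so mean VIE and VAE are positive for physically sensible
# input; a negative mean VIE is rejected as a probable sign-convention error.

#' Reference electrode for the potential scale
#'
#' @param she_potential Absolute potential of the standard hydrogen
#'   electrode in V (default 4.28, the value commonly used with vertical-gap
#'   thermodynamic cycles; it absorbs the gas-phase free energy of the
#'   electron).
#' @param note Free-text provenance string.
#' @return An object of class `reference_electrode`.
#' @export
reference_electrode <- function(she_potential = 4.28,
                                note = "absolute SHE potential, electron term included") {
  if (!is_number(she_potential) || she_potential <= 0) {
    stopf("she_potential must be a positive number (V)")
  }
  structure(list(she_potential = she_potential, note = note),
            class = "reference_electrode")
}

#' Ensemble means and standard deviations of the vertical energies
#'
#' @param neutral,cation `ddna_trajectory` objects (or bare numeric vectors
#'   of energies in eV) for the neutral and cation trajectories. Each needs
#'   at least 2 records; state labels, when present, must match.
#' @return Named list `mean_vie`, `sd_vie`, `mean_vae`, `sd_vae`,
#'   `n_neutral`, `n_cation` (sample SDs, n-1 denominator).
#' @export
ensemble_means <- function(neutral, cation) {
  vie <- trajectory_energies(neutral, "neutral")
  vae <- trajectory_energies(cation, "cation")
  list(mean_vie = mean(vie), sd_vie = stats::sd(vie),
       mean_vae = mean(vae), sd_vae = stats::sd(vae),
       n_neutral = length(vie), n_cation = length(vae))
}

trajectory_energies <- function(x, expected_state) {
  if (inherits(x, "ddna_trajectory")) {
    if (!identical(x$state, expected_state)) {
      if (length(unique(x$state)) > 1L) stopf("mixed state labels in trajectory")
      stopf("expected a %s trajectory, got %s", expected_state, x$state)
    }
    x <- x$energy
  }
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("empty trajectory")
  if (length(x) < 2L) stopf("need at least 2 records per trajectory")
  if (any(!is.finite(x))) stopf("non-finite vertical energies")
  x
}

#' Marcus one-electron oxidation potential from two vertical-energy ensembles
#'
#' The central estimator of the package: combines the ensemble statistics of
#' the vertical ionization energies (neutral trajectory) and vertical
#' attachment energies (cation trajectory) into the linear-response
#' oxidation free energy, the oxidation potential versus the reference
#' electrode, and the reorganization-energy diagnostic. The SD of `e_ox` is
#' propagated treating the two trajectories as independent:
#' `sqrt(sd_vie^2 + sd_vae^2) / 2`.
#'
#' @param neutral,cation `ddna_trajectory` objects or numeric energy vectors
#'   (eV); see [ensemble_means()].
#' @param electrode A [reference_electrode()].
#' @param system Optional [dna_duplex()] or system name used for labelling
#'   and the purine-arrangement annotation.
#' @return An object of class `marcus_redox` with fields `mean_vie`,
#'   `sd_vie`, `mean_vae`, `sd_vae`, `dg_ox` (eV), `e_ox` (V vs SHE),
#'   `sd_eox` (V), `lambda_reorg` (eV), `n_neutral`, `n_cation`, `system`,
#'   `arrangement`, `electrode`.
#' @examples
#' m <- marcus_redox(c(5.3, 5.5), c(4.7, 4.9))
#' coef(m)
#' @export
marcus_redox <- function(neutral, cation, electrode = reference_electrode(),
                         system = NULL) {
  stopifnot(inherits(electrode, "reference_electrode"))
  mm <- ensemble_means(neutral, cation)
  oxidation_potential(mm, electrode = electrode, system = system)
}

#' Oxidation potential from precomputed ensemble means
#'
#' Lower-level constructor used by [marcus_redox()]; takes the output of
#' [ensemble_means()] (or any list with `mean_vie`, `sd_vie`, `mean_vae`,
#' `sd_vae`).
#'
#' @param means List with the four ensemble statistics (eV).
#' @inheritParams marcus_redox
#' @return A `marcus_redox` object; see [marcus_redox()].
#' @export
oxidation_potential <- function(means, electrode = reference_electrode(),
                                system = NULL) {
  m <- means
  for (nm in c("mean_vie", "mean_vae")) {
    if (!is_number(m[[nm]])) stopf("%s must be finite", nm)
  }
  if (m$mean_vie < 0) {
    stopf("negative mean VIE: energies must use the cation-minus-neutral sign convention")
  }
  sd_vie <- if (is.null(m$sd_vie)) 0 else m$sd_vie
  sd_vae <- if (is.null(m$sd_vae)) 0 else m$sd_vae
  dg <- (m$mean_vie + m$mean_vae) / 2
  lambda <- (m$mean_vie - m$mean_vae) / 2
  if (lambda < 0) {
    warnf("negative reorganization energy (%.3f eV): check trajectory assignment", lambda)
  }
  sysname <- NULL; arr <- NA_character_
  if (inherits(system, "dna_duplex")) {
    sysname <- system$name; arr <- system$arrangement
  } else if (is.character(system)) sysname <- system
  structure(
    list(mean_vie = m$mean_vie, sd_vie = sd_vie,
         mean_vae = m$mean_vae, sd_vae = sd_vae,
         dg_ox = dg, e_ox = dg - electrode$she_potential,
         sd_eox = sqrt(sd_vie^2 + sd_vae^2) / 2,
         lambda_reorg = lambda,
         n_neutral = m$n_neutral %||% NA_integer_,
         n_cation = m$n_cation %||% NA_integer_,
         system = sysname %||% NA_character_, arrangement = arr,
         electrode = electrode),
    class = "marcus_redox"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marcus_redox <- function(x, digits = 3, ...) {
  cat("Marcus linear-response oxidation potential\n")
  if (!is.na(x$system)) cat(sprintf("  system: %s\n", x$system))
  cat(sprintf("  <VIE> = %.*f (sd %.*f) eV   <VAE> = %.*f (sd %.*f) eV\n",
              digits, x$mean_vie, digits, x$sd_vie,
              digits, x$mean_vae, digits, x$sd_vae))
  cat(sprintf("  dG_ox = %.*f eV   lambda = %.*f eV\n",
              digits, x$dg_ox, digits, x$lambda_reorg))
  cat(sprintf("  E_ox  = %.*f +/- %.*f V vs SHE (%.2f V)\n",
              digits, x$e_ox, digits, x$sd_eox, x$electrode$she_potential))
  invisible(x)
}

#' @export
summary.marcus_redox <- function(object, ...) {
  print(object, ...)
  if (!is.na(object$n_neutral)) {
    cat(sprintf("  frames: %d neutral, %d cation\n",
                object$n_neutral, object$n_cation))
  }
  invisible(object)
}

#' @export
coef.marcus_redox <- function(object, ...) {
  c(e_ox = object$e_ox, dg_ox = object$dg_ox,
    lambda_reorg = object$lambda_reorg)
}

#' Rank duplex systems by oxidation potential
#'
#' Orders a set of [marcus_redox()] summaries by increasing `e_ox`
#' (decreasing reducing power), keeping the purine-arrangement annotation.
#' Ties retain their input order.
#'
#' @param summaries A list of `marcus_redox` objects (at least 1).
#' @return A data frame with columns `system`, `e_ox`, `sd_eox`,
#'   `lambda_reorg`, `arrangement`, sorted by `e_ox`.
#' @export
compare_systems <- function(summaries) {
  if (inherits(summaries, "marcus_redox")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "marcus_redox")))
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(system = s$system, e_ox = s$e_ox, sd_eox = s$sd_eox,
               lambda_reorg = s$lambda_reorg, arrangement = s$arrangement,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$e_ox), , drop = FALSE]  # stable sort: ties keep input order
  rownames(tab) <- NULL
  tab
}
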