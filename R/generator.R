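# Synthetic ensemble generator: seeded neutral/cation trajectories with
# closed-form ground truth. Emulates the statistical structure of MD + QM/MM
# snapshot ensembles of a 12-bp duplex: multi-basin conformational
# heterogeneity, base-type-dependent hole affinity, and same-strand purine
# stacking enhancement of hole delocalization.

N_PSEUDO_ATOMS <- 72L  # 24 bases x 3 pseudo-atoms

# Effective hole site energies over the 8 analysis-region bases:
# base-type energy minus the stacking bonus for members of same-strand
# adjacent purine-purine pairs.
site_energies_qm1 <- function(system, config) {
  eps <- unname(config$site_energies[system$qm1$base])
  eps - config$stacking_bonus * system$qm1$stacked_purine
}

# Boltzmann free energy of the hole over the analysis region; shifts both
# mean VIE and mean VAE so that guanine- and stacking-rich duplexes are
# easier to oxidize.
hole_free_energy <- function(system, config) {
  eps <- site_energies_qm1(system, config)
  -config$t_eff * log(sum(exp(-eps / config$t_eff)))
}

# Doubly stochastic mixing matrix sharing hole population within each
# same-strand stacked purine-purine pair. Symmetric with unit row sums, so
# applying it can only increase both delocalization indices.
stack_mixing_matrix <- function(system, config) {
  M <- diag(8)
  s <- config$stack_mixing
  pp <- system$stacking_pairs[system$stacking_pairs$purine_purine, , drop = FALSE]
  if (s > 0 && nrow(pp)) {
    for (r in seq_len(nrow(pp))) {
      i <- pp$i[r]; j <- pp$j[r]
      M[i, i] <- M[i, i] - s / 2; M[j, j] <- M[j, j] - s / 2
      M[i, j] <- M[i, j] + s / 2; M[j, i] <- M[j, i] + s / 2
    }
    if (any(diag(M) < 0)) stopf("stack_mixing too large for the stacking topology")
  }
  M
}

# Per-frame hole fractions for given basins, collective coordinates and
# per-base noise. basin, u: length-n vectors; nu: n x 8 matrix (standard
# normal). Returns an n x 8 matrix of true hole fractions.
charge_model <- function(system, config, basin, u, nu) {
  n <- length(basin)
  eps <- site_energies_qm1(system, config)
  pair <- system$qm1$pair
  strand <- system$qm1$strand
  pref <- rep(c("A", "B"), length.out = config$n_basins)
  focus <- config$trap_foci[basin] + config$trap_drift * u       # length n
  trap <- config$trap_kappa * abs(outer(focus, pair, "-")) +
    config$trap_strand_penalty *
      outer(pref[basin], strand, FUN = function(a, b) as.numeric(a != b))
  l <- sweep(-trap, 2L, eps, "-") / config$t_eff + config$charge_noise * nu
  f <- softmax_rows(l)
  f %*% stack_mixing_matrix(system, config)
}

# Nominal neutral-state fragment charges per base type (e); arbitrary but
# fixed, they cancel in the charge differences.
NEUTRAL_BASE_CHARGE <- c(A = -0.03, C = 0.02, G = -0.05, T = 0.01)

# Ideal-helix pseudo-atom template: 3 pseudo-atoms per base at radii 3/6/9,
# helical twist 36 degrees per step, given rise. Returns a 72 x 3 matrix in
# the order strand A pairs 1..12 then strand B pairs 1..12.
helix_coords <- function(rise, twist_deg = 36) {
  p <- 1:12
  z <- rise * (p - 6.5)
  ang_a <- twist_deg * pi / 180 * p
  ang_b <- ang_a + 140 * pi / 180
  radii <- c(3, 6, 9)
  one_strand <- function(ang) {
    do.call(rbind, lapply(p, function(k) {
      cbind(radii * cos(ang[k]), radii * sin(ang[k]), rep(z[k], 3L))
    }))
  }
  rbind(one_strand(ang_a), one_strand(ang_b))
}

basin_rise_offsets <- function(config) {
  m <- seq_len(config$n_basins)
  config$basin_displacement * (m - (config$n_basins + 1) / 2)
}

#' Emit per-base charge pairs for a single synthetic snapshot
#'
#' Computes the neutral-state and cation-state partial charge of each of the
#' 8 analysis-region bases for one frame, at a given latent basin and
#' collective coordinate. The true hole fraction of base i follows a
#' Boltzmann-like weight over the effective site energies (base type,
#' stacking bonus, basin-specific trapping potential, per-base noise), and
#' the cation-state charge is the neutral-state charge plus the hole
#' fraction scaled by `1 - leakage`.
#'
#' @param system A [dna_duplex()] object.
#' @param frame_seed Integer seed for this frame's noise.
#' @param config A [generator_config()].
#' @param basin Latent basin index of the frame (default 1).
#' @param u Within-basin collective coordinate (default 0; standard normal
#'   in sampled trajectories).
#' @return Data frame with one row per analysis-region base: `label`,
#'   `base`, `q_neutral`, `q_cation`, and `hole_truth` (the true fraction
#'   before leakage scaling).
#' @export
emit_charges <- function(system, frame_seed, config, basin = 1L, u = 0) {
  stopifnot(inherits(system, "dna_duplex"), inherits(config, "generator_config"))
  if (config$t_eff <= 0) stopf("t_eff must be > 0")
  if (!basin %in% seq_len(config$n_basins)) stopf("basin out of range")
  nu <- with_seed(frame_seed, matrix(stats::rnorm(8), 1L, 8L))
  f <- charge_model(system, config, basin = basin, u = u, nu = nu)[1L, ]
  q_neu <- unname(NEUTRAL_BASE_CHARGE[system$qm1$base])
  data.frame(label = system$qm1$label, base = system$qm1$base,
             q_neutral = q_neu,
             q_cation = q_neu + (1 - config$leakage) * f,
             hole_truth = f, stringsAsFactors = FALSE)
}

#' Generate a synthetic neutral or cation trajectory
#'
#' Draws `n_frames` snapshots: each frame is assigned a latent basin with the
#' configured weights; its vertical energy is the state mean (`mu_vie` or
#' `mu_vae`) plus the system's hole-stabilization free energy, the basin
#' shift, and a within-basin Normal(0, `sigma_within`) term of which a
#' fraction `geom_coupling` of the variance rides on the frame's collective
#' coordinate `u`; coordinates are an ideal-helix pseudo-atom template
#' deformed by the basin's axial stretch and the collective mode, plus
#' isotropic jitter; per-base charges come from the hole model (see
#' [emit_charges()]). Identical `(system, state, config, seed)` give
#' bit-identical output.
#'
#' @param system A [dna_duplex()] object.
#' @param state `"neutral"` (energies are VIEs) or `"cation"` (VAEs, stored
#'   in the same cation-minus-neutral orientation as VIEs).
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to the config seed. The actual stream
#'   is derived from `(seed, system, state)` so the two trajectories of a
#'   system are independent.
#' @return A `ddna_trajectory` object: vertical energies, per-base charge
#'   matrices, pseudo-atom coordinates (`n_frames x 72 x 3`), and the latent
#'   basin labels and collective coordinates (kept for testing).
#' @export
sample_trajectory <- function(system, state = c("neutral", "cation"),
                              config = generator_config(), seed = NULL) {
  stopifnot(inherits(system, "dna_duplex"), inherits(config, "generator_config"))
  state <- match.arg(state)
  if (config$n_frames < 2L) stopf("n_frames < 2: ensemble statistics undefined")
  if (is.null(seed)) seed <- config$seed
  sub <- derive_seed(seed, system$name, state)
  n <- config$n_frames

  dat <- with_seed(sub, {
    basin <- sample.int(config$n_basins, n, replace = TRUE, prob = config$basin_weights)
    u <- stats::rnorm(n)
    xi <- stats::rnorm(n)
    nu <- matrix(stats::rnorm(n * 8L), n, 8L)
    cnoise <- array(stats::rnorm(n * N_PSEUDO_ATOMS * 3L, sd = config$coord_noise),
                    dim = c(n, N_PSEUDO_ATOMS, 3L))
    list(basin = basin, u = u, xi = xi, nu = nu, cnoise = cnoise)
  })

  mu <- if (state == "neutral") config$mu_vie else config$mu_vae
  mu_sys <- mu + hole_free_energy(system, config)
  g <- config$geom_coupling
  energy <- mu_sys + config$basin_energy_shifts[dat$basin] +
    config$sigma_within * (sqrt(g) * dat$u + sqrt(1 - g) * dat$xi)

  f <- charge_model(system, config, dat$basin, dat$u, dat$nu)
  q_neu <- matrix(rep(unname(NEUTRAL_BASE_CHARGE[system$qm1$base]), each = n), n, 8L)
  q_cat <- q_neu + (1 - config$leakage) * f
  colnames(q_neu) <- colnames(q_cat) <- colnames(f) <- system$qm1$label

  rises <- 3.4 + basin_rise_offsets(config)[dat$basin] + config$rise_jitter * dat$u
  coords <- array(NA_real_, dim = c(n, N_PSEUDO_ATOMS, 3L))
  for (i in seq_len(n)) {
    coords[i, , ] <- helix_coords(rises[i]) + dat$cnoise[i, , ]
  }

  new_trajectory(system_name = system$name, state = state,
                 frame_id = seq_len(n), energy = energy,
                 q_neutral = q_neu, q_cation = q_cat, coords = coords,
                 latent = data.frame(basin = dat$basin, u = dat$u),
                 qm1_labels = system$qm1$label)
}

new_trajectory <- function(system_name, state, frame_id, energy, q_neutral,
                           q_cation, coords = NULL, latent = NULL, qm1_labels) {
  structure(
    list(system_name = system_name, state = state,
         frame_id = as.integer(frame_id), energy = as.numeric(energy),
         q_neutral = q_neutral, q_cation = q_cation, coords = coords,
         latent = latent, qm1_labels = qm1_labels),
    class = "ddna_trajectory"
  )
}

n_frames <- function(traj) length(traj$frame_id)

#' @export
print.ddna_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory of %s: %d frames\n", x$state, x$system_name,
              n_frames(x)))
  lab <- if (identical(x$state, "neutral")) "VIE" else "VAE"
  cat(sprintf("  %s: mean %.3f eV, sd %.3f eV\n", lab, mean(x$energy),
              stats::sd(x$energy)))
  if (!is.null(x$coords)) {
    cat(sprintf("  coordinates: %d pseudo-atoms per frame\n", dim(x$coords)[2]))
  }
  invisible(x)
}

#' Simulate a trajectory from a duplex system
#'
#' `simulate()` method for [dna_duplex()] objects; a thin wrapper around
#' [sample_trajectory()].
#'
#' @param object A `dna_duplex`.
#' @param nsim Number of frames (overrides `config$n_frames` if given).
#' @param seed Seed passed to [sample_trajectory()].
#' @param state,config See [sample_trajectory()].
#' @param ... Unused.
#' @return A `ddna_trajectory`.
#' @export
simulate.dna_duplex <- function(object, nsim = NULL, seed = NULL,
                                state = "neutral",
                                config = generator_config(), ...) {
  if (!is.null(nsim)) {
    cfg <- unclass(config); cfg$n_frames <- as.integer(nsim)
    config <- do.call(generator_config, cfg[setdiff(names(cfg), NULL)])
  }
  sample_trajectory(object, state = state, config = config, seed = seed)
}

#' Closed-form ground truth for a synthetic configuration
#'
#' Computes, without any sampling, the analytic ensemble truths implied by a
#' generator configuration: mixture means and SDs of VIE and VAE, the implied
#' oxidation free energy and potential, and the zero-noise hole fractions and
#' delocalization numbers per basin together with their basin-weight mixture.
#'
#' @param system A [dna_duplex()] object.
#' @param config A [generator_config()].
#' @param electrode A [reference_electrode()] used for the truth `e_ox`.
#' @return A list with elements `mean_vie`, `mean_vae`, `sd_vie`, `sd_vae`,
#'   `dg_ox`, `e_ox`, `lambda_reorg`, `basin` (data frame of per-basin
#'   zero-noise `n` and `nprime`), `fractions` (M x 8 matrix of zero-noise
#'   hole fractions), `n`, `nprime` (basin-weight mixtures), and
#'   `per_base_percent`.
#' @export
ground_truth <- function(system, config = generator_config(),
                         electrode = reference_electrode()) {
  stopifnot(inherits(system, "dna_duplex"), inherits(config, "generator_config"))
  w <- config$basin_weights
  delta <- config$basin_energy_shifts
  shift <- sum(w * delta)
  varb <- sum(w * delta^2) - shift^2
  eps_free <- hole_free_energy(system, config)
  mean_vie <- config$mu_vie + eps_free + shift
  mean_vae <- config$mu_vae + eps_free + shift
  sd_mix <- sqrt(config$sigma_within^2 + varb)
  dg_ox <- (mean_vie + mean_vae) / 2
  e_ox <- dg_ox - electrode$she_potential

  M <- config$n_basins
  fr <- matrix(NA_real_, M, 8L, dimnames = list(NULL, system$qm1$label))
  for (m in seq_len(M)) {
    fr[m, ] <- charge_model(system, config_zero_noise(config), basin = m,
                            u = 0, nu = matrix(0, 1L, 8L))
  }
  n_m <- apply(fr, 1L, effective_number)
  np_m <- apply(fr, 1L, inverse_participation)
  list(mean_vie = mean_vie, mean_vae = mean_vae,
       sd_vie = sd_mix, sd_vae = sd_mix,
       dg_ox = dg_ox, e_ox = e_ox,
       lambda_reorg = (mean_vie - mean_vae) / 2,
       basin = data.frame(weight = w, energy_shift = delta, n = n_m,
                          nprime = np_m),
       fractions = fr,
       n = sum(w * n_m), nprime = sum(w * np_m),
       per_base_percent = 100 * colSums(fr * w))
}

# Copy of a config with all stochastic charge terms switched off.
config_zero_noise <- function(config) {
  cfg <- config
  cfg$charge_noise <- 0
  cfg$trap_drift <- 0
  cfg
}
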