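# Hole distributions and intermolecular delocalization numbers.
#
# The hole created by one-electron (vertical) oxidation is located from the
# per-nucleobase charge differences between the two electronic states at the
# same geometry. Two effective-number indices quantify how many of the 8
# analysis-region bases share the hole:
#   n  - empirical delocalization number: bases are ordered by increasing
#        hole charge and the effective number of occupied bases
#        exp(-sum q log q) (the perplexity of the distribution) is taken;
#        1 for a fully localized hole, 8 for a uniform one.
#   n' - Pipek-Mezey-type participation number adapted to per-base charges:
#        the inverse participation ratio 1 / sum q_i^2, same endpoints.
# n' <= n for every distribution (Renyi-entropy ordering), matching the
# observation that the participation index reads lower than the empirical
# count.

effective_number <- function(q) {
  q <- sort(q)                      # ordered by increasing hole charge
  q <- q[q > 0]
  exp(-sum(q * log(q)))
}

inverse_participation <- function(q) 1 / sum(q^2)

#' Hole distribution of one snapshot from its charge pair
#'
#' Converts the per-base charge differences (post-ionization minus
#' pre-ionization state at the same geometry) into a normalized hole
#' distribution over the 8 analysis-region bases. Slightly negative
#' differences, which population analyses can produce on spectator bases,
#' are clamped to zero and accounted in `clamped_mass`; the remaining mass
#' is renormalized to 1, so charge leaked outside the analysis region (the
#' renormalization deficit) is handled explicitly.
#'
#' @param q_neutral,q_cation Numeric length-8 vectors of per-base partial
#'   charges (e) in the pre- and post-ionization state, or a
#'   `ddna_trajectory` as the first argument (then `q_cation` is ignored
#'   and all frames are processed).
#' @param frame For the trajectory form, which frame to extract (default:
#'   all frames; returns a matrix of fractions).
#' @return For a single charge pair, an object of class `hole_distribution`:
#'   `fractions` (length 8, non-negative, summing to 1), `raw_sum` (the
#'   pre-normalization positive mass) and `clamped_mass` (discarded negative
#'   mass). For a trajectory, a list with `fractions` (n x 8 matrix),
#'   `raw_sum` and `clamped_mass` vectors.
#' @examples
#' h <- hole_fractions(rep(0, 8), c(0.72, 0.30, -0.02, rep(0, 5)))
#' h$fractions[1:2]   # ~0.7059, 0.2941
#' h$clamped_mass     # 0.02
#' @export
hole_fractions <- function(q_neutral, q_cation = NULL, frame = NULL) {
  if (inherits(q_neutral, "ddna_trajectory")) {
    traj <- q_neutral
    if (!is.null(frame)) {
      return(hole_fractions(traj$q_neutral[frame, ], traj$q_cation[frame, ]))
    }
    dq <- traj$q_cation - traj$q_neutral
    clamped <- rowSums(pmin(dq, 0) * -1)
    dq[dq < 0] <- 0
    raw <- rowSums(dq)
    if (any(raw <= 0)) {
      stopf("frame %d has no positive charge difference: no hole in region",
            which(raw <= 0)[1])
    }
    fr <- dq / raw
    colnames(fr) <- traj$qm1_labels
    return(list(fractions = fr, raw_sum = raw, clamped_mass = clamped))
  }
  stopifnot(length(q_neutral) == 8L, length(q_cation) == 8L)
  dq <- as.numeric(q_cation) - as.numeric(q_neutral)
  clamped <- -sum(pmin(dq, 0))
  dq <- pmax(dq, 0)
  raw <- sum(dq)
  if (raw <= 0) stopf("all charge differences <= 0: no hole in region")
  structure(list(fractions = dq / raw, raw_sum = raw, clamped_mass = clamped),
            class = "hole_distribution")
}

as_fraction_vector <- function(q) {
  if (inherits(q, "hole_distribution")) q <- q$fractions
  q <- as.numeric(q)
  if (any(q < -1e-12)) stopf("hole fractions must be non-negative")
  s <- sum(q)
  if (abs(s - 1) > 1e-8) stopf("hole fractions must sum to 1 (got %.6f)", s)
  pmax(q, 0)
}

#' Empirical intermolecular delocalization number n
#'
#' The effective number of nucleobases among which the positive charge is
#' distributed: the bases are ordered by increasing hole charge and the
#' perplexity `exp(-sum q log q)` of the distribution is evaluated. Equals 1
#' for a fully localized hole and the number of bases (8) for a uniform one,
#' and is invariant under any reordering of the bases.
#'
#' @param q A `hole_distribution` or a numeric vector of hole fractions
#'   summing to 1.
#' @return The delocalization number, in `[1, 8]` for 8 bases.
#' @examples
#' deloc_n(c(1, rep(0, 7)))        # 1
#' deloc_n(rep(1/8, 8))            # 8
#' @export
deloc_n <- function(q) effective_number(as_fraction_vector(q))

#' Pipek-Mezey-type delocalization number n'
#'
#' Participation-style delocalization index adapted to per-nucleobase
#' charges: the inverse participation ratio `1 / sum(q_i^2)`. Shares the
#' endpoints of [deloc_n()] (1 localized, 8 uniform) and never exceeds it.
#'
#' @inheritParams deloc_n
#' @return The participation number, in `[1, 8]` for 8 bases.
#' @examples
#' deloc_nprime(c(0.5, 0.5, rep(0, 6)))  # 2
#' @export
deloc_nprime <- function(q) inverse_participation(as_fraction_vector(q))

# Per-frame delocalization numbers for a whole trajectory.
frame_delocalization <- function(traj) {
  h <- hole_fractions(traj)
  data.frame(
    frame_id = traj$frame_id,
    n = apply(h$fractions, 1L, effective_number),
    nprime = apply(h$fractions, 1L, inverse_participation)
  )
}

#' Ensemble delocalization summary of a trajectory
#'
#' Computes per-frame hole distributions and both delocalization numbers,
#' then their ensemble means and standard deviations, together with the mean
#' hole percentage stored in each analysis-region base. Evaluated separately
#' on the neutral trajectory (hole created by vertical ionization, `n_VIE`)
#' and the cation trajectory (`n_VAE`).
#'
#' @param traj A `ddna_trajectory` (from [sample_trajectory()] or
#'   [read_snapshot_table()]) with at least 2 frames.
#' @param system Optional [dna_duplex()]; if given, the purine arrangement
#'   annotation is attached.
#' @return An object of class `deloc_summary`: `n_mean`, `n_sd`,
#'   `nprime_mean`, `nprime_sd`, `per_base_percent` (named, sums to 100),
#'   `clamped_mass_mean`, `state`, `system`, `arrangement`, `n_frames`.
#' @export
hole_summary <- function(traj, system = NULL) {
  stopifnot(inherits(traj, "ddna_trajectory"))
  if (n_frames(traj) < 2L) stopf("need at least 2 frames to summarize")
  h <- hole_fractions(traj)
  n <- apply(h$fractions, 1L, effective_number)
  np <- apply(h$fractions, 1L, inverse_participation)
  structure(
    list(system = traj$system_name, state = traj$state,
         n_mean = mean(n), n_sd = stats::sd(n),
         nprime_mean = mean(np), nprime_sd = stats::sd(np),
         per_base_percent = 100 * colMeans(h$fractions),
         clamped_mass_mean = mean(h$clamped_mass),
         arrangement = if (!is.null(system)) system$arrangement else NA_character_,
         n_frames = n_frames(traj)),
    class = "deloc_summary"
  )
}

#' @export
print.deloc_summary <- function(x, digits = 3, ...) {
  lab <- if (identical(x$state, "neutral")) "n_VIE" else "n_VAE"
  cat(sprintf("Hole delocalization, %s (%s trajectory, %d frames)\n",
              x$system, x$state, x$n_frames))
  cat(sprintf("  %s  = %.*f (sd %.*f)   n' = %.*f (sd %.*f)\n",
              lab, digits, x$n_mean, digits, x$n_sd,
              digits, x$nprime_mean, digits, x$nprime_sd))
  cat("  mean hole per base (%):\n")
  print(round(x$per_base_percent, 1))
  if (!is.na(x$arrangement)) cat(sprintf("  purine arrangement: %s\n", x$arrangement))
  invisible(x)
}
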