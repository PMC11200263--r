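# Shared fixtures: small configurations and independent oracles used across
# test files. Everything is generated in code; no stored data.

# A fast configuration for tests that do not probe the default study
# conditions: fewer frames, same physics.
small_config <- function(n_frames = 40L, ...) {
  generator_config(n_frames = n_frames, ...)
}

# A charge model with every structural term switched off: equal site
# energies, no stacking, no trapping, no noise. Hole fractions are uniform.
flat_charge_config <- function(...) {
  generator_config(site_energies = c(A = 0, C = 0, G = 0, T = 0),
                   stacking_bonus = 0, trap_kappa = 0,
                   trap_strand_penalty = 0, trap_drift = 0,
                   stack_mixing = 0, charge_noise = 0, ...)
}

# Independent effective-number comparator (product form, no logs shared with
# the implementation path).
oracle_effective_number <- function(q) {
  q <- q[q > 0]
  prod(q^(-q))
}

# Independent inverse-participation comparator (explicit loop).
oracle_participation <- function(q) {
  s <- 0
  for (qi in q) s <- s + qi * qi
  1 / s
}

# Random hole distribution over 8 bases (Dirichlet-like via normalized
# exponentials of varying spread).
random_fractions <- function(spread = stats::runif(1, 0.2, 4)) {
  w <- exp(spread * stats::rnorm(8))
  w / sum(w)
}

# Brute-force superposed RMSD: grid search over Euler angles followed by a
# Nelder-Mead refinement. Independent of the SVD path.
oracle_superposed_rmsd <- function(a, b, step = 15) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  f <- function(ang) sqrt(mean(rowSums((ac %*% rot(ang) - bc)^2)))
  grid <- expand.grid(a1 = seq(0, 2 * pi, by = step * pi / 180),
                      a2 = seq(0, pi, by = step * pi / 180),
                      a3 = seq(0, 2 * pi, by = step * pi / 180))
  vals <- apply(grid, 1, f)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# Exhaustive best partition of n items into at most k blocks by restricted
# growth strings; returns the minimum dispersion sum_c sum_{i<j in c}
# d_ij^2 / |c|.
oracle_best_dispersion <- function(d, kmax) {
  n <- nrow(d)
  d2 <- d^2
  best <- Inf
  assign_rec <- function(i, labels, used) {
    if (i > n) {
      disp <- 0
      for (c in seq_len(used)) {
        idx <- which(labels == c)
        if (length(idx) > 1) {
          sub <- d2[idx, idx, drop = FALSE]
          disp <- disp + sum(sub[upper.tri(sub)]) / length(idx)
        }
      }
      if (disp < best) best <<- disp
      return(invisible())
    }
    for (c in seq_len(min(used + 1L, kmax))) {
      labels[i] <- c
      assign_rec(i + 1L, labels, max(used, c))
    }
  }
  assign_rec(1L, integer(n), 0L)
  best
}

# Tiny synthetic coordinate set: m points per basin around well-separated
# centres, for clustering oracles.
toy_basin_coords <- function(centres, m, jitter = 0.02, atoms = 4L, seed = 1) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    n <- length(centres) * m
    arr <- array(0, dim = c(n, atoms, 3))
    lab <- integer(n)
    base <- matrix(stats::rnorm(atoms * 3), atoms, 3)
    r <- 0L
    for (b in seq_along(centres)) {
      for (i in seq_len(m)) {
        r <- r + 1L
        stretch <- 1 + centres[b]
        arr[r, , ] <- base * stretch + matrix(stats::rnorm(atoms * 3, sd = jitter), atoms, 3)
        lab[r] <- b
      }
    }
    list(coords = arr, labels = lab)
  })
}
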