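# Conformational clustering on superposed RMSD, centroid-representative
# selection, cluster-weighted property estimation and convergence/MRUE
# diagnostics.

#' Minimum RMSD between two frames after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch algorithm via SVD, with
#' the determinant correction that excludes reflections) followed by the
#' root-mean-square deviation. Symmetric in its arguments and invariant to
#' rigid motions of either frame.
#'
#' @param a,b Numeric `n x 3` coordinate matrices with the same number of
#'   points (at least 3 non-collinear points for a well-defined rotation).
#' @return The minimum RMSD (length units).
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' superpose_rmsd(x, x + rep(c(0, 0, 5), each = 4))  # ~0: translation removed
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    stopf("mismatched coordinate sets: %dx%d vs %dx%d",
          nrow(a), ncol(a), nrow(b), ncol(b))
  }
  n <- nrow(a)
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  sq <- sum(ac^2) + sum(bc^2)
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u) * det(s$v))
  msd <- (sq - 2 * (s$d[1] + s$d[2] + d * s$d[3])) / n
  sqrt(max(msd, 0))
}

#' Pairwise superposed-RMSD matrix of a trajectory
#'
#' @param coords A `ddna_trajectory`, or an `n_frames x n_atoms x 3` array.
#' @return A symmetric `n_frames x n_frames` matrix of superposed RMSDs.
#' @export
rmsd_matrix <- function(coords) {
  coords <- frame_array(coords)
  n <- dim(coords)[1]
  # centre every frame once; pairwise Kabsch on the centred sets
  centred <- vector("list", n)
  sq <- numeric(n)
  for (i in seq_len(n)) {
    x <- sweep(coords[i, , ], 2L, colMeans(coords[i, , ]))
    centred[[i]] <- x
    sq[i] <- sum(x^2)
  }
  na <- dim(coords)[2]
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- centred[[i]]
    for (j in (i + 1L):n) {
      s <- svd(crossprod(xi, centred[[j]]))
      sgn <- sign(det(s$u) * det(s$v))
      msd <- (sq[i] + sq[j] - 2 * (s$d[1] + s$d[2] + sgn * s$d[3])) / na
      d[i, j] <- d[j, i] <- sqrt(max(msd, 0))
    }
  }
  d
}

frame_array <- function(x) {
  if (inherits(x, "ddna_trajectory")) {
    if (is.null(x$coords)) stopf("trajectory carries no coordinates")
    x <- x$coords
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stopf("coordinates must be an n_frames x n_atoms x 3 array")
  }
  x
}

#' Cluster trajectory frames on superposed RMSD
#'
#' Average-linkage hierarchical agglomeration on the pairwise superposed-RMSD
#' matrix, cut at `k` clusters. Each cluster's representative is its medoid
#' (the member with minimum summed RMSD to its co-members), standing in for
#' the configuration closest to the cluster centroid; the cluster weight
#' `P(i)` is its fraction of frames. Deterministic given the inputs.
#'
#' @param x A `ddna_trajectory`, a coordinate array, or a precomputed
#'   symmetric RMSD matrix.
#' @param k Number of clusters, `1 <= k <= n_frames`.
#' @return An object of class `cluster_model`: `k`, `labels` (per-frame
#'   cluster id, 1..k in order of first appearance), `representatives`
#'   (frame index per cluster), `weights`, `sizes`, and `dispersion`
#'   (sum over clusters of mean within-cluster squared RMSD,
#'   `sum_c sum_{i<j in c} d_ij^2 / |c|`).
#' @export
cluster_frames <- function(x, k) {
  d <- if (is.matrix(x) && nrow(x) == ncol(x)) x else rmsd_matrix(x)
  n <- nrow(d)
  if (!is_count(k) || k > n) stopf("k must be an integer in [1, %d]", n)
  labels <- if (k == 1L) rep(1L, n) else if (k == n) seq_len(n) else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    relabel_first_appearance(stats::cutree(hc, k = k))
  }
  build_cluster_model(d, labels)
}

relabel_first_appearance <- function(labels) {
  u <- unique(labels)
  as.integer(match(labels, u))
}

build_cluster_model <- function(d, labels) {
  n <- length(labels)
  k <- length(unique(labels))
  reps <- integer(k); sizes <- integer(k); disp <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    sizes[c] <- length(idx)
    if (length(idx) == 1L) { reps[c] <- idx; next }
    sub <- d[idx, idx, drop = FALSE]
    reps[c] <- idx[which.min(rowSums(sub))]
    disp <- disp + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  structure(list(k = k, labels = as.integer(labels), representatives = reps,
                 weights = sizes / n, sizes = sizes, dispersion = disp,
                 n_frames = n, method = "average-linkage on superposed RMSD"),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Conformational clustering (%s): %d frames in %d clusters\n",
              x$method, x$n_frames, x$k))
  cat(sprintf("  weights P(i): %s\n", paste(round(x$weights, 3), collapse = ", ")))
  cat(sprintf("  representatives (medoid frames): %s\n",
              paste(x$representatives, collapse = ", ")))
  cat(sprintf("  dispersion: %.4f\n", x$dispersion))
  invisible(x)
}

#' Cluster-weighted property estimate
#'
#' Estimates an ensemble-average property from cluster representatives only:
#' `sum_i P(i) * value(representative_i)`, the population-weighted average of
#' the property evaluated at each cluster's representative structure.
#'
#' @param model A [cluster_frames()] model.
#' @param values Per-frame property values (length `n_frames`); only the
#'   representative entries are used.
#' @return The weighted estimate (scalar).
#' @examples
#' # P = (0.5, 0.3, 0.2), representative values (10, 20, 30) -> 17
#' @export
weighted_estimate <- function(model, values) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(values) != model$n_frames) {
    stopf("need one property value per frame (%d), got %d",
          model$n_frames, length(values))
  }
  v <- values[model$representatives]
  if (any(!is.finite(v))) {
    stopf("missing property value at representative frame %d",
          model$representatives[which(!is.finite(v))[1]])
  }
  sum(model$weights * v)
}

#' Convergence of cluster-representative estimates over the cluster count
#'
#' For every k in `k_grid`, clusters the neutral and cation trajectories on
#' superposed RMSD, evaluates VIE, VAE, the oxidation potential and the two
#' delocalization numbers (`n_VIE` on neutral frames, `n_VAE` on cation
#' frames) at the cluster representatives with population weighting, and
#' compares with the full-ensemble reference values: the relative unsigned
#' error `RUE_k = |A_k - A_ref| / |A_ref| * 100` per property per k. The
#' converged k of a property is the smallest grid point whose estimate moved
#' less than the property tolerance from the previous grid point; the MRUE
#' headline averages RUE over the converged window `[converged_k, max k]`,
#' and the RUE at the converged k is reported alongside.
#'
#' @param neutral,cation `ddna_trajectory` objects with coordinates.
#' @param system Optional [dna_duplex()] for labelling.
#' @param k_grid Strictly increasing cluster counts (default `2:10`).
#' @param electrode A [reference_electrode()].
#' @param tolerances Named per-property convergence tolerances in the
#'   property's own units (defaults: 0.05 eV for VIE/VAE, 0.02 V for e_ox,
#'   0.05 for both delocalization numbers).
#' @return An object of class `convergence_report`: `estimates` (data frame,
#'   one row per k), `reference` (named vector), `rue` (data frame of
#'   percentages), `converged_k`, `mrue`, `rue_at_converged` (named
#'   vectors), `k_grid`, `system`.
#' @export
convergence_scan <- function(neutral, cation, system = NULL, k_grid = 2:10,
                             electrode = reference_electrode(),
                             tolerances = c(vie = 0.05, vae = 0.05,
                                            e_ox = 0.02, n_vie = 0.05,
                                            n_vae = 0.05)) {
  stopifnot(inherits(neutral, "ddna_trajectory"),
            inherits(cation, "ddna_trajectory"))
  k_grid <- as.integer(k_grid)
  if (any(diff(k_grid) <= 0)) stopf("k_grid must be strictly increasing")
  if (max(k_grid) > n_frames(neutral) || max(k_grid) > n_frames(cation)) {
    stopf("k_grid exceeds the number of frames")
  }
  props <- c("vie", "vae", "e_ox", "n_vie", "n_vae")
  stopifnot(all(props %in% names(tolerances)))

  vie <- neutral$energy
  vae <- cation$energy
  n_vie <- frame_delocalization(neutral)$n
  n_vae <- frame_delocalization(cation)$n
  she <- electrode$she_potential
  reference <- c(vie = mean(vie), vae = mean(vae),
                 e_ox = (mean(vie) + mean(vae)) / 2 - she,
                 n_vie = mean(n_vie), n_vae = mean(n_vae))

  d_neu <- rmsd_matrix(neutral)
  d_cat <- rmsd_matrix(cation)
  hc_neu <- stats::hclust(stats::as.dist(d_neu), method = "average")
  hc_cat <- stats::hclust(stats::as.dist(d_cat), method = "average")

  est <- matrix(NA_real_, length(k_grid), length(props),
                dimnames = list(NULL, props))
  for (r in seq_along(k_grid)) {
    k <- k_grid[r]
    m_neu <- build_cluster_model(d_neu, relabel_first_appearance(stats::cutree(hc_neu, k = k)))
    m_cat <- build_cluster_model(d_cat, relabel_first_appearance(stats::cutree(hc_cat, k = k)))
    est[r, "vie"] <- weighted_estimate(m_neu, vie)
    est[r, "vae"] <- weighted_estimate(m_cat, vae)
    est[r, "e_ox"] <- (est[r, "vie"] + est[r, "vae"]) / 2 - she
    est[r, "n_vie"] <- weighted_estimate(m_neu, n_vie)
    est[r, "n_vae"] <- weighted_estimate(m_cat, n_vae)
  }

  rue <- est
  for (p in props) {
    if (abs(reference[p]) < .Machine$double.eps) {
      warnf("reference value of %s is zero: relative error undefined", p)
      rue[, p] <- NA_real_
    } else {
      rue[, p] <- abs(est[, p] - reference[p]) / abs(reference[p]) * 100
    }
  }

  converged_k <- mrue <- rue_conv <- stats::setNames(rep(NA_real_, length(props)), props)
  for (p in props) {
    dk <- abs(diff(est[, p]))
    hit <- which(dk <= tolerances[p])
    if (length(hit)) {
      idx <- hit[1] + 1L           # first grid point within tolerance of its predecessor
      converged_k[p] <- k_grid[idx]
      mrue[p] <- mean(rue[idx:length(k_grid), p])
      rue_conv[p] <- rue[idx, p]
    } else {
      warnf("property %s did not converge on the k grid", p)
      mrue[p] <- rue[length(k_grid), p]
      rue_conv[p] <- rue[length(k_grid), p]
    }
  }

  structure(
    list(system = if (inherits(system, "dna_duplex")) system$name else
           neutral$system_name,
         k_grid = k_grid,
         estimates = data.frame(k = k_grid, est, check.names = FALSE),
         reference = reference,
         rue = data.frame(k = k_grid, rue, check.names = FALSE),
         converged_k = converged_k, mrue = mrue,
         rue_at_converged = rue_conv, tolerances = tolerances[props]),
    class = "convergence_report"
  )
}

#' Relative unsigned errors at a fixed cluster count
#'
#' @param report A [convergence_scan()] report.
#' @param k A cluster count present in the report's grid.
#' @return Named vector of RUE percentages at that k.
#' @export
rue_at_k <- function(report, k) {
  stopifnot(inherits(report, "convergence_report"))
  row <- which(report$k_grid == k)
  if (!length(row)) stopf("k = %d is not on the scanned grid", k)
  unlist(report$rue[row, -1L])
}

#' @export
print.convergence_report <- function(x, digits = 2, ...) {
  cat(sprintf("Cluster-count convergence, %s (k = %d..%d)\n",
              x$system, min(x$k_grid), max(x$k_grid)))
  cat("  reference (200-snapshot-style full ensemble):\n")
  print(round(x$reference, 3))
  tab <- rbind(converged_k = x$converged_k,
               `MRUE %` = round(x$mrue, digits),
               `RUE@conv %` = round(x$rue_at_converged, digits))
  print(tab)
  invisible(x)
}

#' @export
plot.convergence_report <- function(x, ...) {
  est <- as.matrix(x$estimates[, -1L])
  scaled <- sweep(est, 2L, x$reference, "/")
  graphics::matplot(x$k_grid, scaled, type = "b", pch = 1:5, lty = 1,
                    xlab = "number of clusters", ylab = "estimate / reference",
                    main = x$system, ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", colnames(est), col = 1:5, pch = 1:5, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
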