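#' Select the most variably methylated loci by MAD
#'
#' Ranks probes by their median absolute deviation across samples and keeps
#' the top `ceiling(fraction * n_probes)` (the ceiling uniquely reproduces a
#' top-5% count such as 41,851 out of 837,018). Ties at the cutoff are
#' broken lexicographically by probe id, so the selection is deterministic.
#'
#' @param beta probes x samples beta matrix.
#' @param fraction fraction of probes to keep, in (0, 1).
#' @return object of class `variability_selection`: `mad_per_probe` (named),
#'   `cutoff_value` (smallest selected MAD), and `selected_probes` (ordered
#'   by decreasing MAD).
#' @export
select_top_mad <- function(beta, fraction = 0.05) {
  check_beta(beta)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_sel <- ceiling(fraction * nrow(beta))
  if (nrow(beta) * fraction < 1) stop("fraction selects fewer than one probe")
  mads <- row_mads(beta)
  ord <- order(-mads, rownames(beta))
  sel <- rownames(beta)[ord[seq_len(n_sel)]]
  structure(list(mad_per_probe = mads,
                 cutoff_value = mads[[sel[n_sel]]],
                 selected_probes = sel),
            class = "variability_selection")
}

#' @export
print.variability_selection <- function(x, ...) {
  cat(sprintf("variability_selection: %d of %d probes (MAD cutoff %.4g)\n",
              length(x$selected_probes), length(x$mad_per_probe),
              x$cutoff_value))
  invisible(x)
}

#' Principal component reduction of samples
#'
#' PCA with samples as observations and probes as mean-centered features,
#' deliberately *without* scaling the probes by their variance, so that
#' highly variable loci dominate the embedding.
#'
#' @param beta_subset probes x samples beta matrix (complete).
#' @param n_components number of components to keep.
#' @return object of class `reduced_space`: `scores` (samples x components),
#'   `explained_variance_fraction`, `n_components`, plus the rotation and
#'   centering vector for reconstruction.
#' @export
pca_reduce <- function(beta_subset, n_components = 2) {
  check_beta(beta_subset)
  x <- t(beta_subset)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(n_samples, n_probes)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained_variance_fraction = ev[seq_len(n_components)],
                 n_components = n_components,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 center = pc$center),
            class = "reduced_space")
}

# all permutations of 1..k as a matrix (k! rows); k is small (<= 8)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))))
}

# exhaustive shortest open Hamiltonian path over a distance matrix
shortest_hamiltonian_path <- function(d) {
  k <- nrow(d)
  if (k == 1) return(1L)
  perms <- permutations(k)
  # only consider one of each reversed pair
  perms <- perms[perms[, 1] < perms[, k], , drop = FALSE]
  lens <- apply(perms, 1, function(p)
    sum(d[cbind(p[-k], p[-1])]))
  as.integer(perms[which.min(lens), ])
}

# squared distance / arc-length projection of points onto a polyline
project_on_polyline <- function(points, vertices) {
  n <- nrow(points)
  nseg <- nrow(vertices) - 1
  seg_vec <- vertices[-1, , drop = FALSE] - vertices[-nrow(vertices), , drop = FALSE]
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  cum_len <- c(0, cumsum(seg_len))
  arc <- numeric(n); d2 <- numeric(n)
  for (i in seq_len(n)) {
    diff0 <- sweep(vertices[-nrow(vertices), , drop = FALSE], 2, points[i, ])
    tt <- -rowSums(diff0 * seg_vec) / pmax(seg_len2, 1e-300)
    tt <- pmin(1, pmax(0, tt))
    proj <- vertices[-nrow(vertices), , drop = FALSE] + seg_vec * tt
    dd <- rowSums(sweep(proj, 2, points[i, ])^2)
    j <- which.min(dd)
    d2[i] <- dd[j]
    arc[i] <- cum_len[j] + tt[j] * seg_len[j]
  }
  list(arclength = arc, dist2 = d2)
}

# one smoother pass: refit each coordinate against arc-length
smooth_curve <- function(points, arc, df, grid_n) {
  grid <- seq(min(arc), max(arc), length.out = grid_n)
  nu <- length(unique(arc))
  vapply(seq_len(ncol(points)), function(j) {
    if (nu >= 4) {
      fit <- suppressWarnings(
        smooth.spline(arc, points[, j], df = min(df, nu - 1)))
      predict(fit, grid)$y
    } else {
      fit <- lm(points[, j] ~ arc)
      drop(cbind(1, grid) %*% coef(fit))
    }
  }, numeric(grid_n))
}

#' Infer a pseudotime trajectory through the cell stages
#'
#' The trajectory is built in the first two principal components: (1)
#' k-means clustering of the samples (fixed seed, `nstart` restarts); (2)
#' the exhaustive shortest open Hamiltonian path through the k cluster
#' centers (exact enumeration, so k is capped at 8); (3) a principal curve
#' in the Hastie-Stuetzle sense, initialized at the ordered-center polyline
#' and refined by alternating projection of the samples onto the curve and
#' per-coordinate smoothing-spline regression against arc-length; (4)
#' pseudotime as each sample's projected arc-length position, min-max
#' scaled to \[0, 1\].
#'
#' Iteration stops when the relative change in total squared projection
#' distance falls below `tol`, the distance stops improving, or `max_iter`
#' is reached (with a warning); the best iterate seen is returned, so the
#' recorded distance path is non-increasing.
#'
#' @param space a [pca_reduce()] result with >= 2 components.
#' @param k number of k-means clusters (typically the number of stages).
#' @param seed RNG seed for k-means.
#' @param df smoothing-spline degrees of freedom per coordinate.
#' @param max_iter,tol iteration controls.
#' @param grid_n number of vertices of the fitted polyline.
#' @param nstart k-means restarts.
#' @return object of class `methyl_trajectory`: `cluster_centers`,
#'   `center_order`, `curve` (ordered polyline), `pseudotime` (named, in
#'   \[0,1\]), `projection_distance_path`, and `k`.
#' @export
infer_trajectory <- function(space, k = 4, seed = 1, df = 4, max_iter = 50,
                             tol = 1e-4, grid_n = 100, nstart = 10) {
  stopifnot(inherits(space, "reduced_space"))
  pts <- space$scores[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (k > n) stop("k must not exceed the number of samples")
  if (k > 8) stop("k is capped at 8 (exhaustive path enumeration)")

  km <- NULL
  for (try in 1:10) {
    set.seed(child_seed(seed, 10L + try))
    km <- tryCatch(kmeans(pts, centers = k, nstart = nstart),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce k non-empty clusters")

  ord <- shortest_hamiltonian_path(as.matrix(dist(km$centers)))
  curve <- km$centers[ord, , drop = FALSE]

  proj <- project_on_polyline(pts, curve)
  best <- list(curve = curve, proj = proj, d = sum(proj$dist2))
  dpath <- best$d
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    new_curve <- smooth_curve(pts, best$proj$arclength, df, grid_n)
    new_proj <- project_on_polyline(pts, new_curve)
    d <- sum(new_proj$dist2)
    if (d <= best$d) {
      rel <- (best$d - d) / max(best$d, 1e-300)
      best <- list(curve = new_curve, proj = new_proj, d = d)
      dpath <- c(dpath, d)
      if (rel < tol) { converged <- TRUE; break }
    } else {
      converged <- TRUE  # no further improvement; keep best iterate
      break
    }
  }
  if (!converged)
    warning("principal curve did not converge in ", max_iter,
            " iterations; returning the last improving iterate")

  arc <- best$proj$arclength
  rng <- range(arc)
  if (diff(rng) <= 0) stop("degenerate trajectory: all samples project to one point")
  pt <- (arc - rng[1]) / diff(rng)
  names(pt) <- rownames(pts)
  structure(list(cluster_centers = km$centers, center_order = ord,
                 curve = best$curve, pseudotime = pt,
                 projection_distance_path = dpath, k = k),
            class = "methyl_trajectory")
}

#' @export
print.methyl_trajectory <- function(x, ...) {
  cat(sprintf("methyl_trajectory: %d samples, k = %d, %d curve vertices\n",
              length(x$pseudotime), x$k, nrow(x$curve)))
  invisible(x)
}

#' Orient pseudotime so an anchor stage sits at the origin
#'
#' Pseudotime from a principal curve has an arbitrary direction; this flips
#' it (`t -> 1 - t`) when the mean pseudotime of the anchor stage's samples
#' exceeds 0.5, so the anchor (e.g. the pluripotent stage) starts at 0.
#' The operation is idempotent.
#'
#' @param traj a [infer_trajectory()] result.
#' @param samples sample sheet with sample_id and stage.
#' @param anchor_stage stage label to anchor at pseudotime 0.
#' @return the (possibly flipped) trajectory.
#' @export
orient_pseudotime <- function(traj, samples, anchor_stage) {
  stopifnot(inherits(traj, "methyl_trajectory"))
  check_sample_sheet(samples)
  if (!anchor_stage %in% samples$stage)
    stop("unknown stage label: ", anchor_stage)
  anchor_ids <- intersect(samples$sample_id[samples$stage == anchor_stage],
                          names(traj$pseudotime))
  if (length(anchor_ids) == 0)
    stop("no samples of stage '", anchor_stage, "' carry a pseudotime")
  if (mean(traj$pseudotime[anchor_ids]) > 0.5) {
    traj$pseudotime <- 1 - traj$pseudotime
    traj$curve <- traj$curve[rev(seq_len(nrow(traj$curve))), , drop = FALSE]
    traj$center_order <- rev(traj$center_order)
  }
  traj
}

#' Diagnostic trajectory plot
#'
#' Scatter of samples in the first two components with the fitted curve
#' overlaid, colored by stage when a sample sheet is given.
#'
#' @param x a `methyl_trajectory`.
#' @param space the [pca_reduce()] result used to fit it.
#' @param samples optional sample sheet for coloring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.methyl_trajectory <- function(x, space, samples = NULL, ...) {
  pts <- space$scores[, 1:2, drop = FALSE]
  col <- "black"; leg <- NULL
  if (!is.null(samples)) {
    stage <- factor(samples$stage[match(rownames(pts), samples$sample_id)])
    col <- as.integer(stage) + 1
    leg <- levels(stage)
  }
  plot(pts, col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * space$explained_variance_fraction[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * space$explained_variance_fraction[2]),
       ...)
  lines(x$curve, lwd = 2)
  if (!is.null(leg))
    legend("topright", legend = leg, col = seq_along(leg) + 1, pch = 19,
           cex = 0.8)
  invisible(x)
}
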