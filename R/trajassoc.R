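#' Round pseudotime to two decimals, halves up
#'
#' Plain half-up rounding (0.005 -> 0.01), unlike R's banker's rounding, so
#' the discretized pseudotime grid is unambiguous.
#'
#' @param t numeric vector in \[0, 1\].
#' @return rounded vector.
#' @export
round_pseudotime <- function(t) {
  if (any(t < 0 | t > 1)) stop("pseudotime values must lie in [0, 1]")
  floor(t * 100 + 0.5) / 100
}

# Build the fixed pieces of the per-locus spline scan: cubic regression
# spline basis (mgcv), penalty, hat matrices over a lambda grid.
scan_design <- function(t, basis_dim, grid_n) {
  n <- length(t)
  if (length(unique(t)) < 2) stop("pseudotime is constant across samples")
  if (n < basis_dim + 2) stop("need at least basis_dim + 2 samples")
  if (length(unique(t)) < basis_dim)
    stop("need at least basis_dim distinct pseudotime values")
  sm <- mgcv::smoothCon(mgcv::s(t, k = basis_dim, bs = "cr"),
                        data = data.frame(t = t), absorb.cons = TRUE)[[1]]
  X <- cbind(1, sm$X)
  p <- ncol(X)
  S <- matrix(0, p, p)
  S[-1, -1] <- sm$S[[1]]
  S <- S / mean(abs(sm$S[[1]][sm$S[[1]] != 0]))
  lambdas <- c(0, 10^seq(-4, 8, length.out = 25))
  xtx <- crossprod(X)
  fits <- lapply(lambdas, function(l) {
    ridge <- solve(xtx + l * S)
    coef_op <- ridge %*% t(X)          # p x n: y -> coefficients
    hat <- X %*% coef_op
    list(lambda = l, coef_op = coef_op, hat = hat, edf = sum(diag(hat)))
  })
  grid <- seq(0, 1, length.out = grid_n)
  Xg <- cbind(1, mgcv::PredictMat(sm, data.frame(t = grid)))
  list(t = t, n = n, p = p, X = X, fits = fits,
       edf = vapply(fits, `[[`, 0, "edf"), grid = grid, Xg = Xg)
}

#' Per-locus spline scan of methylation against pseudotime
#'
#' For every probe, regresses beta values on (rounded) pseudotime with a
#' penalized cubic regression spline (basis dimension `basis_dim` including
#' the intercept), choosing the smoothing parameter per locus by
#' generalized cross-validation over a shared lambda grid. The fitted curve
#' on a fixed pseudotime grid, its effective degrees of freedom, and the
#' end-to-end change `delta_end = fitted(1) - fitted(0)` come from that
#' penalized fit. The p-value is the exact F-test of the full (unpenalized)
#' spline basis against the intercept-only model, with `basis_dim - 1` and
#' `n - basis_dim` degrees of freedom; referencing the F statistic to
#' GCV-selected effective degrees of freedom is anticonservative at this
#' sample size, so the fixed-basis test is used for inference.
#'
#' Because the design is shared across loci, the scan is vectorized: hat
#' matrices are computed once per lambda and applied to all loci at once.
#'
#' @param beta probes x samples beta matrix (rows = loci to test).
#' @param pseudotime named numeric vector covering `colnames(beta)`.
#' @param basis_dim spline basis dimension including intercept (default 4).
#' @param grid_n number of pseudotime grid points for the fitted curves.
#' @return data.frame of class `gam_scan` with columns probe_id, pvalue,
#'   edf, delta_end, plus attributes `fitted_curves` (loci x grid) and
#'   `grid`.
#' @export
trajectory_gam_scan <- function(beta, pseudotime, basis_dim = 4,
                                grid_n = 101) {
  check_beta(beta)
  if (is.null(names(pseudotime)) ||
      !all(colnames(beta) %in% names(pseudotime)))
    stop("pseudotime must be named and cover all samples in beta")
  Y <- t(beta)                                   # n x loci
  pt <- round_pseudotime(unname(pseudotime[colnames(beta)]))
  des <- scan_design(pt, basis_dim, grid_n)
  n <- des$n
  nl <- ncol(Y)

  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  RSS <- vapply(des$fits, function(f) colSums((Y - f$hat %*% Y)^2),
                numeric(nl))
  RSS <- matrix(RSS, nrow = nl)
  GCV <- sweep(RSS, 2, n / (n - des$edf)^2, `*`)
  best <- max.col(-GCV, ties.method = "first")

  # p-value from the unpenalized (lambda = 0) fit: exact F(test) under the null
  rss_full <- RSS[, 1]
  df1 <- basis_dim - 1
  df2 <- n - basis_dim
  fstat <- ((rss0 - rss_full) / df1) / (rss_full / df2)
  pvalue <- pf(fstat, df1, df2, lower.tail = FALSE)
  degenerate <- rss0 <= .Machine$double.eps * n | !is.finite(fstat)
  if (any(degenerate)) {
    warning(sum(degenerate), " loci with (near-)constant methylation; ",
            "p-value set to 1")
    pvalue[degenerate] <- 1
  }

  curves <- matrix(NA_real_, nl, grid_n,
                   dimnames = list(rownames(beta), NULL))
  for (b in sort(unique(best))) {
    idx <- which(best == b)
    coefs <- des$fits[[b]]$coef_op %*% Y[, idx, drop = FALSE]
    curves[idx, ] <- t(des$Xg %*% coefs)
  }
  out <- data.frame(probe_id = rownames(beta), pvalue = pvalue,
                    edf = des$edf[best],
                    delta_end = curves[, grid_n] - curves[, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fitted_curves") <- curves
  attr(out, "grid") <- des$grid
  attr(out, "basis_dim") <- basis_dim
  class(out) <- c("gam_scan", "data.frame")
  out
}

#' Fit a single locus against pseudotime
#'
#' Convenience wrapper around [trajectory_gam_scan()] for one locus.
#'
#' @param beta_locus named numeric vector of beta values (names = samples).
#' @param pseudotime named pseudotime vector.
#' @param basis_dim spline basis dimension.
#' @param grid_n curve grid size.
#' @return one-row `gam_scan` data.frame (see [trajectory_gam_scan()]).
#' @export
fit_locus_gam <- function(beta_locus, pseudotime, basis_dim = 4,
                          grid_n = 101) {
  m <- matrix(beta_locus, 1, dimnames = list("locus", names(beta_locus)))
  trajectory_gam_scan(m, pseudotime, basis_dim, grid_n)
}

#' Bonferroni selection of the trajectory signature
#'
#' Keeps loci with `pvalue <= alpha / n_tests` and labels each with its
#' methylation direction from the fitted end-to-end change (`hypo` when the
#' curve falls, `hyper` when it rises; an exact zero is called hyper with a
#' warning). The direction split always partitions the signature.
#'
#' @param scan a [trajectory_gam_scan()] result.
#' @param alpha family-wise error rate.
#' @param n_tests number of tests corrected for (defaults to the number of
#'   scanned loci).
#' @return data.frame of class `trajectory_signature` with columns
#'   probe_id, pvalue, direction, delta_end; attributes `alpha`, `n_tests`,
#'   `fitted_curves`, `grid`.
#' @export
bonferroni_select <- function(scan, alpha = 0.05, n_tests = nrow(scan)) {
  stopifnot(inherits(scan, "gam_scan"))
  keep <- scan$pvalue <= alpha / n_tests
  sig <- scan[keep, c("probe_id", "pvalue", "delta_end"), drop = FALSE]
  sig$direction <- classify_direction(sig$delta_end)
  sig <- sig[, c("probe_id", "pvalue", "direction", "delta_end")]
  attr(sig, "alpha") <- alpha
  attr(sig, "n_tests") <- n_tests
  attr(sig, "fitted_curves") <- attr(scan, "fitted_curves")[keep, , drop = FALSE]
  attr(sig, "grid") <- attr(scan, "grid")
  row.names(sig) <- NULL
  class(sig) <- c("trajectory_signature", "data.frame")
  sig
}

#' Direction of methylation change
#'
#' @param delta_end fitted(1) - fitted(0) per locus.
#' @return character vector, `"hypo"` or `"hyper"`.
#' @export
classify_direction <- function(delta_end) {
  if (any(delta_end == 0))
    warning("delta_end exactly 0 for ", sum(delta_end == 0),
            " loci; called hyper by convention")
  ifelse(delta_end < 0, "hypo", "hyper")
}

#' Group signature loci into shape modules
#'
#' Standardizes each locus's fitted curve (z-score over the pseudotime
#' grid), clusters the curves with Ward-linkage hierarchical clustering on
#' Euclidean distance, and cuts the tree into `n_modules` modules. Module
#' ids are relabeled in increasing order of the mean pseudotime at which
#' member curves change fastest, so labels are reproducible.
#'
#' @param signature a [bonferroni_select()] result.
#' @param n_modules number of modules (default 9).
#' @param seed unused (clustering is deterministic); kept for interface
#'   stability.
#' @return the signature with an integer `module` column added.
#' @export
assign_modules <- function(signature, n_modules = 9, seed = 1) {
  stopifnot(inherits(signature, "trajectory_signature"))
  if (nrow(signature) < n_modules)
    stop("signature has fewer loci than requested modules")
  curves <- attr(signature, "fitted_curves")
  if (n_modules == 1) {
    signature$module <- 1L
    return(signature)
  }
  sds <- apply(curves, 1, sd)
  z <- (curves - rowMeans(curves)) / ifelse(sds > 0, sds, 1)
  cl <- cutree(hclust(dist(z), method = "ward.D2"), k = n_modules)
  grid <- attr(signature, "grid")
  change_pos <- apply(curves, 1, function(y)
    grid[which.max(abs(diff(y)))])
  mod_order <- order(tapply(change_pos, cl, mean))
  relabel <- integer(n_modules)
  relabel[mod_order] <- seq_len(n_modules)
  signature$module <- relabel[cl]
  signature
}

#' Mean beta change per module between two stages
#'
#' For each module, the mean over member loci of (mean beta in `stage_b`
#' minus mean beta in `stage_a`), in percentage points; swapping the stages
#' negates the result.
#'
#' @param signature a module-labeled [assign_modules()] result.
#' @param beta probes x samples beta matrix containing the signature loci.
#' @param samples sample sheet (sample_id, stage).
#' @param stage_a,stage_b stage labels.
#' @return named numeric vector, one value per module, in percentage points.
#' @export
summarize_module_change <- function(signature, beta, samples, stage_a,
                                    stage_b) {
  stopifnot(inherits(signature, "trajectory_signature"))
  if (is.null(signature$module)) stop("run assign_modules() first")
  check_sample_sheet(samples)
  for (s in c(stage_a, stage_b))
    if (!s %in% samples$stage) stop("unknown stage label: ", s)
  ids_a <- intersect(samples$sample_id[samples$stage == stage_a], colnames(beta))
  ids_b <- intersect(samples$sample_id[samples$stage == stage_b], colnames(beta))
  delta <- rowMeans(beta[signature$probe_id, ids_b, drop = FALSE]) -
    rowMeans(beta[signature$probe_id, ids_a, drop = FALSE])
  100 * vapply(split(delta, signature$module), mean, 0)
}
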