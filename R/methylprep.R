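#' Paired methylated/unmethylated intensity container
#'
#' Holds the probes x samples methylated and unmethylated signal matrices
#' together with detection p-values, optional bead counts, and the per-probe
#' chemistry type (Infinium I or II). All components must share the same
#' probe and sample index.
#'
#' @param meth,unmeth positive numeric matrices (probes x samples).
#' @param detection_p matrix of detection p-values in \[0,1\].
#' @param beadcount optional integer matrix of bead counts.
#' @param probe_type named character vector, one of "I"/"II" per probe.
#' @return object of class `intensity_pair`.
#' @export
intensity_pair <- function(meth, unmeth, detection_p, beadcount = NULL,
                           probe_type) {
  stop_if_not_matrix(meth); stop_if_not_matrix(unmeth)
  stop_if_not_matrix(detection_p)
  same_dim <- function(x) identical(dimnames(x), dimnames(meth))
  if (!same_dim(unmeth) || !same_dim(detection_p) ||
      (!is.null(beadcount) && !same_dim(beadcount)))
    stop("all intensity components must share probe/sample dimnames")
  if (min(meth) <= 0 || min(unmeth) <= 0)
    stop("intensities must be strictly positive")
  if (min(detection_p) < 0 || max(detection_p) > 1)
    stop("detection p-values must lie in [0, 1]")
  if (!identical(sort(names(probe_type)), sort(rownames(meth))))
    stop("probe_type must be named by the probe ids")
  if (!all(probe_type %in% c("I", "II")))
    stop("probe_type values must be \"I\" or \"II\"")
  structure(list(meth = meth, unmeth = unmeth, detection_p = detection_p,
                 beadcount = beadcount,
                 probe_type = probe_type[rownames(meth)]),
            class = "intensity_pair")
}

#' @export
print.intensity_pair <- function(x, ...) {
  cat(sprintf("intensity_pair: %d probes x %d samples (%d type I, %d type II)%s\n",
              nrow(x$meth), ncol(x$meth), sum(x$probe_type == "I"),
              sum(x$probe_type == "II"),
              if (is.null(x$beadcount)) ", no beadcounts" else ""))
  invisible(x)
}

subset_intensities <- function(ip, probes = rownames(ip$meth),
                               samples = colnames(ip$meth)) {
  intensity_pair(ip$meth[probes, samples, drop = FALSE],
                 ip$unmeth[probes, samples, drop = FALSE],
                 ip$detection_p[probes, samples, drop = FALSE],
                 if (!is.null(ip$beadcount))
                   ip$beadcount[probes, samples, drop = FALSE],
                 ip$probe_type[probes])
}

#' Beta values from intensities
#'
#' The standard Illumina definition `beta = M / (M + U + offset)`; the
#' offset (100 by convention) regularizes low-intensity probes toward 0.
#'
#' @param intensities an [intensity_pair()].
#' @param offset nonnegative stabilizing constant.
#' @return probes x samples matrix of beta values in \[0,1\].
#' @export
#' @examples
#' # a 500/500 split with the conventional offset gives 500/1100
#' 500 / (500 + 500 + 100)
compute_beta <- function(intensities, offset = 100) {
  if (offset < 0) stop("offset must be nonnegative")
  m <- intensities$meth; u <- intensities$unmeth
  m / (m + u + offset)
}

#' Detection p-value and beadcount filter
#'
#' The p-filter quality-control rule: first flag samples in which more than
#' `sample_frac` of probes have detection p above `detp_thresh`; then, among
#' the surviving samples, flag probes with detection p above `detp_thresh`
#' in more than `probe_frac` of samples, and probes with bead count below
#' `bead_min` in more than `bead_frac` of samples (skipped when bead counts
#' are absent). Samples are always assessed before probes.
#'
#' @param intensities an [intensity_pair()].
#' @param detp_thresh detection p-value threshold.
#' @param sample_frac maximum tolerated fraction of failed probes per sample.
#' @param probe_frac maximum tolerated fraction of failed samples per probe.
#' @param bead_min minimum bead count.
#' @param bead_frac maximum tolerated fraction of low-bead samples per probe.
#' @return object of class `qc_report`: failed samples and removed probes
#'   with reasons, the thresholds used, and before/after counts.
#' @export
pfilter <- function(intensities, detp_thresh = 0.05, sample_frac = 0.01,
                    probe_frac = 0.01, bead_min = 3, bead_frac = 0.05) {
  detp <- intensities$detection_p
  bad_frac <- colMeans(detp > detp_thresh)
  failed_samples <- colnames(detp)[bad_frac > sample_frac]
  keep_samples <- setdiff(colnames(detp), failed_samples)
  if (length(keep_samples) == 0)
    stop("empty dataset: all samples failed the detection p-value check")

  sub <- detp[, keep_samples, drop = FALSE]
  probe_detp_bad <- rowMeans(sub > detp_thresh) > probe_frac
  probe_bead_bad <- rep(FALSE, nrow(detp))
  if (!is.null(intensities$beadcount)) {
    bc <- intensities$beadcount[, keep_samples, drop = FALSE]
    probe_bead_bad <- rowMeans(bc < bead_min) > bead_frac
  }
  removed <- rownames(detp)[probe_detp_bad | probe_bead_bad]
  reason_probe <- ifelse(probe_detp_bad[probe_detp_bad | probe_bead_bad] &
                           probe_bead_bad[probe_detp_bad | probe_bead_bad],
                         "detection_p+beadcount",
                         ifelse(probe_detp_bad[probe_detp_bad | probe_bead_bad],
                                "detection_p", "beadcount"))
  structure(list(
    failed_samples = data.frame(
      sample_id = failed_samples,
      reason = rep("detection_p_fraction", length(failed_samples)),
      stringsAsFactors = FALSE),
    removed_probes = data.frame(
      probe_id = removed, reason = reason_probe, stringsAsFactors = FALSE),
    thresholds = list(detp_thresh = detp_thresh, sample_frac = sample_frac,
                      probe_frac = probe_frac, bead_min = bead_min,
                      bead_frac = bead_frac),
    counts = list(samples_before = ncol(detp),
                  samples_after = length(keep_samples),
                  probes_before = nrow(detp),
                  probes_after = nrow(detp) - length(removed))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d samples retained, %d/%d probes retained\n",
              x$counts$samples_after, x$counts$samples_before,
              x$counts$probes_after, x$counts$probes_before))
  if (nrow(x$failed_samples))
    cat("  failed samples:", paste(x$failed_samples$sample_id, collapse = ", "),
        "\n")
  invisible(x)
}

#' Apply a QC report to an intensity pair
#'
#' Drops the samples and probes flagged by [pfilter()] (and any extra failed
#' samples, e.g. from [median_intensity_check()]).
#'
#' @param intensities an [intensity_pair()].
#' @param report a `qc_report`.
#' @param extra_failed_samples additional sample ids to drop.
#' @return the filtered [intensity_pair()].
#' @export
apply_qc <- function(intensities, report, extra_failed_samples = character(0)) {
  drop_s <- union(report$failed_samples$sample_id, extra_failed_samples)
  keep_s <- setdiff(colnames(intensities$meth), drop_s)
  keep_p <- setdiff(rownames(intensities$meth), report$removed_probes$probe_id)
  if (length(keep_s) == 0) stop("empty dataset: no samples survive QC")
  if (length(keep_p) == 0) stop("empty dataset: no probes survive QC")
  subset_intensities(intensities, keep_p, keep_s)
}

#' Median-intensity sample check
#'
#' A sample fails when the median of its methylated or unmethylated channel
#' falls below `min_median`. The threshold depends on scanner and chemistry
#' and is deliberately a required argument.
#'
#' @param intensities an [intensity_pair()].
#' @param min_median positive intensity threshold.
#' @return character vector of failed sample ids (possibly empty).
#' @export
median_intensity_check <- function(intensities, min_median) {
  if (length(min_median) != 1 || min_median < 0)
    stop("min_median must be a single nonnegative number")
  med_m <- apply(intensities$meth, 2, median)
  med_u <- apply(intensities$unmeth, 2, median)
  colnames(intensities$meth)[med_m < min_median | med_u < min_median]
}

#' dasen-style normalization
#'
#' Between-sample normalization of the two Infinium chemistries:
#' (1) per sample, the type I background is shifted to match type II, the
#' offset being the difference of a low quantile (default the 5th
#' percentile) of the two chemistries' intensities; (2) methylated and
#' unmethylated intensities are quantile-normalized across samples
#' separately within each probe type; (3) beta values are computed from the
#' result. The original's smoothed position-dependent background fit is
#' intentionally simplified to a single per-sample quantile shift.
#'
#' @param intensities an [intensity_pair()].
#' @param low_quantile quantile used as the background estimate.
#' @param offset beta-value offset passed to [compute_beta()].
#' @param return_intensities also return the normalized intensity channels.
#' @return probes x samples beta matrix; with `return_intensities = TRUE`, a
#'   list with `beta`, `meth`, `unmeth`.
#' @export
dasen_normalize <- function(intensities, low_quantile = 0.05, offset = 100,
                            return_intensities = FALSE) {
  if (ncol(intensities$meth) < 2)
    stop("dasen normalization needs at least 2 samples")
  type <- intensities$probe_type
  i1 <- which(type == "I"); i2 <- which(type == "II")
  adjust_bg <- function(x) {
    if (length(i1) == 0 || length(i2) == 0) return(x)
    for (s in seq_len(ncol(x))) {
      off <- quantile(x[i1, s], low_quantile) - quantile(x[i2, s], low_quantile)
      x[i1, s] <- pmax(x[i1, s] - off, 1e-6)
    }
    x
  }
  qn_within_type <- function(x) {
    for (idx in list(i1, i2)) {
      if (length(idx) < 2) {
        if (length(idx) > 0)
          warning("probe type with fewer than 2 probes: quantile normalization skipped for it")
        next
      }
      x[idx, ] <- limma::normalizeQuantiles(x[idx, , drop = FALSE])
    }
    x
  }
  m <- qn_within_type(adjust_bg(intensities$meth))
  u <- qn_within_type(adjust_bg(intensities$unmeth))
  beta <- m / (m + u + offset)
  if (return_intensities) list(beta = beta, meth = m, unmeth = u) else beta
}

#' Exclude flagged probes
#'
#' Removes probes flagged for common SNPs near the extension base or for
#' potential cross-hybridization, as well as probes absent from the
#' annotation (with a warning).
#'
#' @param beta probes x samples beta matrix.
#' @param annotation a `probe_annotation` data.frame.
#' @return the reduced beta matrix.
#' @export
filter_probes <- function(beta, annotation) {
  check_beta(beta)
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " probes missing from the annotation were dropped")
    beta <- beta[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  bad <- annotation$snp_flag[idx] | annotation$crossreactive_flag[idx]
  out <- beta[!bad, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no probes remain after SNP/cross-reactive exclusion")
  out
}
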