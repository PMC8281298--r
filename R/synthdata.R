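#' Default trajectory shape templates
#'
#' Nine template functions on \[0,1\] describing how a trajectory-associated
#' locus changes with latent differentiation time: monotone ramps, an early
#' drop, a late rise, sigmoids in both directions, transient peak/dip, and an
#' early rise to a plateau. Each maps \[0,1\] into \[0,1\]; the generator
#' rescales them by a per-locus baseline and amplitude.
#'
#' @return named list of 9 functions, each taking a numeric vector in \[0,1\].
#' @export
#' @examples
#' sapply(module_shapes(), function(f) f(c(0, 0.5, 1)))
module_shapes <- function() {
  list(
    linear_up     = function(t) t,
    linear_down   = function(t) 1 - t,
    early_drop    = function(t) (exp(-5 * t) - exp(-5)) / (1 - exp(-5)),
    late_rise     = function(t) t^4,
    sigmoid_up    = function(t) {
      lo <- plogis(-5); hi <- plogis(5)
      (plogis(10 * (t - 0.5)) - lo) / (hi - lo)
    },
    sigmoid_down  = function(t) {
      lo <- plogis(-5); hi <- plogis(5)
      1 - (plogis(10 * (t - 0.5)) - lo) / (hi - lo)
    },
    transient_peak = function(t) 4 * t * (1 - t),
    transient_dip  = function(t) 1 - 4 * t * (1 - t),
    rise_plateau   = function(t) (1 - exp(-5 * t)) / (1 - exp(-5))
  )
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic differentiation experiment. The
#' defaults emulate the assumed study design: 4 cell stages with 4 technical
#' replicates each (16 samples), of which 2 are planted to fail quality
#' control, a 5% fraction of trajectory-associated loci spread over the 9
#' shape modules of [module_shapes()], and modest technical noise.
#'
#' `noise_sd` is the standard deviation of Gaussian noise added on the logit
#' scale before transforming back, which keeps beta values strictly inside
#' (0, 1) without clipping.
#'
#' @param n_probes number of CpG probes (>= 20).
#' @param n_stages number of differentiation stages.
#' @param replicates_per_stage technical replicates per stage.
#' @param frac_associated fraction of probes with true pseudotime dependence
#'   (0 gives a fully null dataset). When positive, `round(frac_associated *
#'   n_probes)` must be at least 9 so each module is represented.
#' @param module_shapes list of 9 template functions on \[0,1\].
#' @param amplitude beta-scale amplitude of the planted templates.
#' @param noise_sd logit-scale noise standard deviation (> 0 for realistic
#'   data; 0 is allowed for noiseless checks).
#' @param mean_total_intensity mean simulated total (M + U) intensity.
#' @param n_failing_samples number of stage-1 samples planted to fail QC.
#' @param stage_jitter_sd within-stage jitter of latent time.
#' @param seed RNG seed driving all child generators.
#' @return object of class `sim_config` (a list of the above).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 500, seed = 1)
sim_config <- function(n_probes = 10000, n_stages = 4,
                       replicates_per_stage = 4, frac_associated = 0.05,
                       module_shapes = methyltraj::module_shapes(),
                       amplitude = 0.4, noise_sd = 0.03,
                       mean_total_intensity = 5000, n_failing_samples = 2,
                       stage_jitter_sd = 0.01, seed = 1) {
  n_samples <- n_stages * replicates_per_stage
  if (n_probes < 20) stop("invalid config: n_probes must be >= 20")
  if (n_samples < 2) stop("invalid config: fewer than 2 samples")
  if (frac_associated < 0 || frac_associated >= 1)
    stop("invalid config: frac_associated must be in [0, 1)")
  n_assoc <- round(frac_associated * n_probes)
  if (frac_associated > 0 && n_assoc < length(module_shapes))
    stop("invalid config: frac_associated * n_probes must be >= ",
         length(module_shapes), " so every module is represented")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (amplitude <= 0 || amplitude >= 0.8)
    stop("invalid config: amplitude must be in (0, 0.8)")
  if (mean_total_intensity <= 0)
    stop("invalid config: mean_total_intensity must be positive")
  if (n_failing_samples < 0 || n_failing_samples >= n_samples)
    stop("invalid config: n_failing_samples out of range")
  structure(list(
    n_probes = n_probes, n_stages = n_stages,
    replicates_per_stage = replicates_per_stage,
    frac_associated = frac_associated, module_shapes = module_shapes,
    amplitude = amplitude, noise_sd = noise_sd,
    mean_total_intensity = mean_total_intensity,
    n_failing_samples = n_failing_samples,
    stage_jitter_sd = stage_jitter_sd, seed = seed
  ), class = "sim_config")
}

stage_labels <- function(n_stages) {
  if (n_stages == 4) c("iPSC", "NPC", "Neuron37", "Neuron58")
  else paste0("stage", seq_len(n_stages))
}

stage_days <- function(n_stages) {
  if (n_stages == 4) c(0, 16, 37, 58)
  else round(seq(0, 58, length.out = n_stages))
}

#' Simulate a beta-value dataset with planted trajectory structure
#'
#' Draws a latent differentiation time for every sample (equal within stage
#' up to a small jitter), plants `frac_associated` of the probes on one of
#' the 9 module templates with a random baseline and the configured
#' amplitude, leaves the rest flat, and adds logit-scale Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list with components
#'   \describe{
#'     \item{beta}{probes x samples matrix of beta values in \[0,1\].}
#'     \item{samples}{data.frame with sample_id, stage, day.}
#'     \item{truth}{ground truth: `true_time` (named, per sample),
#'       `associated_loci`, `module_label` (named, per associated locus),
#'       and `locus_params` (baseline/amplitude/module per associated
#'       locus) for recovery tests.}
#'   }
#' @export
#' @examples
#' sim <- simulate_beta_dataset(sim_config(n_probes = 200, seed = 7))
#' range(sim$beta)
simulate_beta_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n_stages <- config$n_stages
  reps <- config$replicates_per_stage
  n_samples <- n_stages * reps
  stage <- factor(rep(stage_labels(n_stages), each = reps),
                  levels = stage_labels(n_stages))
  sample_id <- sprintf("S%02d", seq_len(n_samples))
  base_time <- rep(seq(0, 1, length.out = n_stages), each = reps)
  true_time <- base_time + rnorm(n_samples, 0, config$stage_jitter_sd)
  # reflect at the boundaries: stays in [0,1] without creating ties
  true_time <- abs(true_time)
  true_time <- 1 - abs(1 - true_time)
  names(true_time) <- sample_id

  probe_id <- sprintf("cg%08d", seq_len(config$n_probes))
  n_assoc <- round(config$frac_associated * config$n_probes)
  shapes <- config$module_shapes
  beta_clean <- matrix(NA_real_, config$n_probes, n_samples,
                       dimnames = list(probe_id, sample_id))

  if (n_assoc > 0) {
    associated <- sort(sample(probe_id, n_assoc))
    module <- setNames(rep_len(seq_along(shapes), n_assoc), associated)
    baseline <- setNames(runif(n_assoc, 0.1, 0.9 - config$amplitude), associated)
    for (j in seq_along(shapes)) {
      loci <- associated[module == j]
      if (!length(loci)) next
      g <- shapes[[j]](true_time)
      beta_clean[loci, ] <- outer(baseline[loci], config$amplitude * g, `+`)
    }
  } else {
    associated <- character(0)
    module <- setNames(integer(0), character(0))
    baseline <- setNames(numeric(0), character(0))
  }
  flat <- setdiff(probe_id, associated)
  beta_clean[flat, ] <- runif(length(flat), 0.1, 0.9)

  if (config$noise_sd > 0) {
    eps <- matrix(rnorm(length(beta_clean), 0, config$noise_sd),
                  nrow(beta_clean))
    beta <- plogis(qlogis(beta_clean) + eps)
  } else {
    beta <- beta_clean
  }

  truth <- list(
    true_time = true_time,
    associated_loci = associated,
    module_label = module,
    locus_params = data.frame(
      probe_id = associated,
      baseline = unname(baseline),
      amplitude = rep(config$amplitude, n_assoc),
      module = unname(module),
      shape = names(shapes)[unname(module)] %||% character(0),
      stringsAsFactors = FALSE
    )
  )
  list(beta = beta,
       samples = data.frame(sample_id = sample_id, stage = stage,
                            day = rep(stage_days(n_stages), each = reps),
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate methylated/unmethylated intensities from beta values
#'
#' Inverts the beta definition: each probe/sample gets a total intensity
#' `T ~ mean_total_intensity * exp(N(0, intensity_sd))`, split as
#' `M = beta * T`, `U = (1 - beta) * T`, plus a chemistry-specific background
#' offset. Detection p-values are near zero for good samples. The first
#' `n_failing_samples` columns (stage-1 samples, mirroring a run in which the
#' earliest-stage samples failed) are planted to fail quality control: their
#' intensities are scaled down by `failure_scale` and their detection
#' p-values inflated.
#'
#' @param beta probes x samples beta matrix in \[0,1\].
#' @param config a [sim_config()].
#' @param intensity_sd log-scale SD of the total intensity (0 = noiseless).
#' @param type1_offset,type2_offset additive background per probe chemistry.
#' @param failure_scale multiplicative intensity factor for planted failures.
#' @return an [intensity_pair()] with attribute `planted_failures` holding
#'   the sample ids constructed to fail QC.
#' @export
simulate_intensities <- function(beta, config, intensity_sd = 0.2,
                                 type1_offset = 150, type2_offset = 50,
                                 failure_scale = 0.03) {
  check_beta(beta)
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2L))
  np <- nrow(beta); ns <- ncol(beta)
  probe_type <- setNames(sample(c("I", "II"), np, TRUE, prob = c(0.16, 0.84)),
                         rownames(beta))
  total <- config$mean_total_intensity *
    exp(matrix(rnorm(np * ns, 0, intensity_sd), np))
  bg <- ifelse(probe_type == "I", type1_offset, type2_offset)
  meth <- beta * total + bg
  unmeth <- (1 - beta) * total + bg
  detp <- matrix(runif(np * ns, 0, 0.001), np,
                 dimnames = dimnames(beta))
  beadcount <- matrix(rpois(np * ns, 14) + 1L, np, dimnames = dimnames(beta))

  failing <- character(0)
  if (config$n_failing_samples > 0) {
    idx <- seq_len(config$n_failing_samples)
    failing <- colnames(beta)[idx]
    meth[, idx] <- meth[, idx] * failure_scale
    unmeth[, idx] <- unmeth[, idx] * failure_scale
    detp[, idx] <- runif(np * length(idx), 0, 0.2)
  }
  dimnames(meth) <- dimnames(unmeth) <- dimnames(beta)
  ip <- intensity_pair(meth, unmeth, detp, beadcount, probe_type)
  attr(ip, "planted_failures") <- failing
  ip
}

#' Simulate a probe annotation table
#'
#' Assigns each probe a gene-region group, a CpG-island relation, 0-2 gene
#' symbols, SNP and cross-reactive exclusion flags, and coordinates. For
#' trajectory-associated loci the category probabilities can be tilted by
#' per-category odds, which plants enrichment with a known target odds
#' ratio (odds 1 everywhere means no planted enrichment).
#'
#' @param config a [sim_config()].
#' @param truth the truth component of [simulate_beta_dataset()].
#' @param region_odds,cgi_odds named numeric vectors of tilt odds applied to
#'   associated loci (names must be category levels; missing names get 1).
#' @param snp_rate,crossreactive_rate marginal flag probabilities.
#' @return data.frame of class `probe_annotation` with columns probe_id,
#'   gene_symbols (";"-separated, possibly empty), region_group,
#'   cgi_relation, snp_flag, crossreactive_flag, chromosome, position.
#' @export
simulate_annotation <- function(config, truth, region_odds = NULL,
                                cgi_odds = NULL, snp_rate = 0.05,
                                crossreactive_rate = 0.03) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 3L))
  probe_id <- sprintf("cg%08d", seq_len(config$n_probes))
  region_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                     "3'UTR", "intergenic")
  region_base <- c(0.13, 0.10, 0.09, 0.05, 0.35, 0.04, 0.24)
  cgi_levels <- c("island", "shore", "shelf", "open_sea")
  cgi_base <- c(0.20, 0.25, 0.10, 0.45)

  tilt <- function(base, levels, odds) {
    o <- setNames(rep(1, length(levels)), levels)
    if (!is.null(odds)) {
      if (is.null(names(odds)) || !all(names(odds) %in% levels))
        stop("tilt odds must be named by category level")
      o[names(odds)] <- odds
    }
    p <- base * o
    p / sum(p)
  }
  assoc <- probe_id %in% truth$associated_loci
  draw <- function(levels, base, odds) {
    out <- character(length(probe_id))
    out[!assoc] <- sample(levels, sum(!assoc), TRUE, prob = base)
    if (any(assoc))
      out[assoc] <- sample(levels, sum(assoc), TRUE,
                           prob = tilt(base, levels, odds))
    out
  }
  region <- draw(region_levels, region_base, region_odds)
  cgi <- draw(cgi_levels, cgi_base, cgi_odds)

  n_genes <- max(100L, round(config$n_probes / 4))
  gene_pool <- sprintf("G%04d", seq_len(n_genes))
  k <- sample(0:2, length(probe_id), TRUE, prob = c(0.25, 0.65, 0.10))
  gene_symbols <- vapply(k, function(ki)
    paste(sample(gene_pool, ki), collapse = ";"), "")

  structure(data.frame(
    probe_id = probe_id,
    gene_symbols = gene_symbols,
    region_group = region,
    cgi_relation = cgi,
    snp_flag = runif(length(probe_id)) < snp_rate,
    crossreactive_flag = runif(length(probe_id)) < crossreactive_rate,
    chromosome = paste0("chr", sample(1:22, length(probe_id), TRUE)),
    position = sample.int(2^28, length(probe_id), replace = TRUE),
    stringsAsFactors = FALSE
  ), class = c("probe_annotation", "data.frame"))
}

#' Simulate a directed regulatory network with one planted SCC
#'
#' Builds a directed edge list whose only nontrivial strongly connected
#' component is a planted cycle of `scc_size` genes plus `extra_edges`
#' random chords, surrounded by an acyclic periphery (upstream regulators
#' pointing into the SCC and downstream targets receiving from it).
#' `scc_size = 0` disables the planted component and yields a pure DAG.
#'
#' @param n_genes total number of genes.
#' @param scc_size size of the planted strongly connected component
#'   (0 to disable; otherwise >= 2).
#' @param extra_edges number of chord edges added inside the SCC.
#' @param seed RNG seed.
#' @return list with `edges` (data.frame source, target, effect) and
#'   `planted_scc_nodes` (character vector, empty when disabled).
#' @export
simulate_network <- function(n_genes, scc_size = 60, extra_edges = 98,
                             seed = 1) {
  if (scc_size == 1 || scc_size < 0) stop("invalid: scc_size must be 0 or >= 2")
  if (scc_size > n_genes) stop("invalid: scc_size exceeds n_genes")
  set.seed(child_seed(seed, 4L))
  genes <- sprintf("G%04d", seq_len(n_genes))
  edges <- NULL
  scc_nodes <- character(0)

  if (scc_size >= 2) {
    scc_nodes <- genes[seq_len(scc_size)]
    ring <- sample(scc_nodes)
    edges <- cbind(ring, c(ring[-1], ring[1]))
    if (extra_edges > 0) {
      have <- paste(edges[, 1], edges[, 2])
      chords <- matrix(character(0), 0, 2)
      guard <- 0
      while (nrow(chords) < extra_edges) {
        guard <- guard + 1
        if (guard > 100 * extra_edges + 100)
          stop("cannot place the requested number of unique chords")
        s <- sample(scc_nodes, 1); t <- sample(scc_nodes, 1)
        key <- paste(s, t)
        if (s != t && !(key %in% have)) {
          chords <- rbind(chords, c(s, t)); have <- c(have, key)
        }
      }
      edges <- rbind(edges, chords)
    }
  }

  periphery <- setdiff(genes, scc_nodes)
  if (length(periphery) > 0) {
    if (length(scc_nodes) > 0) {
      half <- ceiling(length(periphery) / 2)
      upstream <- periphery[seq_len(half)]
      downstream <- periphery[-seq_len(half)]
      e_up <- cbind(upstream, sample(scc_nodes, length(upstream), TRUE))
      edges <- rbind(edges, e_up)
      if (length(downstream) > 0)
        edges <- rbind(edges, cbind(sample(scc_nodes, length(downstream), TRUE),
                                    downstream))
    } else {
      # pure DAG: edges only from earlier to later genes in a random order
      ord <- sample(genes)
      n_e <- max(1L, n_genes)
      from <- sample(seq_len(n_genes - 1), n_e, TRUE)
      to <- from + vapply(n_genes - from, function(m) sample.int(m, 1), 1L)
      edges <- cbind(ord[from], ord[to])
      edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), , drop = FALSE]
    }
  }
  edges <- data.frame(source = edges[, 1], target = edges[, 2],
                      effect = sample(c("activation", "inhibition", "unspecified"),
                                      nrow(edges), TRUE, prob = c(0.45, 0.35, 0.2)),
                      stringsAsFactors = FALSE)
  list(edges = edges, planted_scc_nodes = scc_nodes)
}

#' Deterministic synthetic regulatory network at published scale
#'
#' A fixed, RNG-free synthetic stand-in for a curated prior-knowledge
#' regulatory network of the size reported for iPSC-to-neuron
#' differentiation: 398 genes and 622 directed interactions whose unique
#' nontrivial strongly connected component has exactly 60 genes and 158
#' interactions, with hub node "STAT3" wired to have in-degree 7 and
#' out-degree 20 inside the component. All other node names are synthetic
#' symbols; the wiring is a deterministic construction, not real curated
#' interactions.
#'
#' @return data.frame with columns source, target, effect.
#' @export
#' @examples
#' net <- synthetic_regulatory_network()
#' nrow(net)  # 622
synthetic_regulatory_network <- function() {
  tf <- sprintf("TF%02d", 2:60)           # 59 ring partners of STAT3
  ring <- c("STAT3", tf)                  # 60-cycle
  edges <- cbind(ring, c(ring[-1], ring[1]))
  # hub wiring: 19 extra out-edges and 6 extra in-edges for STAT3
  extra_out <- sprintf("TF%02d", seq(4, 40, by = 2))
  edges <- rbind(edges, cbind("STAT3", extra_out))
  extra_in <- sprintf("TF%02d", c(10, 20, 30, 40, 50, 55))
  edges <- rbind(edges, cbind(extra_in, "STAT3"))
  # 73 systematic chords among the TF ring (offsets 2 and 3), none touching STAT3
  pos <- function(i) tf[((i - 1) %% 59) + 1]
  chords <- rbind(
    cbind(tf, pos(seq_len(59) + 2)),
    cbind(tf[1:14], pos(1:14 + 3))
  )
  edges <- rbind(edges, chords)          # 60 + 19 + 6 + 73 = 158 in-SCC edges
  # acyclic periphery: 200 upstream, 138 downstream, 464 edges
  pu <- sprintf("PU%03d", 1:200)
  pd <- sprintf("PD%03d", 1:138)
  edges <- rbind(edges,
                 cbind(pu, tf[((seq_along(pu) - 1) %% 59) + 1]),
                 cbind(pu[1:100], pu[2:101]),
                 cbind(tf[((seq_along(pd) - 1) %% 59) + 1], pd),
                 cbind(pd[1:26], pd[2:27]))
  effect <- rep_len(c("activation", "inhibition", "unspecified"), nrow(edges))
  data.frame(source = unname(edges[, 1]), target = unname(edges[, 2]),
             effect = effect, stringsAsFactors = FALSE)
}

#' Simulate an epigenetic clock consistent with the planted trajectory
#'
#' Builds a sparse linear clock whose linear predictor, applied to the
#' noiseless synthetic beta values, equals a linearly increasing target age
#' `age_min + (age_max - age_min) * true_time`. Coefficients are spread over
#' `n_clock_cpgs` linearly increasing associated loci, so prediction error
#' under noise shrinks as the number of clock CpGs grows.
#'
#' @param probe_ids probe universe (used to validate membership).
#' @param truth truth component of [simulate_beta_dataset()]; must contain
#'   associated loci from the linear-up module.
#' @param n_clock_cpgs number of CpGs given nonzero coefficients.
#' @param output_unit `"days_post_conception"` (default) or `"years"`.
#' @param seed RNG seed.
#' @param age_min,age_max target ages at latent time 0 and 1, in
#'   `output_unit` units (defaults span a fetal range of days).
#' @return a [clock_model()] with transform `"identity"`.
#' @export
simulate_clock <- function(probe_ids, truth, n_clock_cpgs = 40,
                           output_unit = "days_post_conception", seed = 1,
                           age_min = 50, age_max = 130) {
  if (n_clock_cpgs > length(probe_ids))
    stop("n_clock_cpgs exceeds the number of probes")
  set.seed(child_seed(seed, 5L))
  lp <- truth$locus_params
  linear_up <- lp[lp$module == 1, , drop = FALSE]
  if (nrow(linear_up) < n_clock_cpgs)
    stop("not enough linearly increasing associated loci for ", n_clock_cpgs,
         " clock CpGs (have ", nrow(linear_up), ")")
  pick <- linear_up[sample.int(nrow(linear_up), n_clock_cpgs), ]
  w <- runif(n_clock_cpgs, 0.5, 1.5); w <- w / sum(w)
  slope <- age_max - age_min
  coefs <- setNames(slope * w / pick$amplitude, pick$probe_id)
  intercept <- age_min - sum(coefs * pick$baseline)
  clock_model(name = "synthetic_linear_clock", coefficients = coefs,
              intercept = intercept, transform = "identity",
              output_unit = output_unit)
}

#' Simulate gene sets with planted enrichment
#'
#' Draws gene sets from the annotation's gene universe; `n_enriched` of them
#' preferentially sample genes annotated to trajectory-associated probes, so
#' bias-adjusted set enrichment has positives to find.
#'
#' @param annotation a [simulate_annotation()] table.
#' @param truth truth component of [simulate_beta_dataset()].
#' @param n_sets number of gene sets.
#' @param set_size genes per set.
#' @param n_enriched number of sets tilted toward associated genes.
#' @param enrich_weight sampling weight multiplier for associated genes in
#'   enriched sets.
#' @param seed RNG seed.
#' @return named list of character vectors (GMT-style gene sets).
#' @export
simulate_gene_sets <- function(annotation, truth, n_sets = 20, set_size = 25,
                               n_enriched = 3, enrich_weight = 15, seed = 1) {
  set.seed(child_seed(seed, 6L))
  all_genes <- unique(unlist(strsplit(annotation$gene_symbols[
    nzchar(annotation$gene_symbols)], ";", fixed = TRUE)))
  assoc_genes <- unique(unlist(strsplit(annotation$gene_symbols[
    annotation$probe_id %in% truth$associated_loci &
      nzchar(annotation$gene_symbols)], ";", fixed = TRUE)))
  w_flat <- setNames(rep(1, length(all_genes)), all_genes)
  w_tilt <- w_flat
  w_tilt[assoc_genes] <- enrich_weight
  sets <- lapply(seq_len(n_sets), function(i) {
    w <- if (i <= n_enriched) w_tilt else w_flat
    sample(all_genes, min(set_size, length(all_genes)), prob = w)
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  sets
}
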