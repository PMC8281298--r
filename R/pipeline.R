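#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks with the analysis defaults:
#' top-5% MAD selection, 2 principal components, k = 4 clusters, Bonferroni
#' at alpha 0.05, 9 shape modules. All values can be overridden by the
#' `config` argument of [run_pipeline()] (shallow-merged per block).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    sim = list(n_probes = 10000, n_stages = 4, replicates_per_stage = 4,
               frac_associated = 0.05, noise_sd = 0.03,
               n_failing_samples = 2),
    qc = list(detp_thresh = 0.05, sample_frac = 0.01, probe_frac = 0.01,
              bead_min = 3, bead_frac = 0.05, min_median = 1000),
    trajectory = list(fraction = 0.05, n_components = 2, k = 4),
    associate = list(alpha = 0.05, basis_dim = 4, n_modules = 9),
    clock = list(n_clock_cpgs = 40),
    enrich = list(enabled = TRUE),
    network = list(enabled = TRUE, n_genes = 398, scc_size = 60,
                   extra_edges = 98)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> QC -> normalize -> clock -> trajectory ->
#' associate -> enrich -> network on one synthetic dataset and collects the
#' summary quantities of each stage: samples retained, loci tested,
#' signature size and hypo/hyper split, per-module counts, clock ages per
#' stage with the ANOVA/Tukey table, enrichment tables, and the SCC size
#' with its top hub genes. The single `seed` drives every stage, so a rerun
#' with the same configuration is identical.
#'
#' @param config configuration list (merged over
#'   [default_pipeline_config()]) or path to a YAML file with the same
#'   structure.
#' @param out_dir optional directory; when given, intermediate artifacts,
#'   `report.json` and `report.md` are written there.
#' @return report list of class `methyltraj_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- cfg$seed
  scfg <- do.call(sim_config, c(cfg$sim, list(seed = seed)))

  sim <- simulate_beta_dataset(scfg)
  ip <- simulate_intensities(sim$beta, scfg)
  ann <- simulate_annotation(scfg, sim$truth)

  # --- QC: median intensity + detection-p filter, samples then probes
  med_fail <- median_intensity_check(ip, cfg$qc$min_median)
  qc <- pfilter(ip, cfg$qc$detp_thresh, cfg$qc$sample_frac,
                cfg$qc$probe_frac, cfg$qc$bead_min, cfg$qc$bead_frac)
  ip_clean <- apply_qc(ip, qc, extra_failed_samples = med_fail)
  samples <- sim$samples[sim$samples$sample_id %in% colnames(ip_clean$meth), ]

  # --- normalization and probe exclusion
  beta <- dasen_normalize(ip_clean)
  beta <- filter_probes(beta, ann)

  # --- epigenetic clock
  clock_block <- NULL
  clock <- tryCatch(
    simulate_clock(rownames(sim$beta), sim$truth,
                   n_clock_cpgs = cfg$clock$n_clock_cpgs, seed = seed),
    error = function(e) NULL)
  if (!is.null(clock)) {
    ages <- apply_clock(beta, clock)
    ages$stage <- samples$stage[match(ages$sample_id, samples$sample_id)]
    cmp <- stage_anova_tukey(ages$age, ages$stage)
    clock_block <- list(ages = ages,
                        mean_age_by_stage = tapply(ages$age, ages$stage, mean),
                        anova_F = cmp$anova_F, anova_p = cmp$anova_p,
                        tukey = cmp$pairwise)
  }

  # --- trajectory
  sel <- select_top_mad(beta, cfg$trajectory$fraction)
  space <- pca_reduce(beta[sel$selected_probes, , drop = FALSE],
                      cfg$trajectory$n_components)
  traj <- infer_trajectory(space, k = cfg$trajectory$k, seed = seed)
  traj <- orient_pseudotime(traj, samples, anchor_stage = samples$stage[1])

  # --- association scan
  scan <- trajectory_gam_scan(beta[sel$selected_probes, , drop = FALSE],
                              traj$pseudotime,
                              basis_dim = cfg$associate$basis_dim)
  sig <- bonferroni_select(scan, alpha = cfg$associate$alpha)
  module_counts <- NULL; module_change <- NULL
  if (nrow(sig) >= cfg$associate$n_modules) {
    sig <- assign_modules(sig, cfg$associate$n_modules)
    module_counts <- table(sig$module)
    st <- levels(factor(samples$stage))
    if (length(st) >= 2)
      module_change <- summarize_module_change(sig, beta, samples,
                                               st[1], st[2])
  }

  # --- enrichment
  enrich_block <- NULL
  if (isTRUE(cfg$enrich$enabled) && nrow(sig) > 0) {
    universe <- sel$selected_probes[sel$selected_probes %in% rownames(beta)]
    by_dir <- split(sig$probe_id, sig$direction)
    fe <- lapply(c(list(all = sig$probe_id), by_dir), function(probes) {
      list(region = feature_enrichment(probes, universe, ann, "region_group"),
           cgi = feature_enrichment(probes, universe, ann, "cgi_relation"))
    })
    counts <- gene_probe_counts(universe, ann)
    sig_genes <- map_probes_to_genes(sig$probe_id, ann)
    sets <- simulate_gene_sets(ann, sim$truth, seed = seed)
    go <- go_enrichment_bias_adjusted(sig_genes, counts, sets)
    enrich_block <- list(feature = fe, gene_sets = go,
                         n_signature_genes = length(sig_genes))
  }

  # --- network
  network_block <- NULL
  if (isTRUE(cfg$network$enabled)) {
    nsim <- simulate_network(cfg$network$n_genes, cfg$network$scc_size,
                             cfg$network$extra_edges, seed = seed)
    net <- load_edge_list(nsim$edges)
    scc <- extract_scc(net)
    if (!is.null(scc)) {
      metrics <- topology_metrics(scc)
      hubs <- rank_hub_genes(metrics)
      network_block <- list(scc_size = nrow(scc$nodes),
                            scc_edges = nrow(scc$edges),
                            planted_scc_recovered =
                              setequal(scc$nodes$name, nsim$planted_scc_nodes),
                            top_hubs = head(hubs, 5))
    }
  }

  report <- structure(list(
    seed = seed,
    samples_retained = nrow(samples),
    failed_samples = sort(union(med_fail, qc$failed_samples$sample_id)),
    probes_after_qc = nrow(beta),
    loci_tested = length(sel$selected_probes),
    explained_variance = space$explained_variance_fraction,
    pseudotime = traj$pseudotime,
    signature_size = nrow(sig),
    n_hypo = sum(sig$direction == "hypo"),
    n_hyper = sum(sig$direction == "hyper"),
    module_counts = module_counts,
    module_change_stage1_to_2 = module_change,
    clock = clock_block,
    enrichment = enrich_block,
    network = network_block,
    truth = sim$truth
  ), class = "methyltraj_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_matrix_tsv(beta, file.path(out_dir, "beta_normalized.tsv"))
    write.table(sig, file.path(out_dir, "signature.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
    png(file.path(out_dir, "trajectory.png"), 700, 600)
    plot(traj, space, samples)
    dev.off()
  }
  report
}

report_to_json <- function(r) {
  list(seed = r$seed, samples_retained = r$samples_retained,
       failed_samples = r$failed_samples,
       probes_after_qc = r$probes_after_qc, loci_tested = r$loci_tested,
       explained_variance = r$explained_variance,
       signature_size = r$signature_size,
       n_hypo = r$n_hypo, n_hyper = r$n_hyper,
       module_counts = if (!is.null(r$module_counts))
         as.list(setNames(as.integer(r$module_counts),
                          names(r$module_counts))),
       scc_size = r$network$scc_size, scc_edges = r$network$scc_edges,
       top_hub = r$network$top_hubs$gene[1])
}

format_report_md <- function(r) {
  c("# methyltraj pipeline report",
    "",
    sprintf("- seed: %d", r$seed),
    sprintf("- samples retained: %d (failed: %s)", r$samples_retained,
            paste(r$failed_samples, collapse = ", ")),
    sprintf("- probes after QC/exclusion: %d", r$probes_after_qc),
    sprintf("- loci tested (top MAD): %d", r$loci_tested),
    sprintf("- variance explained by PC1+PC2: %.1f%%",
            100 * sum(r$explained_variance[1:2])),
    sprintf("- signature: %d loci (%d hypo + %d hyper)", r$signature_size,
            r$n_hypo, r$n_hyper),
    if (!is.null(r$network))
      sprintf("- SCC: %d genes, %d interactions; top hub %s",
              r$network$scc_size, r$network$scc_edges,
              r$network$top_hubs$gene[1]))
}

#' @export
print.methyltraj_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
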