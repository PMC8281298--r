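#' Write / read a probes x samples matrix as TSV
#'
#' Probe id in the first column (`probe_id`), sample ids as the header.
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` the
#'   path, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stop_if_not_matrix(x)
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the standard file layout consumed by the pipeline: beta.tsv,
#' meth.tsv, unmeth.tsv, detp.tsv, beadcount.tsv, samples.csv,
#' annotation.tsv, clock.csv, genesets.gmt, network.tsv and truth.json.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param network_genes,network_scc_size,network_extra_edges parameters
#'   passed to [simulate_network()].
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(config, dir, network_genes = 398,
                          network_scc_size = 60, network_extra_edges = 98) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_beta_dataset(config)
  ip <- simulate_intensities(sim$beta, config)
  ann <- simulate_annotation(config, sim$truth)
  net <- simulate_network(network_genes, network_scc_size,
                          network_extra_edges, seed = config$seed)
  sets <- simulate_gene_sets(ann, sim$truth, seed = config$seed)

  write_matrix_tsv(sim$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(ip$meth, file.path(dir, "meth.tsv"))
  write_matrix_tsv(ip$unmeth, file.path(dir, "unmeth.tsv"))
  write_matrix_tsv(ip$detection_p, file.path(dir, "detp.tsv"))
  write_matrix_tsv(ip$beadcount, file.path(dir, "beadcount.tsv"))
  write.table(sim$samples, file.path(dir, "samples.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = names(ip$probe_type),
                         probe_type = unname(ip$probe_type)),
              file.path(dir, "probe_type.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  n_linear <- sum(sim$truth$locus_params$module == 1)
  if (n_linear >= 2) {
    clock <- simulate_clock(rownames(sim$beta), sim$truth,
                            n_clock_cpgs = min(40L, n_linear),
                            seed = config$seed)
    write_clock(clock, file.path(dir, "clock.csv"))
  }
  write_gmt(sets, file.path(dir, "genesets.gmt"))
  write.table(net$edges, file.path(dir, "network.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$planted_scc_nodes <- net$planted_scc_nodes
  truth$planted_failing_samples <- attr(ip, "planted_failures")
  truth$locus_params <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}
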