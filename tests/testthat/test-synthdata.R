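test_that("generator is deterministic under a fixed seed", {
  s1 <- small_sim(n_probes = 200, seed = 1)
  s2 <- small_sim(n_probes = 200, seed = 1)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$truth, s2$truth)
  i1 <- simulate_intensities(s1$beta, s1$config)
  i2 <- simulate_intensities(s2$beta, s2$config)
  expect_identical(i1$meth, i2$meth)
  a1 <- simulate_annotation(s1$config, s1$truth)
  expect_identical(a1, simulate_annotation(s2$config, s2$truth))
  n1 <- simulate_network(100, 10, 5, seed = 4)
  expect_identical(n1, simulate_network(100, 10, 5, seed = 4))
  s3 <- small_sim(n_probes = 200, seed = 2)
  expect_false(identical(s1$beta, s3$beta))
})

test_that("beta values are bounded and template structure is planted", {
  s <- small_sim(n_probes = 500, seed = 3)
  expect_true(all(s$beta >= 0 & s$beta <= 1))
  expect_length(s$truth$associated_loci, round(0.05 * 500))
  expect_setequal(unique(s$truth$module_label), 1:9)

  # zero-noise limit: a monotone-down locus decreases strictly with time
  s0 <- small_sim(n_probes = 200, seed = 5, noise_sd = 0)
  t <- s0$truth$true_time
  expect_gt(min(diff(sort(t))), 0)  # jitter makes times distinct
  down <- names(s0$truth$module_label)[s0$truth$module_label == 2]
  y <- s0$beta[down[1], order(t)]
  expect_true(all(diff(y) < 0))
  up <- names(s0$truth$module_label)[s0$truth$module_label == 1]
  expect_true(all(diff(s0$beta[up[1], order(t)]) > 0))
})

test_that("null config plants no structure and matches the noise level", {
  s <- small_sim(n_probes = 2000, seed = 7, frac_associated = 0,
                 noise_sd = 0.05)
  expect_length(s$truth$associated_loci, 0)
  # per-locus variance on the logit scale matches noise_sd^2 on average
  v <- apply(qlogis(s$beta), 1, var)
  expect_equal(mean(v), 0.05^2, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_probes = 10), "n_probes")
  expect_error(sim_config(n_probes = 100, frac_associated = 0.05),
               "every module")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_stages = 1, replicates_per_stage = 1),
               "fewer than 2 samples")
})

test_that("intensities invert the beta definition and plant QC failures", {
  beta <- rand_beta(50, 8, seed = 2)
  cfg <- sim_config(n_probes = 50, n_stages = 4, replicates_per_stage = 2,
                    frac_associated = 0.2, n_failing_samples = 1, seed = 2)
  ip <- simulate_intensities(beta, cfg, intensity_sd = 0, type1_offset = 0,
                             type2_offset = 0, failure_scale = 0.03)
  expect_true(min(ip$meth) > 0 && min(ip$unmeth) > 0)
  good <- setdiff(colnames(beta), attr(ip, "planted_failures"))
  # noiseless, offset-free: M + U = T and M/(M+U) = beta exactly
  expect_equal(ip$meth[, good] / (ip$meth[, good] + ip$unmeth[, good]),
               beta[, good], tolerance = 1e-12)
  # recomputed beta with the conventional offset is shrunk by T/(T+100)
  bhat <- compute_beta(ip, offset = 100)
  total <- ip$meth + ip$unmeth
  expect_true(max(abs(bhat - beta)[, good] - (100 / (total + 100) * beta)[, good]) < 1e-12)
  # the planted sample sits below any sensible median-intensity threshold
  fail <- attr(ip, "planted_failures")
  expect_identical(median_intensity_check(ip, 1000), fail)
  expect_identical(pfilter(ip)$failed_samples$sample_id, fail)
})

test_that("QC flags exactly the planted failing samples across seeds", {
  for (seed in 1:10) {
    s <- small_sim(n_probes = 100, seed = seed, frac_associated = 0.1)
    ip <- simulate_intensities(s$beta, s$config)
    planted <- attr(ip, "planted_failures")
    expect_setequal(pfilter(ip)$failed_samples$sample_id, planted)
    expect_setequal(median_intensity_check(ip, 1000), planted)
  }
})

test_that("annotation tilt plants a known enrichment odds ratio", {
  cfg <- sim_config(n_probes = 20000, frac_associated = 0.25, seed = 11)
  sim <- simulate_beta_dataset(cfg)
  ann <- simulate_annotation(cfg, sim$truth, region_odds = c(Body = 2))
  # direct 2x2 count on the emitted table: associated vs rest in Body
  assoc <- ann$probe_id %in% sim$truth$associated_loci
  body <- ann$region_group == "Body"
  or <- (sum(assoc & body) * sum(!assoc & !body)) /
    (sum(assoc & !body) * sum(!assoc & body))
  expect_equal(or, 2, tolerance = 0.15)
  # no tilt: odds ratio concentrates near 1
  ann0 <- simulate_annotation(cfg, sim$truth)
  body0 <- ann0$region_group == "Body"
  or0 <- (sum(assoc & body0) * sum(!assoc & !body0)) /
    (sum(assoc & !body0) * sum(!assoc & body0))
  expect_equal(or0, 1, tolerance = 0.15)
})

test_that("fully flagged annotation empties the probe filter", {
  s <- small_sim(n_probes = 100, seed = 1, frac_associated = 0.1)
  ann <- simulate_annotation(s$config, s$truth, snp_rate = 1)
  expect_error(filter_probes(s$beta, ann), "no probes remain")
})

test_that("planted network SCC matches brute-force reachability", {
  n <- simulate_network(50, 3, 0, seed = 1)
  net <- load_edge_list(n$edges)
  scc <- extract_scc(net)
  expect_setequal(scc$nodes$name, n$planted_scc_nodes)
  expect_equal(nrow(scc$edges), 3)   # bare 3-cycle

  for (seed in 1:5) {
    n <- simulate_network(60, 12, 10, seed = seed)
    net <- load_edge_list(n$edges)
    memb <- strongly_connected_components(net)
    ref <- brute_force_scc(net$edges, names(memb))
    expect_true(same_partition(memb, ref))
    expect_setequal(extract_scc(net)$nodes$name, n$planted_scc_nodes)
  }

  # scc_size = 0: pure DAG, no nontrivial component
  n0 <- simulate_network(40, 0, seed = 3)
  expect_message(res <- extract_scc(load_edge_list(n0$edges)),
                 "no nontrivial")
  expect_null(res)
  expect_error(simulate_network(40, 1, seed = 1), "invalid")
})

test_that("planted clock reproduces target ages and improves with size", {
  cfg <- sim_config(n_probes = 2000, frac_associated = 0.3, noise_sd = 0,
                    seed = 13)
  sim <- simulate_beta_dataset(cfg)
  clk <- simulate_clock(rownames(sim$beta), sim$truth, n_clock_cpgs = 30,
                        seed = 13)
  pred <- apply_clock(sim$beta, clk)
  target <- 50 + 80 * sim$truth$true_time[pred$sample_id]
  expect_equal(pred$age, unname(target), tolerance = 1e-8)

  # with noise, averaging over more clock CpGs shrinks the error
  mae <- sapply(c(4, 60), function(m) {
    errs <- sapply(1:8, function(r) {
      cfgn <- sim_config(n_probes = 2000, frac_associated = 0.3,
                         noise_sd = 0.1, seed = 13 + r)
      simn <- simulate_beta_dataset(cfgn)
      ck <- simulate_clock(rownames(simn$beta), simn$truth, n_clock_cpgs = m,
                           seed = r)
      p <- apply_clock(simn$beta, ck)
      mean(abs(p$age - (50 + 80 * simn$truth$true_time[p$sample_id])))
    })
    mean(errs)
  })
  expect_lt(mae[2], mae[1])
})

test_that("the deterministic stand-in regulatory network has the published scale", {
  edges <- synthetic_regulatory_network()
  expect_equal(nrow(edges), 622)
  expect_equal(length(unique(c(edges$source, edges$target))), 398)
  expect_false(any(duplicated(paste(edges$source, edges$target))))
  expect_false(any(edges$source == edges$target))
})
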