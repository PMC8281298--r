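test_that("pseudotime rounding is half-up to two decimals", {
  expect_equal(round_pseudotime(0.005), 0.01)
  expect_equal(round_pseudotime(0.0049), 0.00)
  expect_equal(round_pseudotime(0.125), 0.13)   # not banker's rounding
  t <- runif(50)
  expect_equal(round_pseudotime(round_pseudotime(t)), round_pseudotime(t))
  expect_error(round_pseudotime(1.2), "\\[0, 1\\]")
})

test_that("the vectorized scan agrees with per-locus reference fits", {
  set.seed(11)
  t <- study_design_time(seed = 11)
  beta <- null_beta(40, t, noise_sd = 0.05)
  beta[1, ] <- plogis(qlogis(0.3 + 0.4 * t) + rnorm(14, 0, 0.02))  # signal
  scan <- trajectory_gam_scan(beta, t)

  # oracle 1: classical F-test with the same basis via lm/anova
  tr <- round_pseudotime(unname(t))
  sm <- mgcv::smoothCon(mgcv::s(tr, k = 4, bs = "cr"),
                        data = data.frame(tr = tr), absorb.cons = TRUE)[[1]]
  for (i in c(1, 5, 17, 40)) {
    fit1 <- lm(beta[i, ] ~ sm$X)
    fit0 <- lm(beta[i, ] ~ 1)
    p_ref <- anova(fit0, fit1)$`Pr(>F)`[2]
    expect_equal(scan$pvalue[i], p_ref, tolerance = 1e-10)
  }

  # oracle 2: independent scalar reimplementation of the penalized fit
  S <- matrix(0, 4, 4); S[2:4, 2:4] <- sm$S[[1]]
  S <- S / mean(abs(sm$S[[1]][sm$S[[1]] != 0]))
  X <- cbind(1, sm$X)
  lams <- c(0, 10^seq(-4, 8, length.out = 25))
  for (i in c(2, 9)) {
    y <- beta[i, ]
    gcv <- sapply(lams, function(l) {
      H <- X %*% solve(crossprod(X) + l * S, t(X))
      sum((y - H %*% y)^2) * 14 / (14 - sum(diag(H)))^2
    })
    l <- lams[which.min(gcv)]
    H <- X %*% solve(crossprod(X) + l * S, t(X))
    expect_equal(scan$edf[i], sum(diag(H)), tolerance = 1e-8)
  }

  # a single-locus fit equals the corresponding row of the scan
  one <- fit_locus_gam(beta[1, ], t)
  expect_equal(one$pvalue, scan$pvalue[1])
  expect_equal(one$delta_end, scan$delta_end[1])
})

test_that("scan results match mgcv on unpenalized strong-signal fits", {
  set.seed(12)
  t <- study_design_time(seed = 12)
  y <- 0.2 + 0.5 * t + rnorm(14, 0, 0.002)
  names(y) <- names(t)
  fit <- fit_locus_gam(y, t)
  expect_lt(fit$pvalue, 1e-6)
  expect_equal(fit$delta_end, 0.5, tolerance = 0.05)
  # the fitted trend is the planted line over the whole pseudotime grid
  expect_lt(max(abs(attr(fit, "fitted_curves")[1, ] -
                      (0.2 + 0.5 * attr(fit, "grid")))), 0.01)
  # mgcv cross-check of the fitted trend at the observed pseudotimes
  g <- mgcv::gam(y ~ s(tt, k = 4, bs = "cr"),
                 data = data.frame(y = y, tt = round_pseudotime(unname(t))))
  curves <- attr(fit, "fitted_curves")
  grid <- attr(fit, "grid")
  pred <- predict(g, data.frame(tt = grid))
  expect_lt(max(abs(curves[1, ] - pred)), 0.01)
})

test_that("null p-values are uniform and fitted curves stay bounded", {
  set.seed(13)
  t <- study_design_time(seed = 13)
  beta <- null_beta(2000, t, noise_sd = 0.03)
  scan <- trajectory_gam_scan(beta, t)
  ks <- suppressWarnings(ks.test(scan$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  curves <- attr(scan, "fitted_curves")
  expect_true(all(curves > -0.1 & curves < 1.1))
  expect_true(all(scan$edf >= 2 - 1e-6 & scan$edf <= 4 + 1e-6))
})

test_that("planted shapes are detected with genome-scale correction", {
  set.seed(14)
  t <- study_design_time(seed = 14)
  thresh <- 0.05 / 10000
  # non-monotone transient shape at low noise
  y <- plogis(qlogis(0.25 + 0.4 * 4 * t * (1 - t)) + rnorm(14, 0, 0.02))
  names(y) <- names(t)
  expect_lt(fit_locus_gam(y, t)$pvalue, thresh)

  # power: monotone amplitude 0.3 at noise 0.05, detection rate >= 0.9
  n_rep <- 200
  beta <- plogis(qlogis(matrix(0.25 + 0.3 * t, n_rep, 14, byrow = TRUE)) +
                   matrix(rnorm(n_rep * 14, 0, 0.05), n_rep))
  dimnames(beta) <- list(sprintf("cg%08d", 1:n_rep), names(t))
  scan <- trajectory_gam_scan(beta, t)
  expect_gte(mean(scan$pvalue < thresh), 0.9)
})

test_that("Bonferroni selection applies the exact threshold", {
  scan <- structure(data.frame(probe_id = c("a", "b", "c"),
                               pvalue = c(1e-8, 1e-5, 2e-6),
                               edf = 2, delta_end = c(-1, 1, 1) * 0.2),
                    class = c("gam_scan", "data.frame"))
  attr(scan, "fitted_curves") <- matrix(0, 3, 101,
                                        dimnames = list(c("a", "b", "c"), NULL))
  attr(scan, "grid") <- seq(0, 1, length.out = 101)
  sig <- bonferroni_select(scan, alpha = 0.05, n_tests = 41851)
  expect_equal(attr(sig, "n_tests"), 41851)
  # 0.05 / 41851 ~ 1.1947e-6: keeps 1e-8, drops 1e-5 and 2e-6
  expect_identical(sig$probe_id, "a")
  expect_identical(sig$direction, "hypo")

  empty <- scan[0, , drop = FALSE]
  attr(empty, "fitted_curves") <- matrix(0, 0, 101)
  attr(empty, "grid") <- attr(scan, "grid")
  class(empty) <- class(scan)
  expect_equal(nrow(bonferroni_select(empty)), 0)

  all1 <- scan; all1$pvalue <- rep(1, 3)
  expect_equal(nrow(bonferroni_select(all1)), 0)
})

test_that("direction split always partitions the signature", {
  expect_identical(classify_direction(c(-0.2, 0.3)), c("hypo", "hyper"))
  expect_warning(d0 <- classify_direction(0), "convention")
  expect_identical(d0, "hyper")

  s <- small_sim(n_probes = 1500, seed = 15)
  sel <- select_top_mad(s$beta, 0.1)
  sp <- pca_reduce(s$beta[sel$selected_probes, ], 2)
  traj <- infer_trajectory(sp, k = 4, seed = 15)
  scan <- trajectory_gam_scan(s$beta[sel$selected_probes, ], traj$pseudotime)
  sig <- bonferroni_select(scan)
  expect_gt(nrow(sig), 0)
  expect_equal(sum(sig$direction == "hypo") + sum(sig$direction == "hyper"),
               nrow(sig))

  # direction matches the template's end-to-end sign for planted loci
  orient <- orient_pseudotime(traj, s$samples, "iPSC")
  scan_o <- trajectory_gam_scan(s$beta[sel$selected_probes, ],
                                orient$pseudotime)
  sig_o <- bonferroni_select(scan_o)
  sig_o <- sig_o[sig_o$probe_id %in% s$truth$associated_loci, ]
  mod <- s$truth$module_label[sig_o$probe_id]
  shapes <- module_shapes()
  temp_sign <- vapply(shapes, function(f) sign(f(1) - f(0)), 0)[mod]
  informative <- temp_sign != 0      # transient shapes end where they start
  agree <- (sig_o$direction == "hyper") == (temp_sign > 0)
  expect_gte(mean(agree[informative]), 0.99)
})

test_that("module assignment recovers well-separated planted shapes", {
  skip_if_not_installed("mclust")
  s <- small_sim(n_probes = 2000, seed = 16, noise_sd = 0.015)
  sel <- select_top_mad(s$beta, 0.1)
  sp <- pca_reduce(s$beta[sel$selected_probes, ], 2)
  traj <- orient_pseudotime(infer_trajectory(sp, k = 4, seed = 16),
                            s$samples, "iPSC")
  scan <- trajectory_gam_scan(s$beta[sel$selected_probes, ], traj$pseudotime)
  sig <- assign_modules(bonferroni_select(scan))
  truth_lab <- s$truth$module_label[sig$probe_id]
  keep <- !is.na(truth_lab)
  ari <- mclust::adjustedRandIndex(sig$module[keep], truth_lab[keep])
  expect_gte(ari, 0.9)
  # deterministic relabeling: a second run is identical
  sig2 <- assign_modules(bonferroni_select(scan))
  expect_identical(sig$module, sig2$module)
})

test_that("module assignment handles degenerate requests", {
  scan <- structure(data.frame(probe_id = paste0("p", 1:5),
                               pvalue = rep(1e-9, 5), edf = 2,
                               delta_end = 0.1),
                    class = c("gam_scan", "data.frame"))
  attr(scan, "fitted_curves") <- matrix(rep(seq(0, 1, length.out = 101),
                                            each = 5), 5,
                                        dimnames = list(paste0("p", 1:5), NULL))
  attr(scan, "grid") <- seq(0, 1, length.out = 101)
  sig <- bonferroni_select(scan)
  expect_error(assign_modules(sig, n_modules = 9), "fewer loci")
  one <- assign_modules(sig, n_modules = 1)
  expect_identical(one$module, rep(1L, 5))
})

test_that("module change summaries are stage means in percentage points", {
  probes <- paste0("p", 1:4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        stage = c("A", "A", "B", "B"),
                        stringsAsFactors = FALSE)
  beta <- rbind(c(0.9, 0.9, 0.4, 0.4),    # -50 percentage points
                c(0.8, 0.8, 0.3, 0.3),    # -50
                c(0.2, 0.2, 0.5, 0.5),    # +30
                c(0.5, 0.5, 0.5, 0.5))    # 0
  dimnames(beta) <- list(probes, samples$sample_id)
  sig <- structure(data.frame(probe_id = probes, pvalue = 1e-9,
                              direction = "hypo", delta_end = -0.1,
                              module = c(1L, 1L, 2L, 3L)),
                   class = c("trajectory_signature", "data.frame"))
  got <- summarize_module_change(sig, beta, samples, "A", "B")
  expect_equal(unname(got), c(-50, 30, 0))
  rev <- summarize_module_change(sig, beta, samples, "B", "A")
  expect_equal(unname(rev), -unname(got))    # antisymmetry
  expect_error(summarize_module_change(sig, beta, samples, "A", "Z"),
               "unknown stage")
})
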