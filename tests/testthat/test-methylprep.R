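test_that("compute_beta matches the elementwise definition", {
  expect_equal(500 / (500 + 500 + 100), 5 / 11)
  beta <- rand_beta(20, 4, seed = 8)
  ip <- toy_intensities(beta, total = 2000)
  got <- compute_beta(ip, offset = 100)
  # scalar-loop oracle
  want <- got
  for (i in seq_len(nrow(beta)))
    for (j in seq_len(ncol(beta)))
      want[i, j] <- ip$meth[i, j] / (ip$meth[i, j] + ip$unmeth[i, j] + 100)
  expect_equal(got, want)
  expect_true(all(got >= 0 & got <= 1))
  expect_error(compute_beta(ip, offset = -1), "nonnegative")
})

test_that("pfilter assesses samples first, then probes", {
  beta <- rand_beta(200, 10, seed = 3)
  ip <- toy_intensities(beta)
  clean <- pfilter(ip)
  expect_equal(nrow(clean$failed_samples), 0)
  expect_equal(nrow(clean$removed_probes), 0)
  expect_equal(clean$counts$samples_after, 10)
  expect_equal(clean$counts$probes_after,
               clean$counts$probes_before - nrow(clean$removed_probes))

  # one bad sample and one bad probe; the probe is only bad because the
  # bad sample is removed first
  detp <- ip$detection_p
  detp[, "S03"] <- 0.5                      # sample failure
  detp["cg00000007", c("S01", "S02")] <- 0.5  # probe failing in 2/9 survivors
  ip2 <- intensity_pair(ip$meth, ip$unmeth, detp, probe_type = ip$probe_type)
  rep2 <- pfilter(ip2)
  expect_identical(rep2$failed_samples$sample_id, "S03")
  expect_identical(rep2$removed_probes$probe_id, "cg00000007")

  # all samples failing is an explicit error
  detp[] <- 1
  ip3 <- intensity_pair(ip$meth, ip$unmeth, detp, probe_type = ip$probe_type)
  expect_error(pfilter(ip3), "empty dataset")
})

test_that("a 16-sample run with 2 planted failures keeps 14 samples", {
  s <- small_sim(n_probes = 300, seed = 21, frac_associated = 0.1)
  ip <- simulate_intensities(s$beta, s$config)
  qc <- pfilter(ip)
  expect_equal(qc$counts$samples_before, 16)
  expect_equal(qc$counts$samples_after, 14)
  clean <- apply_qc(ip, qc, median_intensity_check(ip, 1000))
  expect_equal(ncol(clean$meth), 14)
})

test_that("median intensity check flags only low-intensity samples", {
  beta <- rand_beta(100, 6, seed = 5)
  ip <- toy_intensities(beta, total = 4000)
  expect_identical(median_intensity_check(ip, 0), character(0))
  expect_identical(median_intensity_check(ip, 100), character(0))
  m <- ip$meth; u <- ip$unmeth
  m[, 4] <- m[, 4] * 0.01; u[, 4] <- u[, 4] * 0.01
  ip2 <- intensity_pair(m, u, ip$detection_p, probe_type = ip$probe_type)
  expect_identical(median_intensity_check(ip2, 100), "S04")
})

test_that("quantile normalization is a no-op on identical distributions", {
  beta <- rand_beta(60, 5, seed = 9)
  ip <- toy_intensities(beta, total = 3000)   # all type II: no bg adjustment
  ident <- intensity_pair(matrix(ip$meth[, 1], 60, 5, dimnames = dimnames(ip$meth)),
                          matrix(ip$unmeth[, 1], 60, 5, dimnames = dimnames(ip$meth)),
                          ip$detection_p, probe_type = ip$probe_type)
  expect_equal(dasen_normalize(ident), compute_beta(ident), tolerance = 1e-12)
})

test_that("dasen equalizes within-type order statistics across samples", {
  beta <- rand_beta(500, 6, seed = 10)
  cfg <- sim_config(n_probes = 500, frac_associated = 0.1, seed = 10,
                    n_failing_samples = 0)
  ip <- simulate_intensities(beta, cfg)
  out <- dasen_normalize(ip, return_intensities = TRUE)
  for (ty in c("I", "II")) {
    idx <- which(ip$probe_type == ty)
    # within-type order statistics agree exactly across samples
    sorted_m <- apply(out$meth[idx, ], 2, sort)
    expect_lt(max(abs(sorted_m - rowMeans(sorted_m))), 1e-9)
    sorted_u <- apply(out$unmeth[idx, ], 2, sort)
    expect_lt(max(abs(sorted_u - rowMeans(sorted_u))), 1e-9)
    # quantile normalization is monotone: intensity ranks are preserved
    for (s in 1:6) {
      expect_identical(order(out$meth[idx, s]), order(ip$meth[idx, s]))
      expect_identical(order(out$unmeth[idx, s]), order(ip$unmeth[idx, s]))
    }
  }
})

test_that("dasen matches a hand-worked order-statistic oracle", {
  # 3 probes x 2 samples, all type II, zero offset: quantile-normalized
  # M columns both become the mean of the sorted columns
  m <- matrix(c(100, 300, 200,
                400, 150, 350), 3, 2,
              dimnames = list(paste0("cg0000000", 1:3), c("A", "B")))
  u <- matrix(c(300, 100, 200,
                100, 450, 150), 3, 2, dimnames = dimnames(m))
  detp <- matrix(0, 3, 2, dimnames = dimnames(m))
  ip <- intensity_pair(m, u, detp,
                       probe_type = setNames(rep("II", 3), rownames(m)))
  got <- dasen_normalize(ip, offset = 100)
  m_sorted_mean <- rowMeans(apply(m, 2, sort))   # 125, 250, 375
  u_sorted_mean <- rowMeans(apply(u, 2, sort))   # 100, 175, 375
  mq <- cbind(m_sorted_mean[rank(m[, 1])], m_sorted_mean[rank(m[, 2])])
  uq <- cbind(u_sorted_mean[rank(u[, 1])], u_sorted_mean[rank(u[, 2])])
  want <- mq / (mq + uq + 100)
  dimnames(want) <- dimnames(m)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("type-I background is shifted onto the type-II background", {
  set.seed(4)
  n <- 400
  ids <- sprintf("cg%08d", 1:n)
  type <- setNames(rep(c("I", "II"), each = n / 2), ids)
  base <- matrix(runif(n * 4, 500, 4000), n, dimnames = list(ids, paste0("S", 1:4)))
  m <- base; m[type == "I", ] <- m[type == "I", ] + 800  # type-I offset
  u <- base[n:1, ]; dimnames(u) <- dimnames(m)
  u[type == "I", ] <- u[type == "I", ] + 800
  ip <- intensity_pair(m, u, matrix(0, n, 4, dimnames = dimnames(m)),
                       probe_type = type)
  out <- dasen_normalize(ip, low_quantile = 0.05)
  # after normalization the two chemistries have comparable medians
  med1 <- median(out[type == "I", ]); med2 <- median(out[type == "II", ])
  expect_lt(abs(med1 - med2), 0.1)
})

test_that("probe exclusion removes flagged probes and is idempotent", {
  beta <- rand_beta(1000, 4, seed = 6)
  ann <- data.frame(probe_id = rownames(beta),
                    snp_flag = c(rep(TRUE, 100), rep(FALSE, 900)),
                    crossreactive_flag = c(rep(FALSE, 950), rep(TRUE, 50)),
                    stringsAsFactors = FALSE)
  out <- filter_probes(beta, ann)
  expect_equal(nrow(out), 850)
  expect_identical(filter_probes(out, ann), out)    # idempotent

  ann_none <- transform(ann, snp_flag = FALSE, crossreactive_flag = FALSE)
  expect_identical(filter_probes(beta, ann_none), beta)
  ann_all <- transform(ann, snp_flag = TRUE)
  expect_error(filter_probes(beta, ann_all), "no probes remain")
  expect_warning(filter_probes(beta, ann[-1, ]), "missing from the annotation")
})
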