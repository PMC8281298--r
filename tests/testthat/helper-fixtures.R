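# shared fixture builders; everything is generated in code at test time

small_sim <- function(n_probes = 1000, seed = 1, noise_sd = 0.03,
                      frac_associated = 0.05, ...) {
  cfg <- sim_config(n_probes = n_probes, seed = seed, noise_sd = noise_sd,
                    frac_associated = frac_associated, ...)
  c(simulate_beta_dataset(cfg), list(config = cfg))
}

# a small intensity_pair built by hand (no background, no noise)
toy_intensities <- function(beta, total = 1000) {
  meth <- beta * total
  unmeth <- (1 - beta) * total
  detp <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  intensity_pair(meth, unmeth, detp,
                 probe_type = setNames(rep("II", nrow(beta)), rownames(beta)))
}

rand_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes,
         dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

# the 14-sample post-QC pseudotime design used throughout: 2 iPSC + 3 x 4
study_design_time <- function(seed = 1, jitter = 0.01) {
  set.seed(seed)
  t0 <- rep(c(0, 1/3, 2/3, 1), c(2, 4, 4, 4))
  t <- pmin(1, pmax(0, t0 + rnorm(14, 0, jitter)))
  names(t) <- sprintf("S%02d", seq_len(14))
  t
}

# null beta matrix on the study design: flat loci + logit-scale noise
null_beta <- function(n_probes, t, noise_sd = 0.03) {
  base <- runif(n_probes, 0.1, 0.9)
  clean <- matrix(base, n_probes, length(t))
  b <- plogis(qlogis(clean) + matrix(rnorm(n_probes * length(t), 0, noise_sd),
                                     n_probes))
  dimnames(b) <- list(sprintf("cg%08d", seq_len(n_probes)), names(t))
  b
}

# independent brute-force reachability SCC partition (boolean closure)
brute_force_scc <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  memb <- match(apply(mutual, 1, paste, collapse = ""),
                unique(apply(mutual, 1, paste, collapse = "")))
  setNames(memb, nodes)
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# independent two-sided Fisher p by explicit enumeration with choose()
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; n <- a + b
  N <- m1 + m2
  support <- max(0, n - m2):min(n, m1)
  pr <- choose(m1, support) * choose(m2, n - support) / choose(N, n)
  obs <- choose(m1, a) * choose(m2, n - a) / choose(N, n)
  sum(pr[pr <= obs * (1 + 1e-7)])
}
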