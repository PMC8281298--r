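#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The table is laid out as `a` = signature probes in the category, `b` =
#' signature probes outside it, `c` = background-only probes in the
#' category, `d` = background-only outside. The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the same margins that
#' are no more likely than the observed one (with a relative tie tolerance
#' of 1e-7, matching the convention of [stats::fisher.test()]).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_two_sided(8, 2, 2, 8)   # ~0.023
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  m1 <- a + c          # category margin
  m2 <- b + d
  n <- a + b           # signature margin
  if (m1 == 0 || m2 == 0 || n == 0 || c + d == 0) {
    warning("zero margin; p-value is 1")
    return(1)
  }
  support <- max(0, n - m2):min(n, m1)
  probs <- dhyper(support, m1, m2, n)
  obs <- dhyper(a, m1, m2, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Cross-product odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`; infinite when `b * c = 0` with `a * d > 0`, and
#' `NaN` when both cross products vanish.
#'
#' @inheritParams fisher_exact_two_sided
#' @return sample odds ratio.
#' @export
odds_ratio <- function(a, b, c, d) {
  (a * d) / (b * c)
}

#' Genomic-feature enrichment of a probe signature
#'
#' For every level of an annotation category (gene-region group or
#' CpG-island relation), builds the 2x2 table of signature vs background
#' membership against the given universe and reports the cross-product odds
#' ratio with the two-sided Fisher exact p-value. The natural universe is
#' the set of loci that entered the trajectory scan, so enrichment is
#' conditional on the tested loci.
#'
#' @param signature_probes character vector of signature probe ids.
#' @param universe_probes character vector containing the signature.
#' @param annotation a `probe_annotation` data.frame.
#' @param category_field annotation column to test (`"region_group"` or
#'   `"cgi_relation"`).
#' @return data.frame with category, odds_ratio, pvalue and the table
#'   counts a, b, c, d.
#' @export
feature_enrichment <- function(signature_probes, universe_probes, annotation,
                               category_field = "region_group") {
  if (length(signature_probes) == 0 || length(universe_probes) == 0)
    stop("signature and universe must be non-empty")
  if (!all(signature_probes %in% universe_probes))
    stop("signature must be a subset of the universe")
  if (!category_field %in% names(annotation))
    stop("unknown annotation column: ", category_field)
  idx <- match(universe_probes, annotation$probe_id)
  if (anyNA(idx)) stop("universe contains probes missing from the annotation")
  cat_u <- annotation[[category_field]][idx]
  in_sig <- universe_probes %in% signature_probes
  n_sig <- sum(in_sig)
  n_bg <- length(universe_probes) - n_sig
  res <- lapply(sort(unique(cat_u)), function(lv) {
    a <- sum(in_sig & cat_u == lv)
    b <- n_sig - a
    cc <- sum(!in_sig & cat_u == lv)
    d <- n_bg - cc
    data.frame(category = lv, odds_ratio = odds_ratio(a, b, cc, d),
               pvalue = fisher_exact_two_sided(a, b, cc, d),
               a = a, b = b, c = cc, d = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Map probes to annotated genes
#'
#' @param probes character vector of probe ids.
#' @param annotation a `probe_annotation` data.frame with a ";"-separated
#'   `gene_symbols` column.
#' @return character vector of unique gene symbols annotated to the probes.
#' @export
map_probes_to_genes <- function(probes, annotation) {
  sym <- annotation$gene_symbols[match(probes, annotation$probe_id)]
  sym <- sym[!is.na(sym) & nzchar(sym)]
  unique(unlist(strsplit(sym, ";", fixed = TRUE)))
}

#' Probes-per-gene counts (the gene-set bias covariate)
#'
#' @param probes probe universe over which to count.
#' @param annotation a `probe_annotation` data.frame.
#' @return named integer vector: probes annotated to each gene.
#' @export
gene_probe_counts <- function(probes, annotation) {
  sym <- annotation$gene_symbols[match(probes, annotation$probe_id)]
  sym <- sym[!is.na(sym) & nzchar(sym)]
  genes <- unlist(strsplit(sym, ";", fixed = TRUE))
  table_g <- table(genes)
  setNames(as.integer(table_g), names(table_g))
}

# Wallenius noncentral hypergeometric pmf.
# P(X = x) when n items are drawn without replacement from m1 "white" and
# m2 "black" items, white items having odds `odds` of being drawn. The
# defining integral  C * I[0,1] (1 - u^(odds/D))^x (1 - u^(1/D))^(n-x) du
# is evaluated after the substitution u = v^D, which turns it into a
# Beta(D, n-x+1) expectation of the bounded factor (1 - v^odds)^x; the
# Beta quantile transform keeps the quadrature stable even when the
# integrand mass is extremely concentrated (large universes).
wallenius_pmf <- function(x, m1, m2, n, odds) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  D <- odds * (m1 - x) + (m2 - (n - x))
  lc <- lchoose(m1, x) + lchoose(m2, n - x)
  if (D <= 0) return(exp(lc) * as.numeric(x == m1 && (n - x) == m2))
  b2 <- n - x + 1
  if (x == 0) {
    expectation <- 1
  } else {
    h <- function(s) {
      v <- qbeta(s, D, b2)
      a <- pmin(v^odds, 1 - 1e-16)
      exp(x * log1p(-a))
    }
    expectation <- integrate(h, 0, 1, rel.tol = 1e-11, abs.tol = 1e-13,
                             subdivisions = 1000L, stop.on.error = FALSE)$value
  }
  val <- exp(lc + log(D) + lbeta(D, b2)) * expectation
  min(1, max(0, val))
}

#' Wallenius noncentral hypergeometric upper tail
#'
#' `P(X >= x)` for the Wallenius distribution: drawing `n` genes without
#' replacement from `m1` in-set and `m2` out-of-set genes, in-set genes
#' having selection odds `odds`. With `odds = 1` this reduces to the
#' central hypergeometric tail.
#'
#' @param x observed in-set count.
#' @param m1,m2 in-set and out-of-set universe sizes.
#' @param n number of drawn (significant) genes.
#' @param odds in-set selection odds.
#' @return upper-tail probability.
#' @export
wallenius_tail <- function(x, m1, m2, n, odds = 1) {
  if (x <= max(0, n - m2)) return(1)
  support <- x:min(n, m1)
  p <- sum(vapply(support, wallenius_pmf, 0, m1 = m1, m2 = m2, n = n,
                  odds = odds))
  min(1, max(0, p))
}

#' Probe-bias-adjusted gene-set enrichment
#'
#' Gene-set enrichment that corrects for the uneven number of probes per
#' gene on the array. Each gene's probability of being called significant
#' is estimated as a moving average of the significance indicator over
#' genes ordered by their probe count; per set, the in-set vs out-of-set
#' mean selection probabilities are converted to an odds parameter and the
#' p-value is the Wallenius noncentral hypergeometric upper tail of the
#' observed in-set significant count. P-values are Benjamini-Hochberg
#' corrected across sets.
#'
#' @param significant_genes character vector of significant gene symbols.
#' @param universe_counts named probes-per-gene counts over the tested
#'   universe (see [gene_probe_counts()]); its names define the gene
#'   universe.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param window moving-average window (odd; default 10% of the universe,
#'   at least 5).
#' @return data.frame with set_id, n_genes_in_set, n_significant_genes,
#'   odds, pvalue, fdr_q, ordered by p-value. Sets with no universe
#'   overlap are skipped with a message.
#' @export
go_enrichment_bias_adjusted <- function(significant_genes, universe_counts,
                                        gene_sets, window = NULL) {
  universe <- names(universe_counts)
  if (is.null(universe) || length(universe) == 0)
    stop("universe_counts must be a named vector")
  de <- universe %in% significant_genes
  n_sig <- sum(de)

  w <- window %||% max(5, round(0.1 * length(universe)))
  if (w %% 2 == 0) w <- w + 1
  ord <- order(universe_counts, universe)
  pwf <- numeric(length(universe))
  cs <- cumsum(de[ord])
  half <- (w - 1) / 2
  for (i in seq_along(ord)) {
    lo <- max(1, i - half); hi <- min(length(ord), i + half)
    pwf[ord[i]] <- (cs[hi] - if (lo > 1) cs[lo - 1] else 0) / (hi - lo + 1)
  }
  # pwf must be a function of the probe count: average within tied counts
  pwf <- ave(pwf, universe_counts)
  # clamp away from 0/1 so odds are finite
  pwf <- pmin(pmax(pwf, 1e-6), 1 - 1e-6)

  res <- lapply(names(gene_sets), function(id) {
    in_set <- universe %in% gene_sets[[id]]
    m1 <- sum(in_set)
    if (m1 == 0) {
      message("gene set ", id, " has no overlap with the universe; skipped")
      return(NULL)
    }
    m2 <- length(universe) - m1
    x <- sum(in_set & de)
    if (n_sig == 0) {
      odds <- 1; p <- 1
    } else {
      p_in <- mean(pwf[in_set])
      p_out <- if (m2 > 0) mean(pwf[!in_set]) else p_in
      odds <- (p_in / (1 - p_in)) / (p_out / (1 - p_out))
      p <- wallenius_tail(x, m1, m2, n_sig, odds)
    }
    data.frame(set_id = id, n_genes_in_set = m1, n_significant_genes = x,
               odds = odds, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) stop("no gene set overlaps the universe")
  out$fdr_q <- bh_fdr(out$pvalue)
  out[order(out$pvalue, out$set_id), , drop = FALSE]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values, `q_(i) = min_{j >= i} p_(j) * m / j`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated lines: set id, description, then member gene symbols.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `description` attribute per set; `write_gmt` its path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    structure(f[-(1:2)], description = f[2])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop("sets must be named")
  desc <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), ""),
    path)
  invisible(path)
}
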