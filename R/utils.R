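# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from one global seed. Kept below 2^31 - 1
# so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + stream * 9973) %% 2147483647)
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must have probe rownames and sample colnames", name),
         call. = FALSE)
  invisible(x)
}

check_beta <- function(beta) {
  stop_if_not_matrix(beta, "beta")
  if (anyNA(beta)) stop("beta matrix contains missing values", call. = FALSE)
  if (min(beta) < 0 || max(beta) > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  invisible(beta)
}

check_sample_sheet <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "stage") %in% names(samples)))
    stop("sample sheet must be a data.frame with columns sample_id and stage",
         call. = FALSE)
  invisible(samples)
}

#' Row-wise median absolute deviation
#'
#' MAD of every row of a matrix, `median(|x - median(x)|) * constant`. The
#' default constant 1.4826 makes the MAD a consistent estimator of the
#' standard deviation under normality; any positive constant leaves the
#' ranking of rows, and hence top-fraction selection, unchanged.
#'
#' @param x numeric matrix (probes x samples), no missing values.
#' @param constant consistency constant, default 1.4826.
#' @return named numeric vector of per-row MADs.
#' @seealso [stats::mad()] for the single-vector version this matches.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("p", 1:4), NULL))
#' row_mads(m)
row_mads <- function(x, constant = 1.4826) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x)) stop("'x' contains missing values")
  out <- row_mads_cpp(x, constant)
  names(out) <- rownames(x)
  out
}
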