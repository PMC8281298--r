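#' Epigenetic clock model
#'
#' A sparse linear age predictor over CpGs: `linear_predictor = intercept +
#' sum(coef_i * beta_i)`, followed by an optional output transform. The
#' `horvath_antitrafo` transform maps the predictor to years via the
#' piecewise log-linear inverse used by pan-tissue clocks; `identity` leaves
#' it on the scale of `output_unit` (e.g. a fetal clock reporting days
#' post-conception directly).
#'
#' @param name clock name (used in messages).
#' @param coefficients named numeric vector, probe id -> coefficient.
#' @param intercept intercept of the linear predictor.
#' @param transform `"identity"` or `"horvath_antitrafo"`.
#' @param output_unit `"years"` or `"days_post_conception"`.
#' @param adult_age maturity parameter of `horvath_antitrafo`.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, coefficients, intercept = 0,
                        transform = c("identity", "horvath_antitrafo"),
                        output_unit = c("years", "days_post_conception"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  output_unit <- match.arg(output_unit)
  if (length(coefficients) == 0 || is.null(names(coefficients)))
    stop("coefficients must be a non-empty named vector")
  structure(list(name = name, coefficients = coefficients,
                 intercept = intercept, transform = transform,
                 output_unit = output_unit, adult_age = adult_age),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model '%s': %d CpGs, transform %s, unit %s\n",
              x$name, length(x$coefficients), x$transform, x$output_unit))
  invisible(x)
}

#' Piecewise age transform of pan-tissue clocks
#'
#' Maps the clock's linear predictor `m` to age in years:
#' `(1 + adult_age) * exp(m) - 1` for `m < 0` (a log scale compressing
#' pre-adult ages) and `(1 + adult_age) * m + adult_age` otherwise. The two
#' branches meet continuously at `m = 0` (age `adult_age`), and the function
#' is strictly increasing with lower limit -1 year (conception on a
#' birth-centered scale).
#'
#' @param m numeric vector of linear-predictor values.
#' @param adult_age maturity parameter in years.
#' @return ages in years.
#' @export
#' @examples
#' horvath_antitrafo(0)   # 20 years at the breakpoint
horvath_antitrafo <- function(m, adult_age = 20) {
  ifelse(m < 0, (1 + adult_age) * exp(m) - 1, (1 + adult_age) * m + adult_age)
}

#' Convert age in years to days post-conception
#'
#' `days = years * 365.25 + 280`, taking a Julian year and a full-term
#' gestation of 280 days, so birth (0 years) is 280 days post-conception.
#'
#' @param years numeric vector of ages in years.
#' @return ages in days post-conception.
#' @export
#' @examples
#' years_to_days_post_conception(0)  # 280
years_to_days_post_conception <- function(years) {
  years * 365.25 + 280
}

#' Predict epigenetic age from beta values
#'
#' Applies a sparse linear clock to a beta matrix. Clock CpGs missing from
#' the matrix are skipped and counted per sample (set `strict = TRUE` to
#' error instead); the transform and unit conversion of the clock are then
#' applied. When the transform is `horvath_antitrafo` the transformed value
#' is in years and is converted if the clock reports days post-conception;
#' an `identity` transform is taken to be on the output-unit scale already.
#'
#' @param beta probes x samples beta matrix.
#' @param clock a [clock_model()].
#' @param strict error on missing clock CpGs instead of skipping them.
#' @return data.frame with sample_id, linear_predictor, age,
#'   n_missing_clock_cpgs.
#' @export
apply_clock <- function(beta, clock, strict = FALSE) {
  check_beta(beta)
  stopifnot(inherits(clock, "clock_model"))
  present <- intersect(names(clock$coefficients), rownames(beta))
  n_missing <- length(clock$coefficients) - length(present)
  if (length(present) == 0)
    stop("clock '", clock$name, "' shares no CpGs with the beta matrix")
  if (strict && n_missing > 0)
    stop("clock '", clock$name, "': ", n_missing, " clock CpGs missing")
  lp <- clock$intercept +
    drop(crossprod(beta[present, , drop = FALSE],
                   clock$coefficients[present]))
  age <- switch(clock$transform,
    identity = lp,
    horvath_antitrafo = {
      yrs <- horvath_antitrafo(lp, clock$adult_age)
      if (clock$output_unit == "days_post_conception")
        years_to_days_post_conception(yrs) else yrs
    })
  data.frame(sample_id = colnames(beta), linear_predictor = unname(lp),
             age = unname(age),
             n_missing_clock_cpgs = n_missing, stringsAsFactors = FALSE)
}

#' Stage-wise age comparison: one-way ANOVA with Tukey HSD
#'
#' Tests for differences in predicted epigenetic age between cell stages
#' with a one-way fixed-effects ANOVA, followed by Tukey's honest
#' significant difference test over all stage pairs (Tukey-Kramer standard
#' errors under unbalanced groups, via [stats::TukeyHSD()]).
#'
#' @param ages numeric vector of per-sample ages.
#' @param stages factor or character vector of stage labels, same length.
#' @return object of class `stage_comparison`: `anova_F`, `anova_p`, and a
#'   `pairwise` data.frame (pair, diff, lwr, upr, p_adj).
#' @export
stage_anova_tukey <- function(ages, stages) {
  if (length(ages) != length(stages))
    stop("ages and stages must have the same length")
  stages <- droplevels(factor(stages))
  if (nlevels(stages) < 2) stop("need at least 2 stages")
  if (any(table(stages) < 1)) stop("every stage needs at least one sample")
  if (length(ages) - nlevels(stages) < 2)
    stop("need at least 2 residual degrees of freedom")
  fit <- aov(ages ~ stages)
  tab <- summary(fit)[[1]]
  f <- tab["stages", "F value"]; p <- tab["stages", "Pr(>F)"]
  if (tab["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(tab[, "Sum Sq"])) {
    warning("zero residual variance; p-values reported as 0")
    p <- 0
    tk <- t(utils::combn(levels(stages), 2))
    means <- tapply(ages, stages, mean)
    pairwise <- data.frame(pair = paste(tk[, 2], tk[, 1], sep = "-"),
                           diff = means[tk[, 2]] - means[tk[, 1]],
                           lwr = NA_real_, upr = NA_real_, p_adj = 0,
                           stringsAsFactors = FALSE, row.names = NULL)
  } else {
    hsd <- TukeyHSD(fit)$stages
    pairwise <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                           lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                           p_adj = hsd[, "p adj"], stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  structure(list(anova_F = unname(f), anova_p = unname(p),
                 pairwise = pairwise), class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("stage_comparison: F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Write / read a clock coefficient file
#'
#' CSV with a small metadata header (`#name=`, `#transform=`,
#' `#output_unit=`, `#adult_age=`), then `probe_id,coefficient` rows with a
#' reserved `(Intercept)` row.
#'
#' @param clock a [clock_model()].
#' @param path file path.
#' @return `read_clock` returns a [clock_model()]; `write_clock` its path,
#'   invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  hdr <- c(paste0("#name=", clock$name),
           paste0("#transform=", clock$transform),
           paste0("#output_unit=", clock$output_unit),
           paste0("#adult_age=", clock$adult_age),
           "probe_id,coefficient")
  rows <- c(paste0("(Intercept),", format(clock$intercept, digits = 17)),
            paste0(names(clock$coefficients), ",",
                   format(unname(clock$coefficients), digits = 17)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  body <- read.delim(text = lines[!grepl("^#", lines)], sep = ",",
                     stringsAsFactors = FALSE)
  ic <- body$probe_id == "(Intercept)"
  clock_model(name = meta[["name"]] %||% basename(path),
              coefficients = setNames(body$coefficient[!ic], body$probe_id[!ic]),
              intercept = if (any(ic)) body$coefficient[ic][1] else 0,
              transform = meta[["transform"]] %||% "identity",
              output_unit = meta[["output_unit"]] %||% "years",
              adult_age = as.numeric(meta[["adult_age"]] %||% 20))
}
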