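#' Fisher z-transformation test of a correlation coefficient
#'
#' Tests r against the null of zero correlation: the statistic is
#' `atanh(r) * sqrt(n - 3)`, referred to the standard normal distribution
#' (two-sided).
#'
#' @param r Sample Pearson correlation coefficient.
#' @param n Sample size (must be >= 4).
#' @return Two-sided p-value. For |r| = 1 the value 0 is returned with
#'   attribute `exact = TRUE`.
#' @examples
#' fisher_z_pvalue(0.5, 19)
#' @export
fisher_z_pvalue <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, abs(r) <= 1)
  if (n < 4) stop("Fisher z test requires n >= 4")
  if (abs(r) == 1) return(structure(0, exact = TRUE))
  stat <- atanh(r) * sqrt(n - 3)
  2 * stats::pnorm(-abs(stat))
}

#' Pearson correlation with Fisher z significance
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A `correlation_result` list: `r`, `n`, `p`, `method = "linear"`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  p <- if (length(x) >= 4) fisher_z_pvalue(r, length(x)) else NA_real_
  structure(list(r = r, n = length(x), p = p, method = "linear"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("r_", x$method, " = ", format(x$r, digits = 3), " (n = ", x$n,
      ", p = ", format(x$p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Inverse-polynomial non-linear fit and correlation
#'
#' Fits `f(X) = a + b/X + c/X^2 + d/X^3` by least squares (the model is
#' linear in a-d) and returns the non-linear correlation coefficient,
#' defined as the Pearson correlation between the fitted values `f(x)` and
#' `y`. If the basis is rank deficient (e.g. duplicated x with fewer than 4
#' distinct values), the minimum-norm least-squares solution is used with a
#' warning.
#'
#' @param x Positive numeric vector (e.g. vIP in eV).
#' @param y Numeric response (e.g. normalized SBS frequency).
#' @return A `nonlinear_fit` list: `a`, `b`, `c`, `d`, `r_nonlinear`,
#'   `fitted`, `n`.
#' @export
nonlinear_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x <= 0)) stop("inverse-polynomial fit requires strictly positive x")
  if (length(x) < 4) stop("need at least 4 points to identify a, b, c, d")
  if (stats::sd(y) == 0) stop("correlation undefined for constant y")
  B <- cbind(1, x^-1, x^-2, x^-3)
  qrB <- qr(B)
  if (qrB$rank < 4L) {
    warning("rank-deficient inverse-power basis (duplicated x?); ",
            "using minimum-norm least squares")
    sv <- svd(B)
    pos <- sv$d > max(sv$d) * 1e-12
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coefs <- as.numeric(coefs)
  } else {
    coefs <- qr.coef(qrB, y)
  }
  f <- as.numeric(B %*% coefs)
  r_nl <- if (stats::sd(f) == 0) 0 else stats::cor(f, y)
  structure(list(a = coefs[1], b = coefs[2], c = coefs[3], d = coefs[4],
                 r_nonlinear = r_nl, fitted = f, n = length(x)),
            class = "nonlinear_fit")
}

#' @export
print.nonlinear_fit <- function(x, ...) {
  cat("f(X) = a + b/X + c/X^2 + d/X^3; a=", format(x$a, digits = 4),
      " b=", format(x$b, digits = 4), " c=", format(x$c, digits = 4),
      " d=", format(x$d, digits = 4),
      "; r_nonlinear = ", format(x$r_nonlinear, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares regression line
#'
#' @param x,y Numeric vectors (n >= 2, x non-constant).
#' @return A `regression_line` list: `slope` (response units per eV when x
#'   is a vIP), `intercept`.
#' @export
slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0) stop("regression undefined for constant x")
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1])),
            class = "regression_line")
}

#' Test of the difference between two independent correlations
#'
#' Fisher z-based two-sample test:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' standard-normal p-value.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return List with `statistic` and `p`.
#' @export
correlation_difference_test <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1)
  if (n1 < 4 || n2 < 4) stop("Fisher z difference test requires n >= 4")
  stat <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(statistic = stat, p = 2 * stats::pnorm(-abs(stat)))
}

#' Correlation matrix between motif vIPs and normalized SBS frequencies
#'
#' For one region and motif pattern, correlates per-motif vIP with the
#' normalized SBS frequency, overall ("All") and within the subsets of
#' motifs whose focal (substituted) base is G, C, A or T. Emits the linear
#' Pearson coefficient with its Fisher z p-value, the inverse-polynomial
#' non-linear coefficient, and the regression slope.
#'
#' @param freq_table A `norm_freq_table` (see [normalized_frequency()]).
#' @param stack_table A `stack_vip_table` resolving every motif (length > 4
#'   composed from quadruplet windows).
#' @param subsets Subset labels; default "All" plus the four focal bases.
#' @return Data frame with one row per subset: `region`, `pattern`,
#'   `subset`, `n`, `r_linear`, `p_linear`, `r_nonlinear`, `slope`,
#'   `intercept`, `computable`.
#' @export
vip_frequency_analysis <- function(freq_table, stack_table,
                                   subsets = c("All", "G", "C", "A", "T")) {
  pattern <- attr(freq_table, "pattern")
  region <- attr(freq_table, "region")
  p <- parse_pattern(pattern)
  vip <- motif_vip(stack_table, freq_table$motif)
  focal <- substring(freq_table$motif, p$x_pos, p$x_pos)
  rows <- lapply(subsets, function(s) {
    i <- if (s == "All") seq_along(vip) else which(focal == s)
    base <- data.frame(region = region, pattern = pattern, subset = s,
                       n = length(i), r_linear = NA_real_,
                       p_linear = NA_real_, r_nonlinear = NA_real_,
                       slope = NA_real_, intercept = NA_real_,
                       computable = FALSE, stringsAsFactors = FALSE)
    if (length(i) < 4 || stats::sd(vip[i]) == 0 ||
        stats::sd(freq_table$norm_freq[i]) == 0) {
      return(base)
    }
    lin <- pearson(vip[i], freq_table$norm_freq[i])
    nl <- nonlinear_r(vip[i], freq_table$norm_freq[i])
    sl <- slope(vip[i], freq_table$norm_freq[i])
    base$r_linear <- lin$r; base$p_linear <- lin$p
    base$r_nonlinear <- nl$r_nonlinear
    base$slope <- sl$slope; base$intercept <- sl$intercept
    base$computable <- TRUE
    base
  })
  do.call(rbind, rows)
}

#' 5'-3' asymmetry of the vIP-frequency correlation
#'
#' For motif lengths 2-4, compares the correlation obtained when the flank
#' is taken 3' of the substituted base (patterns `XN`, `XNN`, `XNNN`) with
#' the correlation for the mirrored 5' patterns (`NX`, `NNX`, `NNNX`). A
#' negative difference `r_forward - r_reverse` means the 3'-flank motifs are
#' the more negatively correlated ones, i.e. the 3' flank is the more
#' informative side.
#'
#' @param records An `sbs_records` data.frame.
#' @param genome A `genome_sequence`.
#' @param models List of `gene_model` objects.
#' @param stack_table A `stack_vip_table`.
#' @param regions Region selectors to analyze.
#' @param lengths Motif lengths (subset of 2:4).
#' @param filters Optional record filters (as in [count_sbs_motifs()]).
#' @return Data frame with one row per region x length: `region`, `k`,
#'   `pattern_forward`, `pattern_reverse`, `r_forward`, `r_reverse`, `diff`,
#'   `p`.
#' @export
asymmetry_analysis <- function(records, genome, models, stack_table,
                               regions = "exon", lengths = 2:4,
                               filters = list()) {
  stopifnot(all(lengths %in% 2:4))
  rows <- list()
  for (region in regions) {
    for (k in lengths) {
      fwd <- paste0("X", strrep("N", k - 1))
      rev_ <- paste0(strrep("N", k - 1), "X")
      r_of <- function(pat) {
        bg <- count_region_motifs(genome, models, region, pat)
        sbs <- count_sbs_motifs(records, genome, region, pat, filters)
        ft <- normalized_frequency(sbs, bg)
        pearson(motif_vip(stack_table, ft$motif), ft$norm_freq)
      }
      cf <- r_of(fwd); cr <- r_of(rev_)
      test <- correlation_difference_test(cf$r, cf$n, cr$r, cr$n)
      rows[[length(rows) + 1L]] <-
        data.frame(region = region, k = k, pattern_forward = fwd,
                   pattern_reverse = rev_, r_forward = cf$r,
                   r_reverse = cr$r, diff = cf$r - cr$r, p = test$p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
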