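#' Sample variance of log2 DAI over a gene set
#'
#' Unbiased sample variance (divisor n - 1) of the supplied log2 DAI values;
#' non-finite values are dropped. Used on the combined D and S mRNA set to
#' quantify genome-wide somato-dendritic asymmetry.
#'
#' @param log2_dai numeric vector of log2 DAI values.
#' @return The sample variance (log2^2 units).
#' @export
dai_variance <- function(log2_dai) {
  x <- log2_dai[is.finite(log2_dai)]
  if (length(x) < 2)
    stop("variance needs at least 2 finite values")
  stats::var(x)
}

#' Two-sided variance-ratio F test
#'
#' Tests equality of two variances with `F0 = s2_a / s2_b` on
#' `(n_a - 1, n_b - 1)` degrees of freedom; the two-sided p-value is
#' `2 * min(P(F <= F0), P(F >= F0))`, capped at 1. Swapping the two samples
#' gives the reciprocal F0 and an identical p-value.
#'
#' @param s2_a,s2_b sample variances (> 0).
#' @param n_a,n_b sample sizes (>= 2).
#' @return List with `F0`, `p_value`, `df` (length-2 vector).
#' @export
variance_f_test <- function(s2_a, n_a, s2_b, n_b) {
  if (!(s2_a > 0 && s2_b > 0))
    stop("variance-ratio test requires strictly positive variances")
  if (n_a < 2 || n_b < 2)
    stop("variance-ratio test requires n >= 2 in both groups")
  df <- c(n_a - 1, n_b - 1)
  F0 <- s2_a / s2_b
  p <- 2 * min(stats::pf(F0, df[1], df[2]),
               stats::pf(F0, df[1], df[2], lower.tail = FALSE))
  list(F0 = F0, p_value = min(p, 1), df = df)
}

#' Selectivity correlation between baseline localization and its KO change
#'
#' Pearson correlation between the control log2 DAI and the log2 relative
#' DAI (cKO/control) over a gene subset (typically the D or the S class).
#' A low |r| for D-mRNAs with a high |r| for S-mRNAs indicates that the
#' knockout effect is selective among dendritic transcripts but uniform
#' across somatic ones.
#'
#' @param log2_dai_control per-gene control log2 DAI.
#' @param log2_relative_dai per-gene log2 of the cKO/control DAI ratio.
#' @param subset optional logical or integer index selecting the gene subset.
#' @return The signed Pearson r (callers report `abs(r)`).
#' @export
selectivity_correlation <- function(log2_dai_control, log2_relative_dai,
                                    subset = NULL) {
  x <- log2_dai_control
  y <- log2_relative_dai
  if (length(x) != length(y))
    stop("inputs must have equal length")
  if (!is.null(subset)) {
    x <- x[subset]; y <- y[subset]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("correlation needs at least 3 genes with finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in one of the variables")
  stats::cor(x, y)
}

#' Select D-mRNAs with reduced dendritic localization in the knockout
#'
#' Returns the D-class genes whose relative DAI (cKO/control) is strictly
#' below `threshold` (default 0.8); a gene exactly at the threshold is not
#' selected, and genes with undefined relative DAI are never selected.
#'
#' @param table data.frame with columns `gene_id`, `class`, `relative_dai`
#'   (e.g. the `table` element of a [dai_fit]).
#' @param threshold relative-DAI cut in (0, 1], default 0.8.
#' @return Character vector of gene ids.
#' @export
select_reduced_d_mrnas <- function(table, threshold = 0.8) {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  sel <- table$class == "D" & !is.na(table$relative_dai) &
    table$relative_dai < threshold
  table$gene_id[which(sel)]
}
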