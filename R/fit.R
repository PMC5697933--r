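#' Fit the somato-dendritic localization analysis to an expression set
#'
#' Runs the full localization analysis on a layer-microdissected RNA-seq
#' experiment: FPKM computation, per-genotype DAI, a Welch test for SP-vs-SR
#' differential enrichment in the reference genotype with BH FDR control,
#' classification into D-mRNA / S-mRNA / non-significant sets (with cell-type
#' exclusion lists), the relative DAI between genotypes, the variance-ratio
#' F test for collapse of localization asymmetry, per-class selectivity
#' correlations, and selection of D-mRNAs with reduced dendritic localization.
#'
#' The asymmetry comparison uses the combined D and S set with a defined DAI
#' in both genotypes, so the same `n` enters both variances.
#'
#' @param x an [expr_set] (counts, lengths, sample metadata), e.g. the
#'   `matrix` element of [simulate_dataset()] output or the result of
#'   [read_expression_table()].
#' @param exclusions cell-type exclusion lists ([read_exclusion_lists()]
#'   object, list of character vectors, character vector, or `NULL`).
#' @param alpha FDR threshold for the significance ("yes") flag, default 0.05.
#' @param reference genotype in which D/S classes are defined, default
#'   `"control"`.
#' @param rel_threshold relative-DAI cut defining "reduced" dendritic
#'   localization, default 0.8 (strictly below).
#' @param pseudocount FPKM offset used inside the test statistic only,
#'   default 0.125.
#' @param test per-gene SP-vs-SR test: `"welch"` (default) or `"moderated"`
#'   (limma empirical-Bayes moderated t); see [test_layer_enrichment()].
#'
#' @return An object of class `dai_fit`: a list with
#'   \describe{
#'     \item{table}{per-gene data.frame: `gene_id`, `length`, mean FPKM per
#'       layer and genotype, `dai_control`, `dai_cko`, `log2_dai_control`,
#'       `log2_dai_cko`, `relative_dai`, `p_value`, `q_value`, `significant`,
#'       `class`, `candidate_class`;}
#'     \item{stats}{summary statistics: class counts, `s2_control`, `s2_cko`,
#'       `n_asym`, `F0`, `p_f`, signed `r_D`, `r_S`, `n_reduced_D`,
#'       `rel_threshold`, `alpha`;}
#'     \item{reduced_D}{gene ids of D-mRNAs with relative DAI below the
#'       threshold;}
#'     \item{fpkm}{the FPKM matrix;}
#'     \item{samples}{the sample metadata.}
#'   }
#' @seealso [summary.dai_fit()], [plot.dai_fit()], [run_pipeline()]
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 400, n_contaminant_genes = 20,
#'                                    library_size_per_sample = 4e5, seed = 7))
#' contam <- sim$truth$gene_id[sim$truth$true_class == "contaminant"]
#' fit <- dai_fit(sim$matrix, exclusions = contam)
#' summary(fit)
#' @export
dai_fit <- function(x, exclusions = NULL, alpha = 0.05, reference = "control",
                    rel_threshold = 0.8, pseudocount = 0.125,
                    test = c("welch", "moderated")) {
  test <- match.arg(test)
  stopifnot(inherits(x, "expr_set"))
  reference <- match.arg(reference, c("control", "cKO"))
  other <- setdiff(c("control", "cKO"), reference)

  fpkm <- compute_fpkm(x)
  dai_ref <- compute_dai(fpkm, x$samples, reference)
  dai_oth <- compute_dai(fpkm, x$samples, other)
  p <- test_layer_enrichment(fpkm, x$samples, reference, pseudocount, method = test)
  q <- bh_adjust(p)
  cls <- classify_genes(dai_ref, q, exclusions, alpha)

  dai_control <- if (reference == "control") dai_ref else dai_oth
  dai_cko <- if (reference == "control") dai_oth else dai_ref
  rel <- relative_dai(dai_control$dai, dai_cko$dai)

  tab <- data.frame(gene_id = rownames(fpkm),
                    length = as.numeric(x$lengths),
                    fpkm_sp_control = dai_control$fpkm_sp,
                    fpkm_sr_control = dai_control$fpkm_sr,
                    fpkm_sp_cko = dai_cko$fpkm_sp,
                    fpkm_sr_cko = dai_cko$fpkm_sr,
                    dai_control = dai_control$dai,
                    dai_cko = dai_cko$dai,
                    log2_dai_control = log2(dai_control$dai),
                    log2_dai_cko = log2(dai_cko$dai),
                    relative_dai = rel,
                    p_value = as.numeric(p),
                    q_value = as.numeric(q),
                    significant = cls$table$significant,
                    class = cls$table$class,
                    candidate_class = cls$table$candidate_class,
                    stringsAsFactors = FALSE, row.names = NULL)

  # asymmetry statistics over the shared D u S set with DAI in both genotypes
  ds <- tab$class %in% c("D", "S") & is.finite(tab$log2_dai_control) &
    is.finite(tab$log2_dai_cko)
  stats_out <- c(cls$summary,
                 list(n_asym = sum(ds), s2_control = NA_real_,
                      s2_cko = NA_real_, F0 = NA_real_, p_f = NA_real_,
                      r_D = NA_real_, r_S = NA_real_,
                      rel_threshold = rel_threshold))
  if (sum(ds) >= 2) {
    stats_out$s2_control <- dai_variance(tab$log2_dai_control[ds])
    stats_out$s2_cko <- dai_variance(tab$log2_dai_cko[ds])
    ft <- variance_f_test(stats_out$s2_control, sum(ds),
                          stats_out$s2_cko, sum(ds))
    stats_out$F0 <- ft$F0
    stats_out$p_f <- ft$p_value
  }
  log2_rel <- log2(tab$relative_dai)
  for (cl in c("D", "S")) {
    idx <- tab$class == cl & is.finite(tab$log2_dai_control) & is.finite(log2_rel)
    if (sum(idx, na.rm = TRUE) >= 3) {
      r <- tryCatch(selectivity_correlation(tab$log2_dai_control, log2_rel,
                                            which(idx)),
                    error = function(e) NA_real_)
      if (cl == "D") stats_out$r_D <- r else stats_out$r_S <- r
    }
  }
  reduced <- select_reduced_d_mrnas(tab, rel_threshold)
  stats_out$n_reduced_D <- length(reduced)

  structure(list(table = tab, stats = stats_out, reduced_D = reduced,
                 fpkm = fpkm, samples = x$samples, reference = reference,
                 alpha = alpha, call = match.call()),
            class = "dai_fit")
}

#' @export
print.dai_fit <- function(x, ...) {
  s <- x$stats
  cat("dai_fit:", nrow(x$table), "genes,", nrow(x$samples), "samples",
      sprintf("(reference genotype: %s)\n", x$reference))
  cat(sprintf("  D-mRNAs: %d  S-mRNAs: %d  NS: %d  excluded: %d  unexpressed: %d\n",
              s$n_D, s$n_S, s$n_NS, s$n_excluded, s$n_unexpressed))
  if (is.finite(s$F0))
    cat(sprintf("  asymmetry: s2 %.4g (control) vs %.4g (cKO), n = %d, F0 = %.3f, p = %.3g\n",
                s$s2_control, s$s2_cko, s$n_asym, s$F0, s$p_f))
  invisible(x)
}

#' Summarize a localization fit
#'
#' @param object a [dai_fit] object.
#' @param ... unused.
#' @return An object of class `summary.dai_fit`: the `stats` list of the fit
#'   plus `reference` and the number of genes, with a print method that
#'   reports the class partition, the per-genotype variances of log2 DAI,
#'   the F test, the |r| selectivity correlations and the reduced-D count.
#' @export
summary.dai_fit <- function(object, ...) {
  s <- object$stats
  s$reference <- object$reference
  s$n_genes <- nrow(object$table)
  structure(s, class = "summary.dai_fit")
}

#' @export
print.summary.dai_fit <- function(x, ...) {
  cat("Somato-dendritic localization analysis\n")
  cat(sprintf("  %d genes; reference genotype: %s; alpha = %g\n",
              x$n_genes, x$reference, x$alpha))
  cat(sprintf("  D-mRNAs: %d  S-mRNAs: %d  non-significant: %d\n",
              x$n_D, x$n_S, x$n_NS))
  cat(sprintf("  excluded: %d  unexpressed: %d\n", x$n_excluded, x$n_unexpressed))
  if (is.finite(x$F0)) {
    cat(sprintf("  variance of log2 DAI (D u S, n = %d): s2_control = %.4g, s2_cKO = %.4g\n",
                x$n_asym, x$s2_control, x$s2_cko))
    cat(sprintf("  variance-ratio test: F0 = %.3f, two-sided p = %.3g\n",
                x$F0, x$p_f))
  }
  if (is.finite(x$r_D) || is.finite(x$r_S))
    cat(sprintf("  selectivity |r|: D-mRNAs %.4f, S-mRNAs %.4f\n",
                abs(x$r_D), abs(x$r_S)))
  cat(sprintf("  D-mRNAs with relative DAI < %g: %d\n",
              x$rel_threshold, x$n_reduced_D))
  invisible(x)
}

#' Extract per-gene log2 DAI estimates
#'
#' @param object a [dai_fit] object.
#' @param ... unused.
#' @return Matrix with one row per gene and columns `control` and `cKO`
#'   holding the estimated log2 DAI (NA where undefined).
#' @export
coef.dai_fit <- function(object, ...) {
  m <- cbind(control = object$table$log2_dai_control,
             cKO = object$table$log2_dai_cko)
  rownames(m) <- object$table$gene_id
  m
}

#' MA plot of layer enrichment
#'
#' Plots per-gene mean expression (A) against the log2 DAI (M) for one
#' genotype, with classified D- and S-mRNAs accentuated in color.
#'
#' @param x a [dai_fit] object.
#' @param genotype `"control"` or `"cKO"`.
#' @param highlight classes to accentuate (subset of `c("D", "S")`).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the data.frame of plotted (A, M) coordinates.
#' @export
plot.dai_fit <- function(x, genotype = "control", highlight = c("D", "S"), ...) {
  genotype <- match.arg(genotype, c("control", "cKO"))
  tab <- x$table
  sp <- if (genotype == "control") tab$fpkm_sp_control else tab$fpkm_sp_cko
  sr <- if (genotype == "control") tab$fpkm_sr_control else tab$fpkm_sr_cko
  am <- ma_coordinates(sp, sr)
  graphics::plot(am$A, am$M, pch = 16, cex = 0.4, col = "grey60",
                 xlab = "A = (log2 FPKM_SR + log2 FPKM_SP) / 2",
                 ylab = "M = log2 DAI",
                 main = sprintf("MA plot (%s)", genotype), ...)
  graphics::abline(h = 0, lty = 2)
  cols <- c(D = "red", S = "blue")
  for (cl in intersect(highlight, c("D", "S"))) {
    i <- tab$class == cl
    graphics::points(am$A[i], am$M[i], pch = 16, cex = 0.4, col = cols[[cl]])
  }
  invisible(am)
}
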