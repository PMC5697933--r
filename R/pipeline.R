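#' Run the full localization pipeline on files and write all outputs
#'
#' Orchestrates quantification, classification, asymmetry analysis and GO
#' enrichment end-to-end from tab-separated inputs: reads the count table
#' and sample metadata, fits the localization model ([dai_fit()]), writes the
#' classification tables, an asymmetry report, the reduced-D gene list, the
#' GO enrichment of the reduced-D set against the classified background, MA
#' plots for both genotypes, and a plain-text summary. All referenced input
#' paths are checked before any computation.
#'
#' @param counts path to the count table (see [read_expression_table()]).
#' @param metadata path to the sample metadata table.
#' @param out_dir output directory (created if absent).
#' @param exclusion_paths optional character vector of exclusion-list files.
#' @param annotation optional path to a gene-to-GO annotation table; when
#'   supplied, enrichment of the reduced-D set is computed.
#' @param alpha FDR threshold for classification (default 0.05).
#' @param rel_threshold relative-DAI cut for the reduced-D set (default 0.8).
#' @param plots whether to write MA-plot PNGs (best-effort artifacts).
#' @return Invisibly, the [dai_fit] object.
#' @export
run_pipeline <- function(counts, metadata, out_dir,
                         exclusion_paths = NULL, annotation = NULL,
                         alpha = 0.05, rel_threshold = 0.8, plots = TRUE) {
  inputs <- c(counts, metadata, exclusion_paths, annotation)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  es <- read_expression_table(counts, metadata)
  excl <- if (length(exclusion_paths)) read_exclusion_lists(exclusion_paths) else NULL
  annot <- if (!is.null(annotation)) read_go_annotation(annotation) else NULL

  fit <- withCallingHandlers(
    dai_fit(es, exclusions = excl, alpha = alpha, rel_threshold = rel_threshold),
    error = function(e) stop("stage dai_fit failed: ", conditionMessage(e)))

  write_classification_tables(fit, out_dir)
  fpkm_tab <- data.frame(gene_id = rownames(fit$fpkm), fit$fpkm,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(fpkm_tab, file.path(out_dir, "fpkm.tsv"))
  writeLines(fit$reduced_D, file.path(out_dir, "reduced_D_mRNAs.txt"))

  s <- fit$stats
  asym <- data.frame(statistic = c("s2_control", "s2_cko", "n", "F0", "p_value",
                                   "r_D", "r_S", "abs_r_D", "abs_r_S",
                                   "n_reduced_D", "rel_threshold"),
                     value = c(s$s2_control, s$s2_cko, s$n_asym, s$F0, s$p_f,
                               s$r_D, s$r_S, abs(s$r_D), abs(s$r_S),
                               s$n_reduced_D, s$rel_threshold))
  write_tsv(asym, file.path(out_dir, "asymmetry_stats.tsv"))

  if (!is.null(annot)) {
    background <- fit$table$gene_id[fit$table$class %in% c("D", "S", "NS")]
    enr <- tryCatch(
      go_enrichment(intersect(fit$reduced_D, background), background, annot,
                    alpha = alpha),
      warning = function(w) NULL)
    if (!is.null(enr))
      write_tsv(as.data.frame(enr), file.path(out_dir, "reduced_D_go_enrichment.tsv"))
  }

  if (plots) {
    for (g in c("control", "cKO")) {
      f <- file.path(out_dir, sprintf("ma_plot_%s.png", g))
      grDevices::png(f, width = 900, height = 700)
      try(plot(fit, genotype = g), silent = TRUE)
      grDevices::dev.off()
    }
  }

  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(summary(fit))
  sink()
  close(con)
  invisible(fit)
}
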