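#' Simulation configuration for compartmentalized RNA-seq
#'
#' Defines the generative model for a layer-microdissected RNA-seq experiment:
#' a log-normal baseline expression level per gene, a Gaussian per-class
#' log2 dendritic accumulation index (DAI = SR/SP concentration ratio), and
#' negative-binomial count sampling. The defaults describe a hippocampal CA1
#' experiment with ~6,000 pyramidal-neuron genes plus contaminant transcripts
#' from other cell types, 3 biological replicates for each of the 4
#' (layer x genotype) groups, and a conditional-knockout effect that reduces
#' the DAI of a targeted subset of dendritic mRNAs strongly enough that the
#' true variance ratio of log2 DAI over D and S genes between genotypes is
#' about 1.78.
#'
#' @param n_genes number of pyramidal-neuron genes.
#' @param frac_dendritic,frac_somatic fractions of `n_genes` that are truly
#'   dendritically (D) or somatically (S) enriched; the remainder are neutral.
#'   Must satisfy `frac_dendritic + frac_somatic <= 1`.
#' @param mean_log2_dai_D,mean_log2_dai_S class means of true log2 DAI
#'   (D positive, S negative), in log2 units.
#' @param sd_log2_dai within-class standard deviation of true log2 DAI.
#' @param baseline_log_mean,baseline_log_sd mean and sd of the natural-log
#'   baseline expression level (log-normal across genes).
#' @param nb_dispersion negative-binomial dispersion: variance = mu + dispersion * mu^2.
#'   `0` gives Poisson sampling.
#' @param library_size_per_sample expected total read count per sample.
#' @param n_replicates biological replicates per (layer, genotype) group.
#' @param ko_target_fraction fraction of D genes whose DAI is reduced in the cKO.
#' @param ko_dai_factor multiplicative DAI factor in (0, 1] applied to targeted
#'   D genes in the cKO (log2 DAI shifted by `log2(ko_dai_factor)`).
#' @param ko_dai_sd per-gene standard deviation (log2 units) of the KO effect on
#'   targeted genes; 0 (default) gives a homogeneous effect.
#' @param n_contaminant_genes number of contaminant genes (glia, interneurons,
#'   endothelium) with their own uniform log2 DAI in \[-1, 1\], identical in
#'   both genotypes; removable only via exclusion lists.
#' @param transcript_length_range length-2 interval of transcript lengths (nt).
#' @param seed integer RNG seed; identical seeds give bit-identical datasets.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6000L,
                       frac_dendritic = 0.20,
                       frac_somatic = 0.35,
                       mean_log2_dai_D = 1.5,
                       mean_log2_dai_S = -1.5,
                       sd_log2_dai = 0.5,
                       baseline_log_mean = log(50),
                       baseline_log_sd = 1,
                       nb_dispersion = 0.05,
                       library_size_per_sample = 5e6,
                       n_replicates = 3L,
                       ko_target_fraction = 0.62,
                       ko_dai_factor = 0.25,
                       ko_dai_sd = 0,
                       n_contaminant_genes = 300L,
                       transcript_length_range = c(500, 10000),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_dendritic = frac_dendritic, frac_somatic = frac_somatic,
              mean_log2_dai_D = mean_log2_dai_D, mean_log2_dai_S = mean_log2_dai_S,
              sd_log2_dai = sd_log2_dai,
              baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
              nb_dispersion = nb_dispersion,
              library_size_per_sample = library_size_per_sample,
              n_replicates = as.integer(n_replicates),
              ko_target_fraction = ko_target_fraction,
              ko_dai_factor = ko_dai_factor, ko_dai_sd = ko_dai_sd,
              n_contaminant_genes = as.integer(n_contaminant_genes),
              transcript_length_range = as.numeric(transcript_length_range),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid simulation configuration: ", ..., call. = FALSE)
  if (cfg$n_genes <= 0) stop_cfg("n_genes must be > 0")
  if (cfg$n_replicates <= 0) stop_cfg("n_replicates must be > 0")
  if (cfg$library_size_per_sample <= 0) stop_cfg("library_size_per_sample must be > 0")
  if (cfg$frac_dendritic < 0 || cfg$frac_somatic < 0 ||
      cfg$frac_dendritic + cfg$frac_somatic > 1)
    stop_cfg("frac_dendritic and frac_somatic must be non-negative fractions summing to <= 1")
  if (cfg$mean_log2_dai_D <= 0) stop_cfg("mean_log2_dai_D must be > 0")
  if (cfg$mean_log2_dai_S >= 0) stop_cfg("mean_log2_dai_S must be < 0")
  if (cfg$sd_log2_dai < 0) stop_cfg("sd_log2_dai must be >= 0")
  if (cfg$nb_dispersion < 0) stop_cfg("nb_dispersion must be >= 0")
  if (cfg$ko_dai_factor <= 0 || cfg$ko_dai_factor > 1)
    stop_cfg("ko_dai_factor must be in (0, 1]")
  if (cfg$ko_target_fraction < 0 || cfg$ko_target_fraction > 1)
    stop_cfg("ko_target_fraction must be in [0, 1]")
  if (cfg$ko_dai_sd < 0) stop_cfg("ko_dai_sd must be >= 0")
  if (cfg$n_contaminant_genes < 0) stop_cfg("n_contaminant_genes must be >= 0")
  if (length(cfg$transcript_length_range) != 2 ||
      any(cfg$transcript_length_range <= 0) ||
      diff(cfg$transcript_length_range) < 0)
    stop_cfg("transcript_length_range must be a positive increasing interval")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes (+", x$n_contaminant_genes, "contaminants),",
      x$n_replicates, "replicates x 4 groups\n")
  cat(sprintf("  classes: D %.0f%% (mean log2 DAI %+.2f), S %.0f%% (%+.2f), sd %.2f\n",
              100 * x$frac_dendritic, x$mean_log2_dai_D,
              100 * x$frac_somatic, x$mean_log2_dai_S, x$sd_log2_dai))
  cat(sprintf("  KO: factor %.3g on %.0f%% of D genes (sd %.2g)\n",
              x$ko_dai_factor, 100 * x$ko_target_fraction, x$ko_dai_sd))
  cat(sprintf("  NB dispersion %.3g, library %.3g reads/sample, seed %d\n",
              x$nb_dispersion, x$library_size_per_sample, x$seed))
  invisible(x)
}

#' Read a simulation configuration from a key = value text file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Keys are the argument names of [sim_config()]; `transcript_length_range`
#' takes two comma-separated numbers.
#'
#' @param path file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(sim_config)))
      stop("unknown configuration key: ", key)
    args[[key]] <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  do.call(sim_config, args)
}

# draw per-class true log2 DAI values and center them so that the sum over
# non-contaminant genes is exactly zero while keeping D genes > 0 and
# S genes < 0 (resample offending tail draws and re-center; the shift is
# small so this converges in a few rounds).
draw_true_log2_dai <- function(class, cfg) {
  pyram <- class != "contaminant"
  draw <- function(cl, n) {
    switch(cl,
           D = stats::rnorm(n, cfg$mean_log2_dai_D, cfg$sd_log2_dai),
           S = stats::rnorm(n, cfg$mean_log2_dai_S, cfg$sd_log2_dai),
           neutral = rep(0, n),
           contaminant = stats::runif(n, -1, 1))
  }
  x <- numeric(length(class))
  for (cl in unique(class)) {
    i <- which(class == cl)
    x[i] <- draw(cl, length(i))
  }
  for (iter in seq_len(100)) {
    x[pyram] <- x[pyram] - mean(x[pyram])
    bad <- (class == "D" & x <= 0) | (class == "S" & x >= 0)
    if (!any(bad)) break
    if (iter == 100)
      stop("could not reconcile zero-sum log2 DAI with class signs; ",
           "class means are too close to zero for this configuration")
    for (cl in c("D", "S")) {
      i <- which(bad & class == cl)
      if (length(i)) x[i] <- draw(cl, length(i))
    }
  }
  x
}

#' Simulate a compartmentalized RNA-seq dataset with known ground truth
#'
#' Generates counts for 4 sample groups (SP/SR x control/cKO) with
#' `n_replicates` biological replicates each. The expected count of gene g in
#' a sample of layer L is the library-size-scaled share of the gene's
#' baseline expression assigned to that layer by its true DAI:
#' `share_SR = DAI / (1 + DAI)` and `share_SP = 1 / (1 + DAI)`, so the
#' SR/SP FPKM ratio recovers the DAI in expectation. Counts are drawn
#' negative-binomially with the configured dispersion. The knockout effect is
#' applied to the true DAI values by [apply_ko_effect()] before the cKO
#' counts are drawn.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `dai_sim` with elements
#'   \describe{
#'     \item{matrix}{an [expr_set] with the counts, lengths and metadata;}
#'     \item{truth}{a data.frame of per-gene ground truth: `gene_id`,
#'       `true_class` (`D`/`S`/`neutral`/`contaminant`),
#'       `true_log2_dai_control`, `true_log2_dai_cko`, `ko_targeted`,
#'       `transcript_length`.}
#'   }
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  n_p <- config$n_genes
  n_c <- config$n_contaminant_genes
  n_total <- n_p + n_c
  n_D <- round(config$frac_dendritic * n_p)
  n_S <- round(config$frac_somatic * n_p)
  if (n_D + n_S > n_p) n_S <- n_p - n_D

  gene_id <- c(sprintf("gene%05d", seq_len(n_p)),
               if (n_c) sprintf("contam%04d", seq_len(n_c)))
  class <- c(sample(rep(c("D", "S", "neutral"), c(n_D, n_S, n_p - n_D - n_S))),
             rep("contaminant", n_c))

  lengths <- round(stats::runif(n_total, config$transcript_length_range[1],
                                config$transcript_length_range[2]))
  baseline <- exp(stats::rnorm(n_total, config$baseline_log_mean, config$baseline_log_sd))
  log2_dai_ctrl <- draw_true_log2_dai(class, config)

  truth <- data.frame(gene_id = gene_id,
                      true_class = class,
                      true_log2_dai_control = log2_dai_ctrl,
                      true_log2_dai_cko = log2_dai_ctrl,
                      ko_targeted = FALSE,
                      transcript_length = lengths,
                      stringsAsFactors = FALSE)
  truth <- apply_ko_effect(truth, config)

  # expected counts: baseline weight split between layers by the true DAI,
  # normalized by a genotype-independent total so relative shares are kept
  w <- baseline * lengths
  z <- sum(w)
  mu_layer <- function(log2_dai, layer) {
    dai <- 2^log2_dai
    share <- if (layer == "SR") dai / (1 + dai) else 1 / (1 + dai)
    2 * config$library_size_per_sample * w * share / z
  }

  groups <- expand.grid(replicate = seq_len(config$n_replicates),
                        layer = c("SP", "SR"), genotype = c("control", "cKO"),
                        stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$genotype, c("control", "cKO")),
                         match(groups$layer, c("SP", "SR")),
                         groups$replicate), ]
  sample_id <- sprintf("%s_%s_%d", groups$genotype, groups$layer, groups$replicate)

  counts <- matrix(0, n_total, nrow(groups),
                   dimnames = list(gene_id, sample_id))
  for (j in seq_len(nrow(groups))) {
    l2 <- if (groups$genotype[j] == "control") truth$true_log2_dai_control
          else truth$true_log2_dai_cko
    mu <- mu_layer(l2, groups$layer[j])
    counts[, j] <- if (config$nb_dispersion > 0)
      stats::rnbinom(n_total, mu = mu, size = 1 / config$nb_dispersion)
    else
      stats::rpois(n_total, mu)
  }

  samples <- data.frame(sample = sample_id, layer = groups$layer,
                        genotype = groups$genotype, replicate = groups$replicate,
                        stringsAsFactors = FALSE)
  structure(list(matrix = expr_set(counts, lengths, samples),
                 truth = truth, config = config),
            class = "dai_sim")
}

#' @export
print.dai_sim <- function(x, ...) {
  cat("dai_sim: simulated compartment RNA-seq dataset\n")
  print(x$matrix)
  print(table(true_class = x$truth$true_class))
  invisible(x)
}

#' Apply the knockout localization effect to ground-truth DAI values
#'
#' A random `ko_target_fraction` of D genes has its cKO log2 DAI shifted by
#' `log2(ko_dai_factor)` (plus optional per-gene Gaussian heterogeneity,
#' `ko_dai_sd`). A single additive constant is then applied to the cKO
#' log2 DAI of all non-contaminant genes so that their sum is exactly zero:
#' the loss of dendritic mRNA mass is compensated by a global shift that
#' raises the apparent DAI of the remaining (mostly somatic) transcripts.
#'
#' @param truth ground-truth data.frame as produced by [simulate_dataset()],
#'   holding control DAI values.
#' @param config a [sim_config()] object.
#' @return The truth data.frame with `true_log2_dai_cko` and `ko_targeted` set.
#' @export
apply_ko_effect <- function(truth, config) {
  d_idx <- which(truth$true_class == "D")
  n_target <- round(config$ko_target_fraction * length(d_idx))
  if (length(d_idx) == 0 && config$ko_target_fraction > 0)
    stop("no D genes to target: ko_target_fraction > 0 requires frac_dendritic > 0")
  cko <- truth$true_log2_dai_control
  targeted <- rep(FALSE, nrow(truth))
  if (n_target > 0) {
    tgt <- sample(d_idx, n_target)
    shift <- log2(config$ko_dai_factor)
    if (config$ko_dai_sd > 0)
      shift <- shift + stats::rnorm(n_target, 0, config$ko_dai_sd)
    cko[tgt] <- cko[tgt] + shift
    targeted[tgt] <- TRUE
  }
  pyram <- truth$true_class != "contaminant"
  cko[pyram] <- cko[pyram] - mean(cko[pyram])
  truth$true_log2_dai_cko <- cko
  truth$ko_targeted <- targeted
  truth
}

#' Write a simulated dataset to disk as plain-text fixture files
#'
#' Emits `counts.tsv` (gene id, transcript length, one column per sample),
#' `metadata.tsv` (sample, layer, genotype, replicate), `ground_truth.tsv`
#' and `exclusion_contaminants.txt` (the contaminant gene ids, one per line)
#' into `dir`. All files round-trip losslessly through the package readers.
#'
#' @param sim a `dai_sim` object from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "dai_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             exclusion = file.path(dir, "exclusion_contaminants.txt"))
  write_expression_table(sim$matrix, paths["counts"], paths["metadata"])
  write_tsv(sim$truth, paths["truth"])
  contam <- sim$truth$gene_id[sim$truth$true_class == "contaminant"]
  writeLines(c("# contaminant (non-pyramidal) gene ids", contam), paths["exclusion"])
  invisible(paths)
}
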