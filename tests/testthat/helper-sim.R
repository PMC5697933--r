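# small simulated datasets used across test files

tiny_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300L, n_contaminant_genes = 20L,
               library_size_per_sample = 3e5, seed = as.integer(seed))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a 2-gene, hand-checkable expression set: 2 replicates per group
toy_expr_set <- function() {
  counts <- rbind(g1 = c(10, 12, 40, 44, 10, 11, 20, 22),
                  g2 = c(90, 88, 60, 56, 90, 89, 80, 78))
  colnames(counts) <- c("control_SP_1", "control_SP_2", "control_SR_1", "control_SR_2",
                        "cKO_SP_1", "cKO_SP_2", "cKO_SR_1", "cKO_SR_2")
  samples <- data.frame(sample = colnames(counts),
                        layer = rep(c("SP", "SP", "SR", "SR"), 2),
                        genotype = rep(c("control", "cKO"), each = 4),
                        replicate = rep(1:2, 4),
                        stringsAsFactors = FALSE)
  expr_set(counts, c(g1 = 1000, g2 = 2000), samples)
}
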