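# generator: determinism, ground-truth structure, KO effect, moments

test_that("identical config and seed give bit-identical datasets", {
  a <- simulate_dataset(tiny_config(seed = 5))
  b <- simulate_dataset(tiny_config(seed = 5))
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(tiny_config(seed = 6))
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_dendritic = 0.7, frac_somatic = 0.5), "frac")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(ko_dai_factor = 0), "ko_dai_factor")
  expect_error(sim_config(ko_dai_factor = 1.2), "ko_dai_factor")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(library_size_per_sample = -1), "library_size")
  expect_error(sim_config(mean_log2_dai_D = -1), "mean_log2_dai_D")
})

test_that("ground truth has the promised class structure and sign constraints", {
  sim <- simulate_dataset(tiny_config(seed = 2))
  tr <- sim$truth
  expect_setequal(unique(tr$true_class), c("D", "S", "neutral", "contaminant"))
  expect_true(all(tr$true_log2_dai_control[tr$true_class == "D"] > 0))
  expect_true(all(tr$true_log2_dai_control[tr$true_class == "S"] < 0))
  pyram <- tr$true_class != "contaminant"
  expect_lt(abs(sum(tr$true_log2_dai_control[pyram])), 1e-9)
  expect_lt(abs(sum(tr$true_log2_dai_cko[pyram])), 1e-9)
  expect_true(all(abs(tr$true_log2_dai_control[tr$true_class == "contaminant"]) <= 1))
})

test_that("expression matrix has 4 groups x n_replicates and integer counts", {
  cfg <- tiny_config(seed = 3, n_replicates = 2)
  sim <- simulate_dataset(cfg)
  es <- sim$matrix
  expect_equal(ncol(es$counts), 8)
  grp <- table(es$samples$layer, es$samples$genotype)
  expect_true(all(grp == 2))
  expect_true(all(es$counts >= 0))
  expect_true(all(es$counts == round(es$counts)))
})

test_that("ko_target_fraction = 0 leaves the cKO truth equal to control", {
  sim <- simulate_dataset(tiny_config(seed = 4, ko_target_fraction = 0))
  expect_equal(sim$truth$true_log2_dai_cko, sim$truth$true_log2_dai_control)
  expect_false(any(sim$truth$ko_targeted))
})

test_that("ko_dai_factor = 1 reduces to the identity (renormalization constant 0)", {
  sim <- simulate_dataset(tiny_config(seed = 4, ko_dai_factor = 1))
  expect_equal(sim$truth$true_log2_dai_cko, sim$truth$true_log2_dai_control,
               tolerance = 1e-12)
})

test_that("targeted genes are shifted by exactly log2(ko_dai_factor) before compensation", {
  cfg <- tiny_config(seed = 7, ko_dai_factor = 0.5, ko_target_fraction = 0.5)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  pyram <- tr$true_class != "contaminant"
  # undo the single additive compensation constant, then targeted genes must
  # sit exactly log2(0.5) = -1 below their control value
  delta <- tr$true_log2_dai_cko - tr$true_log2_dai_control
  const <- mean(delta[pyram & !tr$ko_targeted])
  expect_equal(unname(delta[tr$ko_targeted] - const),
               rep(-1, sum(tr$ko_targeted)), tolerance = 1e-9)
  expect_equal(sd(delta[pyram & !tr$ko_targeted]), 0, tolerance = 1e-12)
})

test_that("apply_ko_effect errors when there are no D genes to target", {
  sim <- simulate_dataset(tiny_config(seed = 1, frac_dendritic = 0,
                                      ko_target_fraction = 0))
  expect_error(apply_ko_effect(sim$truth, tiny_config(seed = 1)), "no D genes")
})

test_that("KO with factor < 1 shrinks the true DAI variance over D and S genes", {
  for (s in 1:5) {
    sim <- simulate_dataset(tiny_config(seed = s))
    tr <- sim$truth
    ds <- tr$true_class %in% c("D", "S")
    expect_lt(var(tr$true_log2_dai_cko[ds]), var(tr$true_log2_dai_control[ds]))
  }
})

test_that("realized sample log2 DAI variance matches the analytic mixture variance", {
  # moment oracle for the configured mixture of true log2 DAI across genes:
  # var = sum_c w_c (sd^2 + m_c^2) - (sum_c w_c m_c)^2 over D/S/neutral classes,
  # plus the delta-method measurement variance of a log2 FPKM-ratio of
  # replicate means: 2 * (dispersion + 1/mu_typical) / (n_rep * ln(2)^2)
  fD <- 0.2; fS <- 0.35; mD <- 1.5; mS <- -1.5; sd0 <- 0.5
  disp <- 0.05; nrep <- 3; n_genes <- 2000; n_ctm <- 0; lib <- 2e6
  mix_mean <- fD * mD + fS * mS
  mix_var <- fD * (sd0^2 + mD^2) + fS * (sd0^2 + mS^2) - mix_mean^2
  mu_typ <- lib / (n_genes + n_ctm)
  meas_var <- 2 * (disp + 1 / mu_typ) / (nrep * log(2)^2)
  oracle <- mix_var + meas_var

  vars <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = n_genes, n_contaminant_genes = n_ctm,
                      frac_dendritic = fD, frac_somatic = fS,
                      mean_log2_dai_D = mD, mean_log2_dai_S = mS,
                      sd_log2_dai = sd0, nb_dispersion = disp,
                      n_replicates = nrep, library_size_per_sample = lib,
                      seed = s)
    sim <- simulate_dataset(cfg)
    fpkm <- compute_fpkm(sim$matrix)
    d <- compute_dai(fpkm, sim$matrix$samples, "control")
    var(log2(d$dai), na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(vars) - oracle) / oracle, 0.15)
})

test_that("group means of realized counts converge to the negative-binomial mean", {
  cfg <- sim_config(n_genes = 250, n_contaminant_genes = 0, n_replicates = 200,
                    library_size_per_sample = 5e5, seed = 11)
  sim <- simulate_dataset(cfg)
  es <- sim$matrix
  tr <- sim$truth
  # reconstruct the expected counts for control/SP from the generative model
  # is implementation-coupled; instead check SR/SP ratio of group-mean counts
  # against the true DAI (they share the library-scaled baseline), and the
  # overall mean against the library size
  sp <- es$samples$genotype == "control" & es$samples$layer == "SP"
  sr <- es$samples$genotype == "control" & es$samples$layer == "SR"
  m_sp <- rowMeans(es$counts[, sp]); m_sr <- rowMeans(es$counts[, sr])
  keep <- m_sp > 50
  ratio <- m_sr[keep] / m_sp[keep]
  expect_lt(median(abs(log2(ratio) - tr$true_log2_dai_control[keep])), 0.05)
  expect_lt(abs(mean(colSums(es$counts)) / cfg$library_size_per_sample - 1), 0.05)
})

test_that("ground truth does not depend on gene order within a class draw", {
  # classes are assigned by permutation; per-gene statistics must be stable
  # under reordering of the output tables
  sim <- simulate_dataset(tiny_config(seed = 9))
  tr <- sim$truth[order(sim$truth$gene_id), ]
  resorted <- sim$truth[order(match(sim$truth$gene_id, rev(sim$truth$gene_id))), ]
  resorted <- resorted[order(resorted$gene_id), ]
  expect_equal(tr, resorted, ignore_attr = TRUE)
})
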