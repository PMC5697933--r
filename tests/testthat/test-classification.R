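# Welch layer test, BH adjustment, and the D/S/NS partition rules

test_that("Welch p-values equal an independent t.test computation on toy data", {
  # 3-vs-3 toy FPKM values; reference computed with stats::t.test on the
  # same log2(FPKM + 0.125) transform
  fpkm <- rbind(g1 = c(10, 12, 9, 30, 35, 28),
                g2 = c(5, 5.5, 4.8, 5.1, 5.2, 4.9),
                g3 = c(100, 90, 110, 10, 12, 9))
  samples <- data.frame(sample = paste0("s", 1:6),
                        layer = rep(c("SP", "SR"), each = 3),
                        genotype = "control", replicate = rep(1:3, 2))
  colnames(fpkm) <- samples$sample
  p <- test_layer_enrichment(fpkm, samples, "control")
  for (g in rownames(fpkm)) {
    ref <- t.test(log2(fpkm[g, 4:6] + 0.125), log2(fpkm[g, 1:3] + 0.125),
                  var.equal = FALSE)$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }
})

test_that("identical replicate values in both layers give p = 1 (tie convention)", {
  fpkm <- rbind(g1 = rep(7, 6))
  samples <- data.frame(sample = paste0("s", 1:6),
                        layer = rep(c("SP", "SR"), each = 3),
                        genotype = "control", replicate = rep(1:3, 2))
  colnames(fpkm) <- samples$sample
  expect_equal(unname(test_layer_enrichment(fpkm, samples, "control")), 1)
})

test_that("permuting replicate order within a layer leaves p unchanged", {
  set.seed(42)
  fpkm <- matrix(rexp(60, 0.1), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  samples <- data.frame(sample = paste0("s", 1:6),
                        layer = rep(c("SP", "SR"), each = 3),
                        genotype = "control", replicate = rep(1:3, 2))
  p1 <- test_layer_enrichment(fpkm, samples, "control")
  perm <- c(3, 1, 2, 4, 6, 5)
  fpkm2 <- fpkm[, perm]
  samples2 <- samples[perm, ]
  p2 <- test_layer_enrichment(fpkm2, samples2, "control")
  expect_equal(p1, p2)
})

test_that("unexpressed genes get no p-value and <2 replicates is an error", {
  samples <- data.frame(sample = paste0("s", 1:6),
                        layer = rep(c("SP", "SR"), each = 3),
                        genotype = "control", replicate = rep(1:3, 2))
  fpkm <- rbind(g1 = c(0, 0, 0, 5, 6, 7), g2 = c(1, 2, 3, 4, 5, 6))
  colnames(fpkm) <- samples$sample
  p <- test_layer_enrichment(fpkm, samples, "control")
  expect_true(is.na(p["g1"]))
  expect_false(is.na(p["g2"]))
  expect_error(test_layer_enrichment(fpkm[, -(1:2)], samples[-(1:2), ], "control"),
               "2 replicates")
})

test_that("moderated method agrees with a direct limma computation", {
  skip_if_not_installed("limma")
  set.seed(7)
  fpkm <- matrix(rexp(120, 0.05), 20, 6,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  samples <- data.frame(sample = paste0("s", 1:6),
                        layer = rep(c("SP", "SR"), each = 3),
                        genotype = "control", replicate = rep(1:3, 2))
  p <- test_layer_enrichment(fpkm, samples, "control", method = "moderated")
  e <- log2(fpkm + 0.125)
  ref <- limma::eBayes(limma::lmFit(e, model.matrix(~factor(samples$layer))),
                       trend = TRUE)$p.value[, 2]
  expect_equal(unname(p), unname(ref), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up example", {
  # step-up by hand: p = (.01,.02,.03,.04), m = 4:
  # q_(4) = .04; q_(3) = min(.04, .03*4/3=.04) = .04; q_(2) = .04; q_(1) = .04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA values pass through without inflating the family size
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.02), "BH"))
})

test_that("classification applies significance, DAI split, tie rule and exclusion in order", {
  dai <- data.frame(dai = c(3.2, 0.4, 2.0, 1.0, 0.4, 5.0, NA),
                    unexpressed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
                    row.names = paste0("g", 1:7))
  q <- c(0.01, 0.20, 0.03, 0.001, 0.01, 0.02, NA)
  res <- classify_genes(dai, q, exclusions = c("g5", "g6"), alpha = 0.05)
  tab <- res$table
  expect_equal(tab$class, c("D", "NS", "D", "NS", "excluded", "excluded", "unexpressed"))
  # excluded genes keep their would-be class for audit
  expect_equal(tab$candidate_class[5:6], c("S", "D"))
  expect_equal(tab$significant[1:2], c("yes", "no"))
  s <- res$summary
  expect_equal(s$n_D + s$n_S + s$n_NS, 7 - s$n_excluded - s$n_unexpressed)
})

test_that("every expressed, non-excluded, tested gene gets exactly one class", {
  sim <- simulate_dataset(tiny_config(seed = 31))
  contam <- sim$truth$gene_id[sim$truth$true_class == "contaminant"]
  fit <- dai_fit(sim$matrix, exclusions = contam)
  tab <- fit$table
  tested <- !is.na(tab$q_value) & !is.na(tab$dai_control)
  classes <- tab$class[tested & !(tab$gene_id %in% contam)]
  expect_true(all(classes %in% c("D", "S", "NS")))
  expect_equal(length(classes), fit$stats$n_D + fit$stats$n_S + fit$stats$n_NS)
  expect_true(all(tab$dai_control[tab$class == "D"] > 1))
  expect_true(all(tab$dai_control[tab$class == "S"] < 1))
})

test_that("raising alpha never shrinks the D u S set", {
  sim <- simulate_dataset(tiny_config(seed = 32))
  es <- sim$matrix
  fpkm <- compute_fpkm(es)
  d <- compute_dai(fpkm, es$samples, "control")
  q <- bh_adjust(test_layer_enrichment(fpkm, es$samples, "control"))
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a) {
    s <- classify_genes(d, q, NULL, a)$summary
    s$n_D + s$n_S
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
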