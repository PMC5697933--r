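#' Compute FPKM from counts and transcript lengths
#'
#' FPKM normalizes read counts by transcript length and library size:
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length_nt[g] * library_size[s])`,
#' where the library size of a sample is its column sum of counts (the
#' count-level proxy for total mapped reads).
#'
#' @param counts genes x samples matrix of non-negative counts, or an
#'   [expr_set] (in which case `lengths` is taken from it).
#' @param lengths transcript lengths in nucleotides, one per gene.
#' @return Matrix of FPKM values with the dimnames of `counts`.
#' @export
compute_fpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "expr_set")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("`lengths` must have one entry per gene")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("transcript length must be > 0 for all genes")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("library size undefined: sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts / lengths, 2, lib, "/") * 1e9
}

#' Per-gene dendritic accumulation index (DAI) for one genotype
#'
#' The DAI of a gene is the ratio of its mean FPKM across SR (dendritic
#' layer) replicates to its mean FPKM across SP (somatic layer) replicates.
#' Genes whose mean FPKM is 0 in either layer are flagged unexpressed and
#' carry no DAI (returned as `NA`), mirroring the requirement that only
#' transcripts with FPKM > 0 in both compartments are analyzed.
#'
#' @param fpkm genes x samples FPKM matrix (see [compute_fpkm()]).
#' @param samples sample metadata data.frame (`sample`, `layer`, `genotype`,
#'   `replicate`) matching the columns of `fpkm`.
#' @param genotype `"control"` or `"cKO"`.
#' @return data.frame with `fpkm_sp`, `fpkm_sr` (replicate means), `dai` and
#'   `unexpressed`; rownames are gene ids.
#' @export
compute_dai <- function(fpkm, samples, genotype) {
  sp <- sample_cols(samples, genotype, "SP")
  sr <- sample_cols(samples, genotype, "SR")
  if (length(sp) < 1 || length(sr) < 1)
    stop("genotype ", genotype, " needs at least one SP and one SR replicate")
  m_sp <- rowMeans(fpkm[, sp, drop = FALSE])
  m_sr <- rowMeans(fpkm[, sr, drop = FALSE])
  unexpressed <- m_sp == 0 | m_sr == 0
  dai <- ifelse(unexpressed, NA_real_, m_sr / m_sp)
  data.frame(fpkm_sp = m_sp, fpkm_sr = m_sr, dai = dai,
             unexpressed = unexpressed, row.names = rownames(fpkm))
}

#' Relative DAI between genotypes
#'
#' Per-gene ratio of the DAI in the conditional knockout to the DAI in
#' controls; `NA` in either input propagates.
#'
#' @param dai_control,dai_cko numeric vectors of per-gene DAI.
#' @return Numeric vector `dai_cko / dai_control`.
#' @export
relative_dai <- function(dai_control, dai_cko) {
  if (length(dai_control) != length(dai_cko))
    stop("DAI vectors must have equal length")
  ifelse(is.na(dai_control) | is.na(dai_cko), NA_real_, dai_cko / dai_control)
}

#' MA-plot coordinates for layer enrichment
#'
#' `M = log2(fpkm_sr / fpkm_sp)` (the log2 DAI) and
#' `A = (log2 fpkm_sr + log2 fpkm_sp) / 2`. Genes with zero FPKM in either
#' layer get `NA` coordinates and are excluded from the plot set.
#'
#' @param fpkm_sp,fpkm_sr per-gene mean FPKM in the somatic and dendritic layer.
#' @return data.frame with columns `A` and `M`.
#' @export
ma_coordinates <- function(fpkm_sp, fpkm_sr) {
  if (length(fpkm_sp) != length(fpkm_sr))
    stop("FPKM vectors must have equal length")
  ok <- !is.na(fpkm_sp) & !is.na(fpkm_sr) & fpkm_sp > 0 & fpkm_sr > 0
  A <- M <- rep(NA_real_, length(fpkm_sp))
  A[ok] <- (log2(fpkm_sr[ok]) + log2(fpkm_sp[ok])) / 2
  M[ok] <- log2(fpkm_sr[ok]) - log2(fpkm_sp[ok])
  data.frame(A = A, M = M)
}
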