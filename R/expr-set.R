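#' Expression set: counts, transcript lengths and sample metadata
#'
#' Light-weight container for a gene-level RNA-seq experiment with two
#' microdissected layers (SP = stratum pyramidale, soma; SR = stratum
#' radiatum, dendrites) and two genotypes (`control`, `cKO`).
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids,
#'   colnames are sample ids. Counts must be non-negative integers.
#' @param lengths numeric vector of transcript lengths in nucleotides, one
#'   per gene (named or in row order).
#' @param samples data.frame with columns `sample`, `layer` (`"SP"`/`"SR"`),
#'   `genotype` (`"control"`/`"cKO"`) and `replicate` (integer index), one
#'   row per column of `counts`.
#'
#' @return An object of class `expr_set`: a list with elements `counts`,
#'   `lengths` and `samples`.
#' @export
expr_set <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers")
  storage.mode(counts) <- "double"

  if (!is.null(names(lengths))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
      stop("transcript length missing for gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("`lengths` must have one entry per gene")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("transcript lengths must be positive")
  storage.mode(lengths) <- "double"
  names(lengths) <- rownames(counts)

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "layer", "genotype", "replicate")
  if (!all(req %in% names(samples)))
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample))
    stop("sample metadata does not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  bad_layer <- setdiff(unique(samples$layer), c("SP", "SR"))
  if (length(bad_layer))
    stop("unknown layer token(s): ", paste(bad_layer, collapse = ", "))
  bad_geno <- setdiff(unique(samples$genotype), c("control", "cKO"))
  if (length(bad_geno))
    stop("unknown genotype token(s): ", paste(bad_geno, collapse = ", "))
  grp <- table(samples$layer, samples$genotype)
  if (!all(dim(grp) == c(2, 2)) || any(grp < 1))
    stop("every (layer, genotype) group must have at least one replicate")

  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(layer = x$samples$layer, genotype = x$samples$genotype))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$counts)

# columns of an expr_set belonging to one (genotype, layer) group
sample_cols <- function(samples, genotype, layer = NULL) {
  sel <- samples$genotype == genotype
  if (!is.null(layer)) sel <- sel & samples$layer == layer
  which(sel)
}
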