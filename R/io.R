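# Tab-separated I/O for expression tables, gene lists, GO annotations and
# the classification output tables. UTF-8, header row, dot decimal separator;
# readers validate and reject rather than coerce.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write an expression set as a count table plus sample metadata table
#'
#' @param es an [expr_set].
#' @param counts_path output path for the count table (columns: `gene_id`,
#'   `length`, then one column per sample).
#' @param metadata_path output path for the sample table (columns: `sample`,
#'   `layer`, `genotype`, `replicate`).
#' @return Invisibly, `c(counts_path, metadata_path)`.
#' @export
write_expression_table <- function(es, counts_path, metadata_path) {
  stopifnot(inherits(es, "expr_set"))
  tab <- data.frame(gene_id = rownames(es$counts),
                    length = as.numeric(es$lengths),
                    es$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, counts_path)
  write_tsv(es$samples, metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' Read a gene-level expression table with sample metadata
#'
#' The count table is tab-separated with a header: first column gene id,
#' second column transcript length (nt), remaining columns one per sample.
#' The metadata table maps each sample column to its layer (`SP`/`SR`),
#' genotype (`control`/`cKO`) and replicate index. Duplicated gene ids,
#' samples missing from the metadata, negative counts and unknown
#' layer/genotype tokens are format errors.
#'
#' @param path count table path.
#' @param metadata_path sample metadata path.
#' @return An [expr_set].
#' @export
read_expression_table <- function(path, metadata_path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 3)
    stop("expression table needs gene id, length and at least one sample column")
  gene_id <- trimws(as.character(tab[[1]]))
  if (anyDuplicated(gene_id))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  lengths <- tab[[2]]
  if (!is.numeric(lengths))
    stop("transcript length column must be numeric")
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(counts))
    stop("count columns must be numeric")
  if (any(is.na(counts)))
    stop("missing values are not permitted in count tables")
  if (any(counts < 0))
    stop("negative count in expression table")
  rownames(counts) <- gene_id
  meta <- read_tsv(metadata_path)
  req <- c("sample", "layer", "genotype", "replicate")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing))
    stop("sample(s) in count table absent from metadata: ",
         paste(missing, collapse = ", "))
  meta <- meta[meta$sample %in% colnames(counts), , drop = FALSE]
  expr_set(counts, stats::setNames(lengths, gene_id), meta)
}

#' Read ground truth written by [write_fixture()]
#' @param path ground-truth table path.
#' @return The per-gene truth data.frame.
#' @export
read_ground_truth <- function(path) {
  tr <- read_tsv(path, colClasses = list(gene_id = "character"))
  req <- c("gene_id", "true_class", "true_log2_dai_control",
           "true_log2_dai_cko", "ko_targeted", "transcript_length")
  if (!all(req %in% names(tr)))
    stop("ground-truth table must have columns: ", paste(req, collapse = ", "))
  tr
}

#' Read cell-type exclusion gene lists
#'
#' Each file holds one gene id per line; `#` starts a comment and surrounding
#' whitespace is trimmed. Gene ids are matched case-sensitively. An empty
#' file yields an empty set.
#'
#' @param paths character vector of file paths; names (or basenames without
#'   extension) label the cell types.
#' @return An object of class `exclusion_lists`: a named list of character
#'   vectors of gene ids.
#' @export
read_exclusion_lists <- function(paths) {
  labels <- names(paths)
  if (is.null(labels)) labels <- rep("", length(paths))
  auto <- sub("\\.[^.]*$", "", basename(paths))
  labels[!nzchar(labels)] <- auto[!nzchar(labels)]
  if (anyDuplicated(labels))
    stop("exclusion list labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("exclusion list not found: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    unique(lines[nzchar(lines)])
  })
  names(out) <- labels
  structure(out, class = "exclusion_lists")
}

#' Union of all excluded gene ids
#' @param x an `exclusion_lists` object (or a plain list / character vector).
#' @return Character vector of unique gene ids.
#' @export
exclusion_union <- function(x) {
  if (is.null(x)) return(character(0))
  if (is.character(x)) return(unique(x))
  unique(unlist(x, use.names = FALSE))
}

#' @export
print.exclusion_lists <- function(x, ...) {
  cat("exclusion_lists:", length(x), "list(s),",
      length(exclusion_union(x)), "unique gene ids\n")
  for (nm in names(x)) cat(" ", nm, ":", length(x[[nm]]), "genes\n")
  invisible(x)
}

#' Read a gene-to-GO-term annotation table
#'
#' Tab-separated, no header: column 1 gene id, column 2 GO term id, optional
#' column 3 human-readable term name. Duplicate pairs are collapsed; rows with
#' missing fields are format errors reported with their line number.
#'
#' @param path annotation file path.
#' @return An object of class `annotation_map`: a list with `gene2terms`
#'   (named list: gene id -> character vector of term ids) and `term_names`
#'   (named character vector, possibly empty).
#' @export
read_go_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  genes <- terms <- character(length(keep))
  names_acc <- character(0)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- trimws(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]))
      stop(sprintf("malformed annotation row at line %d: need gene id and term id", ln))
    genes[i] <- f[1]; terms[i] <- f[2]
    if (length(f) >= 3 && nzchar(f[3])) names_acc[f[2]] <- f[3]
  }
  pairs <- unique(data.frame(gene = genes, term = terms, stringsAsFactors = FALSE))
  gene2terms <- if (nrow(pairs)) split(pairs$term, pairs$gene) else
    stats::setNames(list(), character(0))
  structure(list(gene2terms = gene2terms, term_names = names_acc),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(x$gene2terms), "genes,",
      length(unique(unlist(x$gene2terms, use.names = FALSE))), "terms\n")
  invisible(x)
}

#' Write the classification output tables
#'
#' Emits three tab-separated tables into `dir`, mirroring the structure of
#' the study's supplementary lists: `all_mRNAs.tsv` with a yes/no significance
#' flag, per-genotype mean FPKM in each layer, DAI in each genotype and the
#' relative DAI (cKO/control); `D_mRNAs.tsv` and `S_mRNAs.tsv` with the same
#' columns restricted to the final D and S classes. Column order is fixed:
#' gene_id, significant, fpkm_sp_control, fpkm_sr_control, fpkm_sp_cko,
#' fpkm_sr_cko, dai_control, dai_cko, relative_dai, p_value, q_value, class,
#' candidate_class.
#'
#' @param fit a [dai_fit] object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_classification_tables <- function(fit, dir) {
  stopifnot(inherits(fit, "dai_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("gene_id", "significant", "fpkm_sp_control", "fpkm_sr_control",
            "fpkm_sp_cko", "fpkm_sr_cko", "dai_control", "dai_cko",
            "relative_dai", "p_value", "q_value", "class", "candidate_class")
  tab <- fit$table[, cols]
  paths <- c(all = file.path(dir, "all_mRNAs.tsv"),
             D = file.path(dir, "D_mRNAs.tsv"),
             S = file.path(dir, "S_mRNAs.tsv"))
  write_tsv(tab, paths["all"])
  write_tsv(tab[tab$class == "D", ], paths["D"])
  write_tsv(tab[tab$class == "S", ], paths["S"])
  invisible(paths)
}
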