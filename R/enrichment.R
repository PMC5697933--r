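#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term, the probability of seeing at
#' least `k` carriers. Evaluated through the stable distribution-function
#' implementation in \pkg{stats}.
#'
#' @param k observed carriers in the query.
#' @param n query size.
#' @param K carriers in the universe.
#' @param N universe size.
#' @return The one-sided upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term over-representation by hypergeometric test
#'
#' Tests each GO term for over-representation in a query gene set against a
#' background, using the one-sided upper-tail hypergeometric probability and
#' BH FDR control across terms. The universe is annotation-restricted: genes
#' without any annotation are dropped from both query and background, so `n`
#' and `N` count annotated genes only. One result row is produced per term
#' carried by at least one annotated background gene (subject to
#' `min_term_size`).
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param annotation an `annotation_map` from [read_go_annotation()], or a
#'   named list mapping gene id -> character vector of term ids.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param min_term_size drop terms carried by fewer than this many background
#'   genes (default 1 = keep all).
#' @return data.frame of class `go_enrichment` with one row per term:
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment = (k/n) / (K/N)`, `p_value`, `q_value`, `significant`;
#'   sorted by decreasing fold enrichment, ties broken by increasing p.
#' @export
go_enrichment <- function(query, background, annotation, alpha = 0.05,
                          min_term_size = 1L) {
  if (inherits(annotation, "annotation_map")) {
    gene2terms <- annotation$gene2terms
    term_names <- annotation$term_names
  } else {
    gene2terms <- annotation
    term_names <- character(0)
  }
  query <- unique(trimws(query))
  background <- unique(trimws(background))
  if (!all(query %in% background))
    stop("query genes must be a subset of the background")

  bg_annot <- intersect(background, names(gene2terms))
  q_annot <- intersect(query, bg_annot)
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(q_annot) == 0) {
    warning("no annotated genes in the query; returning empty result")
    return(structure(empty, class = c("go_enrichment", "data.frame")))
  }
  N <- length(bg_annot)
  n <- length(q_annot)
  K_tab <- table(unlist(gene2terms[bg_annot], use.names = FALSE))
  K_tab <- K_tab[K_tab >= min_term_size]
  if (length(K_tab) == 0)
    return(structure(empty, class = c("go_enrichment", "data.frame")))
  k_tab <- table(unlist(gene2terms[q_annot], use.names = FALSE))
  terms <- names(K_tab)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L
  K <- as.integer(K_tab)
  p <- vapply(seq_along(terms),
              function(i) hypergeom_upper_tail(k[i], n, K[i], N), numeric(1))
  res <- data.frame(term_id = terms,
                    term_name = unname(ifelse(terms %in% names(term_names),
                                              term_names[terms], NA_character_)),
                    k = k, n = n, K = K, N = N,
                    fold_enrichment = (k / n) / (K / N),
                    p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res$significant <- res$q_value < alpha
  res <- res[order(-res$fold_enrichment, res$p_value, res$term_id), ]
  rownames(res) <- NULL
  structure(res, class = c("go_enrichment", "data.frame"))
}
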