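#' Annotation-term over-representation (hypergeometric test)
#'
#' For each annotation term, the exact hypergeometric upper tail
#' `P(X >= k)` of drawing `k` term genes in a set of size `n` from a universe
#' of `N` genes of which `K` carry the term, with Benjamini-Hochberg
#' adjustment across the tested terms. Terms are opaque labels: no ontology
#' structure is consulted. The universe must be chosen explicitly (all genes
#' screened, or all genes on the expression platform).
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of background genes.
#' @param annotation data.frame with columns `gene`, `term`.
#' @param min_term_size terms annotating fewer universe genes are skipped
#'   (count reported in the `skipped` attribute).
#' @return data.frame of class `enrichment_result` sorted by p: `term, k, K,
#'   n, N, p, q`.
#' @export
enrich <- function(gene_set, universe, annotation, min_term_size = 2) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stopf("gene set is not a subset of the universe (e.g. %s)", outside[1L])
  }
  if (!all(c("gene", "term") %in% names(annotation))) {
    stop("`annotation` needs columns `gene` and `term`", call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% universe, c("gene", "term")]
  ann <- unique(ann)
  if (!nrow(ann)) stop("annotation does not intersect the universe",
                       call. = FALSE)
  term_sizes <- table(ann$term)
  tested <- names(term_sizes)[term_sizes >= min_term_size]
  skipped <- length(term_sizes) - length(tested)

  N <- length(universe)
  n <- length(gene_set)
  in_set <- ann$gene %in% gene_set
  k_all <- table(factor(ann$term[in_set], levels = tested))
  K_all <- term_sizes[tested]
  p <- stats::phyper(as.numeric(k_all) - 1, as.numeric(K_all),
                     N - as.numeric(K_all), n, lower.tail = FALSE)
  out <- data.frame(term = tested, k = as.integer(k_all),
                    K = as.integer(K_all), n = n, N = N, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("enrichment_result", "data.frame"))
}

#' Read a gene-to-term annotation table
#' @param path TSV with columns `gene` and `term`.
#' @export
read_annotation <- function(path) {
  read_tsv_checked(path, required = c("gene", "term"))
}
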