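# IQR-rule hit calling: per category, a line is an enhancer (suppressor) when
# its mean score lies strictly above (below) the category median plus (minus)
# the interquartile range.

#' Hit-calling thresholds for one category
#'
#' Median and interquartile range of the per-line mean scores in a category,
#' computed over all non-lethal scored lines (zero-phenotype lines included).
#' Bounds are `median - IQR` and `median + IQR`.
#'
#' @param matrix a `line_score_matrix` or plain numeric matrix
#'   (lines x categories).
#' @param category category name (a column of `matrix`).
#' @param quantile_type quantile algorithm passed to [stats::quantile()];
#'   the default 7 is linear interpolation. IQR is method-sensitive at screen
#'   size, so the choice is exposed and recorded in the output.
#' @return list of class `category_thresholds`: `category, median, iqr,
#'   lower, upper, n, quantile_type`.
#' @export
category_thresholds <- function(matrix, category, quantile_type = 7) {
  if (!category %in% colnames(matrix)) {
    stopf("unknown category: '%s'", category)
  }
  x <- matrix[, category]
  x <- x[is.finite(x)]
  if (length(x) < 4L) {
    stopf("category '%s': need >= 4 scored lines for quartiles", category)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  iqr <- q[3L] - q[1L]
  structure(list(category = category, median = q[2L], iqr = iqr,
                 lower = q[2L] - iqr, upper = q[2L] + iqr,
                 n = length(x), quantile_type = quantile_type),
            class = "category_thresholds")
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat(sprintf("<thresholds '%s'> median %.3f | IQR %.3f | call outside (%.3f, %.3f) | n = %d\n",
              x$category, x$median, x$iqr, x$lower, x$upper, x$n))
  invisible(x)
}

#' Call enhancer/suppressor hits per category
#'
#' Strict inequalities against the category bounds: ties at a bound are not
#' hits, and a zero IQR therefore calls any line off the median. Per-category
#' hit counts and hit score ranges are attached for audit.
#'
#' @inheritParams category_thresholds
#' @param categories categories to call (default: all columns).
#' @return a `hit_table`: data.frame `line_id, gene_id, category, mean_score,
#'   call` (call in enhancer/suppressor/none) with attributes `summary` (per
#'   category: thresholds, `n_enhancers`, `n_suppressors`, hit score ranges)
#'   and `thresholds` (list of `category_thresholds`).
#' @export
call_hits <- function(matrix, categories = colnames(matrix),
                      quantile_type = 7) {
  if (!length(categories)) stop("empty category list", call. = FALSE)
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- sprintf("L%04d", seq_len(nrow(matrix)))
  }
  gm <- line_genes(matrix)
  thresholds <- lapply(categories, function(cc)
    category_thresholds(matrix, cc, quantile_type))
  names(thresholds) <- categories

  rows <- lapply(categories, function(cc) {
    th <- thresholds[[cc]]
    mean_score <- matrix[, cc]
    call <- ifelse(mean_score > th$upper, "enhancer",
                   ifelse(mean_score < th$lower, "suppressor", "none"))
    data.frame(line_id = rownames(matrix), gene_id = unname(gm),
               category = cc, mean_score = as.numeric(mean_score),
               call = call, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(categories, function(cc) {
    th <- thresholds[[cc]]
    sub <- tab[tab$category == cc, ]
    enh <- sub$mean_score[sub$call == "enhancer"]
    sup <- sub$mean_score[sub$call == "suppressor"]
    data.frame(category = cc, median = th$median, iqr = th$iqr,
               lower = th$lower, upper = th$upper,
               n_enhancers = length(enh), n_suppressors = length(sup),
               enh_min = if (length(enh)) min(enh) else NA_real_,
               enh_max = if (length(enh)) max(enh) else NA_real_,
               sup_min = if (length(sup)) min(sup) else NA_real_,
               sup_max = if (length(sup)) max(sup) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(tab, summary = summ, thresholds = thresholds,
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<hit_table> %d categories | %d enhancer and %d suppressor calls over %d lines\n",
              nrow(s), sum(s$n_enhancers), sum(s$n_suppressors),
              length(unique(x$line_id))))
  invisible(x)
}

#' Combine hits across categories into one gene set
#'
#' Union of the genes with the requested call in any of the listed categories
#' (e.g. the invasion, multilayering and cell-body-rounding enhancers that
#' seed the invasion-suppressor network), retaining per-gene category
#' membership for node annotation.
#'
#' @param hits a `hit_table` from [call_hits()].
#' @param categories categories to combine (must be present in `hits`).
#' @param direction `"enhancer"` or `"suppressor"`.
#' @return data.frame `gene_id, categories` (comma-joined), `n_categories`.
#' @export
combine_hits <- function(hits, categories,
                         direction = c("enhancer", "suppressor")) {
  direction <- match.arg(direction)
  stopifnot(inherits(hits, "hit_table"))
  if (!length(categories)) stop("empty category list", call. = FALSE)
  missing <- setdiff(categories, unique(hits$category))
  if (length(missing)) {
    stopf("categories absent from hit table: %s",
          paste(missing, collapse = ", "))
  }
  sub <- hits[hits$category %in% categories & hits$call == direction, ]
  if (!nrow(sub)) {
    return(data.frame(gene_id = character(), categories = character(),
                      n_categories = integer(), stringsAsFactors = FALSE))
  }
  by_gene <- split(sub$category, sub$gene_id)
  data.frame(
    gene_id = names(by_gene),
    categories = vapply(by_gene, function(x)
      paste(sort(unique(x)), collapse = ","), ""),
    n_categories = vapply(by_gene, function(x)
      length(unique(x)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
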