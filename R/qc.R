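# Quality control of the score database: qualitative-vs-quantitative
# correlation, blinded-scorer agreement, and RNAi-line-pair concordance.

#' Correlate qualitative scores with quantitative measurements
#'
#' For each category, Spearman rank correlation (midranks for ties) between
#' per-animal qualitative scores and a matched quantitative measurement of
#' the same trait, with a two-sided p-value. This is the check that ordinal
#' blind scoring tracks real measurements.
#'
#' @param qual named list (per category) of per-animal qualitative scores, or
#'   a single numeric vector.
#' @param quant matched quantitative values, same shape as `qual`.
#' @return data.frame `category, rho, p, n`.
#' @export
qual_quant_correlation <- function(qual, quant) {
  if (is.numeric(qual)) qual <- list(overall = qual)
  if (is.numeric(quant)) quant <- list(overall = quant)
  if (!identical(names(qual), names(quant))) {
    stop("`qual` and `quant` must cover the same categories", call. = FALSE)
  }
  rows <- lapply(names(qual), function(cat) {
    x <- qual[[cat]]; y <- quant[[cat]]
    if (length(x) != length(y)) {
      stopf("category '%s': paired vectors differ in length", cat)
    }
    if (length(x) < 3L) {
      stopf("category '%s': need >= 3 paired animals", cat)
    }
    s <- spearman_midrank(x, y)
    data.frame(category = cat, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between the two blinded scorers
#'
#' Spearman correlation per category between the two scorers' score vectors
#' over matched (line, animal) cells; cells seen by only one scorer are
#' excluded and counted.
#'
#' @param table a [score_table()].
#' @param scorers which two scorer ids to compare (default: the first two
#'   present).
#' @return data.frame `category, rho, p, n_cells, n_single` plus an `overall`
#'   attribute with the pooled correlation.
#' @export
scorer_agreement <- function(table, scorers = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(scorers)) {
    scorers <- sort(unique(table$scorer_id))[1:2]
  }
  if (length(scorers) != 2L || anyNA(scorers)) {
    stop("need two scorers to compare", call. = FALSE)
  }
  df <- table[table$scorer_id %in% scorers, , drop = FALSE]
  key <- paste(df$line_id, df$animal_id, df$category, sep = "\r")
  w1 <- df$scorer_id == scorers[1L]
  m1 <- df$score[w1]; names(m1) <- key[w1]
  m2 <- df$score[!w1]; names(m2) <- key[!w1]
  common <- intersect(names(m1), names(m2))
  n_single <- length(m1) + length(m2) - 2L * length(common)
  if (!length(common)) stop("no doubly-scored cells", call. = FALSE)
  x <- m1[common]; y <- m2[common]
  cat_of <- vapply(strsplit(common, "\r", fixed = TRUE), `[[`, "", 3L)
  rows <- lapply(split(seq_along(common), cat_of), function(i) {
    s <- spearman_midrank(x[i], y[i])
    data.frame(rho = s$rho, p = s$p, n_cells = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(category = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$n_single <- n_single
  attr(out, "overall") <- spearman_midrank(x, y)
  out
}

#' Concordance of independent RNAi-line pairs
#'
#' For every gene targeted by two independent RNAi lines, the Spearman
#' correlation between the two lines' category profiles, with a seeded
#' permutation p-value (category entries of one profile shuffled). A pair is
#' concordant when `rho > 0` and `p < alpha`; constant (degenerate) profiles
#' carry no evidence of similarity and are non-concordant, never errors.
#' Genes with more than two lines contribute all unordered line pairs and are
#' flagged.
#'
#' @param matrix a `line_score_matrix` (means per line x category).
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level for concordance.
#' @param seed integer seed for the permutations.
#' @return a `concordance_report`: data.frame `gene_id, line_a, line_b, rho,
#'   p, concordant, degenerate, multi_line` with attribute `overall`
#'   (`n_genes_two_lines`, `n_concordant`, `fraction`).
#' @export
rnai_pair_concordance <- function(matrix, n_perm = 10000, alpha = 0.05,
                                  seed = 1) {
  n_perm <- check_count(n_perm, "n_perm", 100L)
  gm <- line_genes(matrix)
  by_gene <- split(names(gm), gm)
  multi <- names(by_gene)[lengths(by_gene) >= 2L]
  if (!length(multi)) {
    stop("no gene is covered by two or more RNAi lines", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (g in multi) {
      lines <- sort(by_gene[[g]])
      prs <- utils::combn(lines, 2L)
      for (j in seq_len(ncol(prs))) {
        a <- matrix[prs[1L, j], ]; b <- matrix[prs[2L, j], ]
        ra <- rank(a); rb <- rank(b)
        degenerate <- stats::sd(ra) == 0 || stats::sd(rb) == 0
        if (degenerate) {
          rho <- NA_real_; p <- NA_real_
        } else {
          rho <- stats::cor(ra, rb)
          # permutation roles are assigned by vector content, not line
          # label, so the report is invariant to swapping line_a/line_b
          if (paste(ra, collapse = ",") <= paste(rb, collapse = ",")) {
            fixed <- ra; shuffled <- rb
          } else {
            fixed <- rb; shuffled <- ra
          }
          perm <- replicate(n_perm, sample(shuffled))
          rho_perm <- cor_vec_mat(fixed, perm)
          p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, line_a = prs[1L, j], line_b = prs[2L, j],
          rho = rho, p = p,
          concordant = !degenerate && !is.na(rho) && rho > 0 && p < alpha,
          degenerate = degenerate, multi_line = length(lines) > 2L,
          stringsAsFactors = FALSE)
      }
    }
    report <- do.call(rbind, rows)
    two_line <- !report$multi_line
    overall <- list(
      n_genes_two_lines = length(unique(report$gene_id[two_line])),
      n_concordant = length(unique(report$gene_id[two_line & report$concordant])),
      alpha = alpha, n_perm = n_perm)
    overall$fraction <- overall$n_concordant /
      max(overall$n_genes_two_lines, 1L)
    structure(report, overall = overall,
              class = c("concordance_report", "data.frame"))
  })
}

#' @export
print.concordance_report <- function(x, ...) {
  ov <- attr(x, "overall")
  cat(sprintf("<concordance_report> %d line pairs | %d two-line genes | %d concordant (%.1f%%) at alpha %.2f\n",
              nrow(x), ov$n_genes_two_lines, ov$n_concordant,
              100 * ov$fraction, ov$alpha))
  invisible(x)
}
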