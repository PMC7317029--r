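# Knockdown microarray differential expression: per-gene t-tests on log2
# intensities against the two control conditions, signed fold changes from
# anti-logged group means, and the p/FC pass filter.

#' Signed fold change from linear-scale group means
#'
#' Ratio convention used for microarray reporting: `r = mean_kd / mean_ctrl`
#' reported as `r` when `r >= 1` and `-1/r` otherwise, so a halving is -2 and
#' thresholds read "FC >= 1.5 or FC <= -1.5". Never in (-1, 1).
#'
#' @param mean_kd,mean_ctrl positive linear-scale means (vectorized).
#' @return signed fold change(s).
#' @export
fold_change <- function(mean_kd, mean_ctrl) {
  if (any(!is.finite(mean_kd)) || any(!is.finite(mean_ctrl)) ||
      any(mean_kd <= 0) || any(mean_ctrl <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  r <- mean_kd / mean_ctrl
  ifelse(r >= 1, r, -1 / r)
}

# Vectorized two-sample t-test on the rows of two log2 matrices.
row_t_test <- function(a, b, variance = c("equal", "unequal")) {
  variance <- match.arg(variance)
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  if (variance == "equal") {
    df <- rep(n1 + n2 - 2L, length(m1))
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(p = p, t = tt, flag_zero_var = zero)
}

#' Per-gene differential-expression tests
#'
#' Two-sided t-tests on log2 intensities comparing the knockdown condition
#' with its controls. The default `mode = "each"` requires the knockdown to
#' differ from each control separately and reports the larger of the two
#' p-values; `mode = "pooled"` tests against all control samples pooled.
#' `variance = "equal"` (default) uses the pooled-variance t; `"unequal"`
#' uses Welch, whose degrees of freedom collapse at very small group sizes.
#' Fold changes come from anti-logged group means (knockdown vs all controls
#' pooled). Zero-variance, equal-mean genes get `p = 1` with a flag.
#'
#' @param expr genes x samples numeric matrix of log2 intensities.
#' @param samples data.frame `sample, condition` (or a named character
#'   vector sample -> condition).
#' @param kd_label condition label of the knockdown (default: first
#'   condition).
#' @param mode `"each"` or `"pooled"`, see above.
#' @param variance `"equal"` or `"unequal"`.
#' @return data.frame of class `de_result`: per gene the mean log2 per
#'   condition, `fc` (signed), `p`, `q` (BH, context only), `flag_zero_var`,
#'   `passes` is added by [de_filter()].
#' @export
de_test <- function(expr, samples, kd_label = NULL,
                    mode = c("each", "pooled"),
                    variance = c("equal", "unequal")) {
  mode <- match.arg(mode)
  variance <- match.arg(variance)
  expr <- as.matrix(expr)
  if (is.character(samples) && !is.null(names(samples))) {
    samples <- data.frame(sample = names(samples), condition = samples,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample", "condition") %in% names(samples)))
  miss <- setdiff(samples$sample, colnames(expr))
  if (length(miss)) stopf("sample(s) absent from matrix: %s",
                          paste(miss, collapse = ", "))
  conds <- unique(samples$condition)
  if (is.null(kd_label)) kd_label <- conds[1L]
  if (!kd_label %in% conds) stopf("no '%s' condition", kd_label)
  controls <- setdiff(conds, kd_label)
  if (!length(controls)) stop("no control condition", call. = FALSE)
  cols_of <- function(cond) samples$sample[samples$condition == cond]
  if (any(vapply(conds, function(cc) length(cols_of(cc)), 0L) < 2L)) {
    stop("each condition needs >= 2 samples", call. = FALSE)
  }
  kd <- expr[, cols_of(kd_label), drop = FALSE]
  ctrl_all <- expr[, unlist(lapply(controls, cols_of)), drop = FALSE]

  if (mode == "pooled") {
    tst <- row_t_test(kd, ctrl_all, variance)
    p <- tst$p
    zero <- tst$flag_zero_var
  } else {
    tests <- lapply(controls, function(cc)
      row_t_test(kd, expr[, cols_of(cc), drop = FALSE], variance))
    p <- do.call(pmax, lapply(tests, `[[`, "p"))
    zero <- Reduce(`|`, lapply(tests, `[[`, "flag_zero_var"))
  }
  means <- vapply(conds, function(cc)
    rowMeans(expr[, cols_of(cc), drop = FALSE]), numeric(nrow(expr)))
  colnames(means) <- paste0("mean_log2_", conds)
  fc <- fold_change(2^rowMeans(kd), 2^rowMeans(ctrl_all))
  out <- data.frame(gene = rownames(expr) %||%
                      as.character(seq_len(nrow(expr))),
                    means, fc = fc, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    flag_zero_var = zero,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "variance") <- variance
  attr(out, "kd_label") <- kd_label
  class(out) <- c("de_result", "data.frame")
  out
}

#' Filter differential-expression results
#'
#' Pass rule: `p < p_thresh` and `|fc| >= fc_thresh` (the fold-change bound
#' is inclusive; no multiple-testing correction is applied in the rule
#' itself, the BH `q` column is context only). Returns passing genes sorted
#' by decreasing |fc|, with up/down counts attached.
#'
#' @param results a `de_result` from [de_test()].
#' @param p_thresh raw p-value cut-off (exclusive).
#' @param fc_thresh absolute signed-fold-change cut-off (inclusive).
#' @return the passing subset, sorted by `|fc|` descending, with attribute
#'   `counts` (`n_up`, `n_down`, `n_tested`); all rows gain a logical
#'   `passes` column in the `full` attribute.
#' @export
de_filter <- function(results, p_thresh = 0.01, fc_thresh = 1.5) {
  stopifnot(is.data.frame(results), all(c("fc", "p") %in% names(results)))
  passes <- results$p < p_thresh &
    (results$fc >= fc_thresh | results$fc <= -fc_thresh)
  results$passes <- passes
  hits <- results[passes, , drop = FALSE]
  hits <- hits[order(-abs(hits$fc)), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "counts") <- list(n_up = sum(hits$fc > 0),
                               n_down = sum(hits$fc < 0),
                               n_tested = nrow(results))
  attr(hits, "full") <- results
  hits
}

#' Read an expression matrix (genes x samples, log2) from TSV
#' @param path TSV; first column gene ids, remaining columns samples.
#' @export
read_expression <- function(path) read_matrix_tsv(path)

#' Read a sample sheet
#' @param path TSV with columns `sample` and `condition`.
#' @export
read_sample_sheet <- function(path) {
  read_tsv_checked(path, required = c("sample", "condition"))
}
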