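# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary, restored RNG state
#'
#' All randomised operations in the package take an explicit integer seed and
#' run through this helper, so they never disturb (nor depend on) the caller's
#' global RNG stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Positive-count argument check: counts must be single finite integers >= min.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_proportion <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a proportion in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Spearman correlation with midranks
#'
#' Rank correlation used throughout the QC and track modules. Ties receive
#' midranks; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' A constant vector has no rank ordering: `rho` is `NA` and the result is
#' flagged degenerate rather than raising an error.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `rho`, `rho2`, `p`, `n`, `degenerate`.
#' @examples
#' spearman_midrank(1:4, c(2, 3, 3, 5))$rho
#' @export
spearman_midrank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) {
    return(list(rho = NA_real_, rho2 = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, rho2 = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (n > 2L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE))
  } else {
    p <- NA_real_
  }
  list(rho = rho, rho2 = rho^2, p = p, n = n, degenerate = FALSE)
}

# Fast Pearson correlation of a fixed vector against the columns of a matrix.
# Used by the permutation machinery in the QC module.
cor_vec_mat <- function(x, M) {
  x <- x - mean(x)
  M <- sweep(M, 2L, colMeans(M))
  num <- drop(crossprod(M, x))
  den <- sqrt(sum(x^2)) * sqrt(colSums(M^2))
  num / den
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Two-sided t-test p-value that degrades gracefully when the data are
# (numerically) constant: equal means give p = 1, different means p = 0.
safe_t_p <- function(x, y, paired = FALSE) {
  tryCatch(stats::t.test(x, y, paired = paired)$p.value,
           error = function(e) {
             d <- mean(x) - mean(y)
             if (abs(d) < 1e-8 * (abs(mean(x)) + abs(mean(y)) + 1)) 1 else 0
           })
}

read_tsv_checked <- function(path, required = NULL, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stopf("%s: missing required column(s): %s", path,
            paste(miss, collapse = ", "))
    }
  }
  df
}

#' Write a data frame as TSV (no quoting, no row names)
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a matrix as TSV with a leading id column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name for the rowname column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path; first column is taken as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
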