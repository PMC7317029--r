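#' Construct and validate a phenotype score table
#'
#' The score database is long-form: one row per animal, scorer, RNAi line and
#' phenotype category, with an integer score on a symmetric ordinal scale
#' (0 = indistinguishable from the sensitized baseline, sign = direction of
#' change). Lethal lines carry no score rows and are tracked separately.
#'
#' @param df data.frame with columns `line_id`, `gene_id`, `animal_id`,
#'   `scorer_id`, `category`, `score`.
#' @param scale integer ordinal bounds `c(min, max)` with `min < 0 < max`.
#' @param lethal_lines character vector of lethal line ids (no score rows).
#' @param categories category registry; defaults to [default_categories()].
#' @return a `score_table` (data.frame subclass with `scale`, `lethal_lines`
#'   and `categories` attributes).
#' @export
score_table <- function(df, scale = c(-2L, 2L), lethal_lines = character(),
                        categories = default_categories()) {
  required <- c("line_id", "gene_id", "animal_id", "scorer_id", "category",
                "score")
  miss <- setdiff(required, names(df))
  if (length(miss)) stopf("score table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  scale <- check_scale(scale)
  df <- as.data.frame(df)[required]
  for (col in required[1:5]) df[[col]] <- as.character(df[[col]])

  bad <- which(!is.finite(df$score) | df$score != trunc(df$score) |
                 df$score < scale[1L] | df$score > scale[2L])
  if (length(bad)) {
    stopf("score out of range [%d, %d] at row %d (line %s, category '%s', score %s)",
          scale[1L], scale[2L], bad[1L], df$line_id[bad[1L]],
          df$category[bad[1L]], format(df$score[bad[1L]]))
  }
  df$score <- as.integer(df$score)

  unknown <- setdiff(unique(df$category), categories)
  if (length(unknown)) {
    stopf("category not in registry: %s (registry has %d entries)",
          paste(utils::head(unknown, 3L), collapse = ", "), length(categories))
  }

  key <- paste(df$line_id, df$animal_id, df$scorer_id, df$category, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("duplicate (line, animal, scorer, category) at row %d: %s / %s / %s / '%s'",
          dup[1L], df$line_id[dup[1L]], df$animal_id[dup[1L]],
          df$scorer_id[dup[1L]], df$category[dup[1L]])
  }

  scored_lethal <- intersect(unique(df$line_id), lethal_lines)
  if (length(scored_lethal)) {
    stopf("lethal line(s) have score rows: %s",
          paste(utils::head(scored_lethal, 3L), collapse = ", "))
  }

  structure(df, scale = scale, lethal_lines = unique(as.character(lethal_lines)),
            categories = categories,
            class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  sc <- attr(x, "scale")
  cat(sprintf("<score_table> %d rows | %d lines | %d genes | scale [%d, %d] | %d lethal lines\n",
              nrow(x), length(unique(x$line_id)), length(unique(x$gene_id)),
              sc[1L], sc[2L], length(attr(x, "lethal_lines"))))
  invisible(x)
}

#' Read a score database from TSV
#'
#' Expects columns `line_id gene_id animal_id scorer_id category score lethal`.
#' Rows with `lethal` true declare lethal lines (their `score` may be empty);
#' alternatively pass a sidecar file with one lethal line id per line.
#'
#' @param path TSV file.
#' @param scale ordinal bounds, see [score_table()].
#' @param lethal_file optional sidecar text file of lethal line ids.
#' @param categories category registry.
#' @return validated `score_table`; per-line animal counts are attached as
#'   attribute `n_animals`.
#' @export
read_scores <- function(path, scale = c(-2L, 2L), lethal_file = NULL,
                        categories = default_categories()) {
  df <- read_tsv_checked(path, required = c("line_id", "gene_id", "animal_id",
                                            "scorer_id", "category", "score"))
  lethal <- character()
  if ("lethal" %in% names(df)) {
    flag <- as.logical(df$lethal)
    flag[is.na(flag)] <- FALSE
    lethal <- unique(df$line_id[flag])
    df <- df[!flag, , drop = FALSE]
  }
  if (!is.null(lethal_file)) {
    lethal <- union(lethal, readLines(lethal_file, warn = FALSE))
    lethal <- lethal[nzchar(lethal)]
  }
  tab <- score_table(df, scale = scale, lethal_lines = lethal,
                     categories = categories)
  counts <- tapply(tab$animal_id, tab$line_id,
                   function(a) length(unique(a)))
  attr(tab, "n_animals") <- counts
  tab
}

#' Write a score database to TSV
#'
#' Inverse of [read_scores()]: score rows get `lethal = FALSE`, and each lethal
#' line is written as a single row with empty animal/scorer/category fields and
#' `lethal = TRUE`.
#'
#' @param table a `score_table`.
#' @param path output TSV path.
#' @export
write_scores <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  df <- as.data.frame(table)
  df$lethal <- FALSE
  lethal <- attr(table, "lethal_lines")
  if (length(lethal)) {
    extra <- data.frame(line_id = lethal, gene_id = "", animal_id = "",
                        scorer_id = "", category = "", score = NA_integer_,
                        lethal = TRUE, stringsAsFactors = FALSE)
    df <- rbind(df, extra)
  }
  write_tsv(df, path)
}

#' Aggregate a score table to per-line mean scores
#'
#' One matrix cell per RNAi line and category: the arithmetic mean over all
#' animals and both scorers (equal weight; use `scorer_first = TRUE` for the
#' two-stage mean that first averages within scorer). Category cells never
#' scored for a line are 0-filled -- a 0 means "no deviation from baseline
#' recorded" -- and flagged in the `filled` attribute.
#'
#' @param table a `score_table`.
#' @param min_animals declared minimum animals per line; lines below it trigger
#'   a warning, not an error.
#' @param scorer_first average within scorer before across scorers.
#' @return a `line_score_matrix`: numeric matrix (lines x categories) with
#'   attributes `gene_map` (named character, line -> gene), `n_animals`,
#'   `filled` (logical matrix), `scale`.
#' @export
aggregate_scores <- function(table, min_animals = 5L, scorer_first = FALSE) {
  stopifnot(inherits(table, "score_table"))
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  categories <- attr(table, "categories")
  lines <- sort(unique(table$line_id))

  li <- match(table$line_id, lines)
  ci <- match(table$category, categories)
  nl <- length(lines); nc <- length(categories)
  accumulate <- function(values, li, ci) {
    idx <- (ci - 1L) * nl + li
    s <- rowsum(as.numeric(values), idx)
    n <- rowsum(rep(1, length(values)), idx)
    sums <- counts <- matrix(0, nl, nc)
    at <- as.integer(rownames(s))
    sums[at] <- s
    counts[at] <- n
    list(sums = sums, counts = counts)
  }
  if (scorer_first) {
    k <- paste(li, ci, match(table$scorer_id, unique(table$scorer_id)),
               sep = "\r")
    per_scorer <- rowsum(as.numeric(table$score), k) /
      as.vector(rowsum(rep(1, nrow(table)), k))
    # rowsum orders groups by sorted key; recover (line, category) per key
    keys <- sort(unique(k))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    acc <- accumulate(per_scorer[, 1L],
                      as.integer(vapply(parts, `[[`, "", 1L)),
                      as.integer(vapply(parts, `[[`, "", 2L)))
  } else {
    acc <- accumulate(table$score, li, ci)
  }
  counts <- acc$counts
  m <- ifelse(counts > 0, acc$sums / pmax(counts, 1), 0)
  dimnames(m) <- list(lines, categories)
  filled <- counts == 0
  dimnames(filled) <- dimnames(m)

  gene_map <- vapply(split(table$gene_id, table$line_id),
                     function(g) g[[1L]], "")
  gene_map <- gene_map[lines]
  n_animals <- vapply(split(table$animal_id, table$line_id),
                      function(a) length(unique(a)), 0L)[lines]
  low <- names(n_animals)[n_animals < min_animals]
  if (length(low)) {
    warning(sprintf("%d line(s) below the declared minimum of %d animals (e.g. %s)",
                    length(low), min_animals, low[1L]), call. = FALSE)
  }
  line_score_matrix(m, gene_map = gene_map, n_animals = n_animals,
                    scale = attr(table, "scale"), filled = filled)
}

#' Construct a line-score matrix
#'
#' @param m numeric matrix, lines as rows, categories as columns.
#' @param gene_map named character vector mapping line id to gene id; defaults
#'   to the identity (rownames).
#' @param n_animals named integer vector of animals per line.
#' @param scale ordinal bounds the means must respect (NULL to skip the check).
#' @param filled logical matrix flagging 0-filled cells.
#' @export
line_score_matrix <- function(m, gene_map = NULL, n_animals = NULL,
                              scale = NULL, filled = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%04d", seq_len(nrow(m)))
  if (is.null(gene_map)) {
    gene_map <- stats::setNames(rownames(m), rownames(m))
  }
  if (!is.null(scale)) {
    scale <- check_scale(scale)
    if (any(m < scale[1L] - 1e-9) || any(m > scale[2L] + 1e-9)) {
      stop("line means outside the declared ordinal scale", call. = FALSE)
    }
  }
  structure(m, gene_map = gene_map, n_animals = n_animals, scale = scale,
            filled = filled, class = c("line_score_matrix", "matrix", "array"))
}

#' Line-to-gene map of a line-score matrix
#' @param m a `line_score_matrix` (or plain matrix: identity map on rownames).
#' @return named character vector, line id -> gene id.
#' @export
line_genes <- function(m) {
  gm <- attr(m, "gene_map")
  if (is.null(gm)) gm <- stats::setNames(rownames(m), rownames(m))
  gm[rownames(m)]
}

#' @export
print.line_score_matrix <- function(x, ...) {
  cat(sprintf("<line_score_matrix> %d lines x %d categories\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Roll line-level scores up to gene level
#'
#' Hits are counted as RNAi lines but networks and enrichment work on genes.
#' `mean` averages a gene's lines per category; `best-line` keeps, per
#' category, the value of the line with the largest absolute score.
#'
#' @param matrix a `line_score_matrix` (or plain matrix with a gene map).
#' @param rule `"mean"` or `"best-line"`.
#' @return numeric matrix, genes x categories.
#' @export
gene_level <- function(matrix, rule = c("mean", "best-line")) {
  rule <- match.arg(rule)
  gm <- line_genes(matrix)
  if (anyNA(gm)) stop("line -> gene map does not cover all rows", call. = FALSE)
  genes <- sort(unique(gm))
  out <- base::matrix(0, length(genes), ncol(matrix),
                      dimnames = list(genes, colnames(matrix)))
  for (g in genes) {
    rows <- matrix[gm == g, , drop = FALSE]
    out[g, ] <- if (rule == "mean") {
      colMeans(rows)
    } else {
      rows[cbind(max.col(t(abs(rows)), ties.method = "first"),
                 seq_len(ncol(rows)))]
    }
  }
  out
}
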