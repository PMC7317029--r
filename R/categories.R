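#' The default phenotype-category registry
#'
#' The screen scores each animal across 33 ordinal phenotype categories, each
#' describing one aspect of clonal tumor behaviour relative to the sensitized
#' baseline (clone geometry, epithelial architecture, cytoskeleton, mitosis,
#' invasion, and adult cuticle read-outs). Only part of the published category
#' list is recoverable from text, so the registry ships these 33 working names
#' and is user-extensible: every function that consumes categories accepts a
#' `categories` argument.
#'
#' @return character vector of 33 category names.
#' @export
#' @examples
#' length(default_categories())
default_categories <- function() {
  c("clone size", "clone shape", "clone dispersal", "clone integrity",
    "invasion", "invasion depth", "multilayering", "cell body rounding",
    "cell size", "cell shape", "apex size", "apex defects",
    "apical constriction", "basal protrusions", "junction defects",
    "junction fragmentation", "adherens junction intensity",
    "septate junction defects", "actin organization", "actin accumulation",
    "cortical actin loss", "microtubule defects", "number of dividing cells",
    "mitotic orientation", "nuclear position", "nuclear size", "cell death",
    "delamination", "basement membrane defects", "tissue folding",
    "bristle defects", "cuticle defects", "pigmentation defects")
}

# Category names used when a generator is asked for an arbitrary number of
# categories: the default registry when it fits, generic labels otherwise.
category_names <- function(n_categories) {
  reg <- default_categories()
  if (n_categories <= length(reg)) reg[seq_len(n_categories)]
  else c(reg, sprintf("cat%02d", seq.int(length(reg) + 1L, n_categories)))
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 2L || any(is.na(scale)) ||
      any(scale != trunc(scale))) {
    stop("`scale` must be two integers (min, max)", call. = FALSE)
  }
  scale <- as.integer(scale)
  if (!(scale[1L] < 0 && 0 < scale[2L])) {
    stop("ordinal `scale` must satisfy min < 0 < max (0 = baseline)",
         call. = FALSE)
  }
  scale
}
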