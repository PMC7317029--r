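# Invading-cell trajectory metrics: path length, displacement, speed,
# straightness, directionality verdicts, group speed comparisons, and the
# polarized-actin / invasion correlation.

#' Per-track trajectory statistics
#'
#' For each track: path length (sum of 3-D segment norms), displacement
#' (straight line from first to last point), speed (length / elapsed time)
#' and straightness (displacement / length, in `[0, 1]`). 2-D tracks are
#' accepted by zero-filling `z_um`. A track that never moves has undefined
#' straightness (`NA`, flagged), not an error; non-increasing time stamps are
#' an error.
#'
#' @param tracks data.frame with columns `track_id, t_min, x_um, y_um` and
#'   optionally `z_um`, `genotype`, `n_actin_spots`, or the `tracks` element
#'   of [gen_tracks()].
#' @return data.frame of class `track_stats`: one row per track with
#'   `length_um, displacement_um, speed_um_min, straightness, n_samples,
#'   degenerate` plus any grouping columns present.
#' @export
track_stats <- function(tracks) {
  if (is.list(tracks) && !is.data.frame(tracks) && !is.null(tracks$tracks)) {
    tracks <- tracks$tracks
  }
  need <- c("track_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stopf("track table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"z_um" %in% names(tracks)) tracks$z_um <- 0
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < 2L) stopf("track %s: needs >= 2 samples", tr$track_id[1L])
    if (any(diff(tr$t_min) <= 0)) {
      stopf("track %s: time stamps must be strictly increasing",
            tr$track_id[1L])
    }
    seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    len <- sum(seg)
    disp <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1L])^2 +
                   (tr$y_um[nrow(tr)] - tr$y_um[1L])^2 +
                   (tr$z_um[nrow(tr)] - tr$z_um[1L])^2)
    elapsed <- tr$t_min[nrow(tr)] - tr$t_min[1L]
    out <- data.frame(
      track_id = tr$track_id[1L],
      length_um = len, displacement_um = disp,
      speed_um_min = len / elapsed,
      straightness = if (len > 0) disp / len else NA_real_,
      n_samples = nrow(tr), degenerate = len == 0,
      stringsAsFactors = FALSE)
    for (extra in c("genotype", "n_actin_spots")) {
      if (extra %in% names(tr)) out[[extra]] <- tr[[extra]][1L]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("track_stats", "data.frame")
  out
}

#' Directionality verdict for a group of tracks
#'
#' Directional migration shows no significant difference between path length
#' and displacement. The default verdict is the inverse of a paired two-sided
#' t-test of length vs displacement across cells (directional when
#' `p >= alpha`) -- note this is an inverse test and is flagged as such. A
#' TOST equivalence mode (`margin_um` equivalence band on the mean
#' difference) and a plain straightness-threshold mode are provided.
#'
#' @param stats a `track_stats` data.frame (>= 3 tracks).
#' @param alpha significance level.
#' @param method `"paired-t"`, `"tost"` or `"straightness"`.
#' @param margin_um equivalence margin for TOST; defaults to 25% of the mean
#'   path length.
#' @param straightness_min threshold for the straightness mode.
#' @return list: `verdict` ("directional"/"non-directional"), `p`,
#'   `mean_length`, `mean_displacement`, `mean_straightness`, `n`, `method`,
#'   `inverse_test`.
#' @export
directionality_test <- function(stats, alpha = 0.05,
                                method = c("paired-t", "tost",
                                           "straightness"),
                                margin_um = NULL, straightness_min = 0.6) {
  method <- match.arg(method)
  if (nrow(stats) < 3L) stop("need >= 3 tracks", call. = FALSE)
  len <- stats$length_um
  disp <- stats$displacement_um
  d <- len - disp
  ms <- mean(stats$straightness, na.rm = TRUE)
  inverse <- FALSE
  if (method == "straightness") {
    verdict <- if (ms >= straightness_min) "directional" else "non-directional"
    p <- NA_real_
  } else if (method == "paired-t") {
    inverse <- TRUE
    p <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else {
      safe_t_p(len, disp, paired = TRUE)
    }
    verdict <- if (p >= alpha) "directional" else "non-directional"
  } else {
    if (is.null(margin_um)) margin_um <- 0.25 * mean(len)
    if (stats::sd(d) == 0) {
      p <- if (all(abs(d) < margin_um)) 0 else 1
    } else {
      se <- stats::sd(d) / sqrt(length(d))
      df <- length(d) - 1L
      p_lo <- stats::pt((mean(d) + margin_um) / se, df, lower.tail = FALSE)
      p_hi <- stats::pt((mean(d) - margin_um) / se, df)
      p <- max(p_lo, p_hi)  # TOST: both one-sided tests must reject
    }
    verdict <- if (p < alpha) "directional" else "non-directional"
  }
  list(verdict = verdict, p = p, mean_length = mean(len),
       mean_displacement = mean(disp), mean_straightness = ms,
       n = nrow(stats), method = method, inverse_test = inverse)
}

#' Per-group migration speed with two-group comparison
#'
#' Mean +/- SEM of per-cell speed by genotype or by actin-spot class (a
#' single spot vs multiple dynamic spots). With two groups a two-sided
#' Welch t-test and the fold change of means (first over second group, in
#' the grouping's level order) are reported; with more groups, one-way
#' ANOVA.
#'
#' @param stats a `track_stats` data.frame.
#' @param grouping `"genotype"` or `"n_actin_spots"`.
#' @return list: `groups` (data.frame `group, n, mean_speed, sem`),
#'   `fold_change` (two groups only), `p`, `test`.
#' @export
group_speed <- function(stats, grouping = c("genotype", "n_actin_spots")) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(stats)) {
    stopf("`stats` has no '%s' column", grouping)
  }
  grp <- if (grouping == "n_actin_spots") {
    factor(ifelse(stats$n_actin_spots > 1, "multiple", "single"),
           levels = c("multiple", "single"))
  } else {
    factor(stats$genotype, levels = unique(stats$genotype))
  }
  grp <- droplevels(grp)
  sizes <- table(grp)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stopf("group '%s' has fewer than 2 tracks",
          names(sizes)[which(sizes < 2L)[1L]])
  }
  sp <- split(stats$speed_um_min, grp)
  groups <- data.frame(
    group = names(sp), n = lengths(sp),
    mean_speed = vapply(sp, mean, 0),
    sem = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(sp) == 2L) {
    p <- safe_t_p(sp[[1L]], sp[[2L]])
    list(groups = groups, fold_change = groups$mean_speed[1L] /
           groups$mean_speed[2L], p = p, test = "welch-t")
  } else {
    fit <- stats::oneway.test(speed ~ g,
                              data = data.frame(speed = stats$speed_um_min,
                                                g = grp))
    list(groups = groups, fold_change = NA_real_, p = fit$p.value,
         test = "anova")
  }
}

#' Correlation between polarized-actin and invasion fractions
#'
#' Per-animal percentages of clonal cells with polarized actin accumulation
#' vs percentages of invading cells: midrank Spearman rho, its square (the
#' rank-based coefficient of determination), and the two-sided p-value.
#'
#' @param pct_polarized,pct_invading paired per-animal percentages (>= 3).
#' @return list: `rho`, `r_s2`, `p`, `n`, `degenerate`.
#' @export
spot_invasion_correlation <- function(pct_polarized, pct_invading) {
  if (length(pct_polarized) < 3L) stop("need >= 3 animals", call. = FALSE)
  s <- spearman_midrank(pct_polarized, pct_invading)
  list(rho = s$rho, r_s2 = s$rho2, p = s$p, n = s$n,
       degenerate = s$degenerate)
}

#' Read a track table from CSV
#'
#' Expects `track_id,genotype,t_min,x_um,y_um,z_um[,n_actin_spots]`; `z_um`
#' may be absent for 2-D tracks.
#'
#' @param path CSV path.
#' @export
read_tracks <- function(path) {
  read_tsv_checked(path, required = c("track_id", "t_min", "x_um", "y_um"),
                   sep = ",")
}

#' Write a track table to CSV
#' @param tracks track data.frame (or [gen_tracks()] output).
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  if (is.list(tracks) && !is.data.frame(tracks) && !is.null(tracks$tracks)) {
    tracks <- tracks$tracks
  }
  utils::write.table(tracks, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
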