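# Seeded generators for every input the pipeline consumes, with ground truth.
#
# The score generator uses a continuous Gaussian latent per animal, shared by
# both blinded scorers, discretized to the ordinal scale by round-and-clip.
# Tracks use a persistent random walk; the interactome plants vertex-disjoint
# dense complexes among hit genes; expression plants signed log2 fold changes.

#' Simulate the phenotype score database
#'
#' Emulates the screen's structure: `n_genes` genes covered by one or two
#' independent RNAi lines, each line scored in `n_categories` ordinal
#' categories for `n_animals` animals by `n_scorers` blinded scorers. A
#' fraction `frac_hits` of genes per category receives a planted latent effect
#' of magnitude `effect_size` with random sign (an enhancer or suppressor for
#' that category); both lines of a gene share its effects. Each score is
#' `round(effect + animal noise + scorer noise)` clipped to `scale`.
#'
#' @param n_genes number of genes (screen scale: 497).
#' @param frac_two_lines fraction of genes covered by two independent lines
#'   (screen scale: 256/497).
#' @param n_categories number of phenotype categories (default 33).
#' @param n_animals animals scored per line (minimum five in the screen).
#' @param effect_size latent effect magnitude of planted hits.
#' @param scorer_sd per-scorer Gaussian noise SD.
#' @param seed integer seed.
#' @param animal_sd per-animal Gaussian noise SD (defaults to `scorer_sd`).
#' @param frac_hits per-category fraction of genes planted as hits.
#' @param frac_lethal fraction of genes whose lines are lethal (no scores).
#' @param n_scorers blinded scorers per animal.
#' @param scale ordinal score bounds.
#' @return list with `table` (a [score_table()]) and `truth`, a `screen_truth`
#'   list: `gene_effects` (gene x category signed effects), `lethal_genes`,
#'   `pair_map` (gene -> line ids), `seed`.
#' @export
gen_score_db <- function(n_genes = 497, frac_two_lines = 256 / 497,
                         n_categories = 33, n_animals = 5,
                         effect_size = 1.2, scorer_sd = 0.3, seed = 1,
                         animal_sd = scorer_sd, frac_hits = 0.05,
                         frac_lethal = 0, n_scorers = 2,
                         scale = c(-2L, 2L)) {
  n_genes <- check_count(n_genes, "n_genes")
  n_categories <- check_count(n_categories, "n_categories")
  n_animals <- check_count(n_animals, "n_animals")
  n_scorers <- check_count(n_scorers, "n_scorers")
  check_proportion(frac_two_lines, "frac_two_lines")
  check_proportion(frac_hits, "frac_hits")
  check_proportion(frac_lethal, "frac_lethal")
  if (scorer_sd < 0 || animal_sd < 0) stop("noise SDs must be >= 0",
                                           call. = FALSE)
  scale <- check_scale(scale)
  categories <- category_names(n_categories)

  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    two <- sort(sample.int(n_genes, round(frac_two_lines * n_genes)))
    n_lines_per <- rep(1L, n_genes)
    n_lines_per[two] <- 2L
    pair_map <- lapply(seq_len(n_genes), function(i) {
      sprintf("%s_L%d", genes[i], seq_len(n_lines_per[i]))
    })
    names(pair_map) <- genes

    lethal_idx <- sort(sample.int(n_genes, round(frac_lethal * n_genes)))
    lethal_genes <- genes[lethal_idx]
    lethal_lines <- unlist(pair_map[lethal_genes], use.names = FALSE)
    if (is.null(lethal_lines)) lethal_lines <- character()

    effects <- matrix(0, n_genes, n_categories,
                      dimnames = list(genes, categories))
    n_hit <- round(frac_hits * n_genes)
    for (c_ in seq_len(n_categories)) {
      who <- sample.int(n_genes, n_hit)
      effects[who, c_] <- effect_size * sample(c(-1, 1), n_hit, replace = TRUE)
    }
    effects[lethal_idx, ] <- 0  # lethal genes generate no scores

    scored <- setdiff(seq_len(n_genes), lethal_idx)
    line_id <- unlist(pair_map[scored], use.names = FALSE)
    line_gene <- rep(genes[scored], n_lines_per[scored])
    nl <- length(line_id)

    # latent per (line, animal, category): gene effect + animal noise
    n_lac <- nl * n_animals * n_categories
    eff <- effects[line_gene, , drop = FALSE]  # nl x ncat
    lat <- rep(as.vector(eff), each = n_animals) +
      stats::rnorm(n_lac, 0, animal_sd)
    # expand to scorers: shared animal latent, independent scorer noise
    obs <- rep(lat, times = n_scorers) +
      stats::rnorm(n_lac * n_scorers, 0, scorer_sd)
    score <- pmin(pmax(round(obs), scale[1L]), scale[2L])

    rows <- data.frame(
      line_id = rep(rep(line_id, each = n_animals), times = n_categories * n_scorers),
      gene_id = rep(rep(line_gene, each = n_animals), times = n_categories * n_scorers),
      animal_id = rep(sprintf("a%d", seq_len(n_animals)),
                      times = nl * n_categories * n_scorers),
      scorer_id = rep(sprintf("scorer%d", seq_len(n_scorers)),
                      each = n_lac),
      category = rep(rep(categories, each = nl * n_animals), times = n_scorers),
      score = as.integer(score),
      stringsAsFactors = FALSE
    )
    tab <- score_table(rows, scale = scale, lethal_lines = lethal_lines,
                       categories = categories)
    truth <- structure(
      list(gene_effects = effects, lethal_genes = lethal_genes,
           pair_map = pair_map, seed = seed, effect_size = effect_size),
      class = "screen_truth")
    list(table = tab, truth = truth)
  })
}

#' Planted hits of a simulated screen
#'
#' @param truth `screen_truth` from [gen_score_db()].
#' @return data.frame `gene_id`, `category`, `direction`
#'   (enhancer = positive planted effect).
#' @export
truth_hits <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  idx <- which(truth$gene_effects != 0, arr.ind = TRUE)
  data.frame(
    gene_id = rownames(truth$gene_effects)[idx[, 1L]],
    category = colnames(truth$gene_effects)[idx[, 2L]],
    direction = ifelse(truth$gene_effects[idx] > 0, "enhancer", "suppressor"),
    stringsAsFactors = FALSE
  )
}

#' Simulate single-cell invasion tracks
#'
#' Persistent random walk in 3-D: the direction vector is updated as the
#' normalized blend `p * previous + (1 - p) * random unit vector`, so
#' `persistence = 1` gives a straight line and `persistence = 0` an
#' uncorrelated random walk. Cells are sampled every `dt_min` minutes for
#' `duration_min` minutes at constant speed. Directional cells are given
#' multiple actin-rich spots, random cells a single spot, mirroring the
#' observed association between polarized actin and directional migration.
#'
#' @param n_directional,n_random number of tracks of each class.
#' @param dt_min sampling interval (minutes).
#' @param duration_min track duration; must be divisible by `dt_min`.
#' @param speed_um_min constant cell speed (micrometres per minute).
#' @param persistence directional-class persistence in `[0, 1]`; the random
#'   class always uses 0.
#' @param seed integer seed.
#' @return list with `tracks` (data.frame `track_id, genotype, t_min, x_um,
#'   y_um, z_um, n_actin_spots`) and `truth` (per-track data.frame).
#' @export
gen_tracks <- function(n_directional, n_random, dt_min = 3, duration_min = 30,
                       speed_um_min = 1, persistence = 0.9, seed = 1) {
  n_directional <- check_count(n_directional, "n_directional", min = 0L)
  n_random <- check_count(n_random, "n_random", min = 0L)
  if (speed_um_min < 0) stop("`speed_um_min` must be >= 0", call. = FALSE)
  check_proportion(persistence, "persistence")
  if (dt_min <= 0 || duration_min <= 0 ||
      abs(duration_min / dt_min - round(duration_min / dt_min)) > 1e-9) {
    stop("`duration_min` must be a positive multiple of `dt_min`",
         call. = FALSE)
  }
  n_steps <- as.integer(round(duration_min / dt_min))
  n <- n_directional + n_random
  directional <- rep(c(TRUE, FALSE), c(n_directional, n_random))

  with_seed(seed, {
    ids <- sprintf("T%05d", seq_len(n))
    n_spots <- ifelse(directional, sample(2:4, n, replace = TRUE), 1L)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      p <- if (directional[i]) persistence else 0
      u <- matrix(stats::rnorm(3 * (n_steps + 1L)), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      d <- matrix(0, n_steps, 3L)
      v <- u[1L, ]
      for (s in seq_len(n_steps)) {
        if (s > 1L) {
          v <- p * v + (1 - p) * u[s + 1L, ]
          v <- v / sqrt(sum(v^2))
        }
        d[s, ] <- v
      }
      pos <- rbind(c(0, 0, 0), apply(d * speed_um_min * dt_min, 2L, cumsum))
      res[[i]] <- data.frame(
        track_id = ids[i],
        genotype = if (directional[i]) "directional" else "random",
        t_min = seq.int(0L, n_steps) * dt_min,
        x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
        n_actin_spots = n_spots[i],
        stringsAsFactors = FALSE
      )
    }
    tracks <- do.call(rbind, res)
    truth <- data.frame(track_id = ids, directional = directional,
                        n_spots = n_spots, speed_um_min = speed_um_min,
                        stringsAsFactors = FALSE)
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a typed interaction edge table with planted complexes
#'
#' Plants vertex-disjoint dense subgraphs among hit genes (each with at least
#' the requested edge density), wires each planted linker (a non-hit gene) to
#' two or three hit genes, and adds independent background edges among all
#' nodes with probability `p_background`. Edge evidence types are sampled
#' uniformly from genetic / physical / interolog.
#'
#' @param hit_genes character vector of hit gene ids.
#' @param lethal_genes character vector of lethal gene ids.
#' @param background_genes number of extra background genes.
#' @param planted_complexes list of `c(size, density)` pairs; sizes >= 3,
#'   densities in (0, 1].
#' @param p_background background edge probability.
#' @param n_linkers number of planted linker genes.
#' @param seed integer seed.
#' @return list with `edges` (data.frame `gene_a, gene_b, type, source`) and
#'   `truth` (list: `complexes`, `linkers`, `background`).
#' @export
gen_interactome <- function(hit_genes, lethal_genes = character(),
                            background_genes = 0, planted_complexes = list(),
                            p_background = 0.01, n_linkers = 0, seed = 1) {
  hit_genes <- unique(as.character(hit_genes))
  background_genes <- check_count(background_genes, "background_genes", 0L)
  n_linkers <- check_count(n_linkers, "n_linkers", 0L)
  check_proportion(p_background, "p_background")
  sizes <- vapply(planted_complexes, function(x) as.numeric(x[[1L]]), 0)
  dens <- vapply(planted_complexes, function(x) as.numeric(x[[2L]]), 0)
  if (any(sizes < 3)) stop("planted complex sizes must be >= 3", call. = FALSE)
  if (any(dens <= 0 | dens > 1)) stop("densities must be in (0, 1]",
                                      call. = FALSE)
  if (sum(sizes) > length(hit_genes)) {
    stop("planted complex sizes exceed the number of hit genes",
         call. = FALSE)
  }

  with_seed(seed, {
    pool <- sample(hit_genes)  # random disjoint assignment
    complexes <- list()
    edges <- list()
    at <- 0L
    for (i in seq_along(sizes)) {
      members <- sort(pool[at + seq_len(sizes[i])])
      at <- at + sizes[i]
      complexes[[i]] <- members
      pairs <- t(utils::combn(members, 2L))
      keep <- sample.int(nrow(pairs), ceiling(dens[i] * nrow(pairs)))
      edges[[length(edges) + 1L]] <- pairs[sort(keep), , drop = FALSE]
    }
    linkers <- if (n_linkers > 0) sprintf("linker%02d", seq_len(n_linkers))
               else character()
    for (l in linkers) {
      k <- sample(2:min(3L, length(hit_genes)), 1L)
      edges[[length(edges) + 1L]] <- cbind(l, sample(hit_genes, k))
    }
    backg <- if (background_genes > 0) sprintf("bg%04d",
                                               seq_len(background_genes))
             else character()
    nodes <- c(hit_genes, setdiff(lethal_genes, hit_genes), linkers, backg)
    if (p_background > 0 && length(nodes) >= 2L) {
      pairs <- t(utils::combn(nodes, 2L))
      pick <- stats::runif(nrow(pairs)) < p_background
      if (any(pick)) edges[[length(edges) + 1L]] <- pairs[pick, , drop = FALSE]
    }
    em <- do.call(rbind, edges)
    if (is.null(em)) em <- matrix(character(), 0L, 2L)
    a <- pmin(em[, 1L], em[, 2L]); b <- pmax(em[, 1L], em[, 2L])
    keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
    df <- data.frame(
      gene_a = a[keep], gene_b = b[keep],
      type = sample(c("genetic", "physical", "interolog"), sum(keep),
                    replace = TRUE),
      source = "synthetic", stringsAsFactors = FALSE)
    list(edges = df,
         truth = list(complexes = complexes, linkers = linkers,
                      background = backg, seed = seed))
  })
}

#' Simulate a log2 expression matrix with planted differential expression
#'
#' Three conditions (knockdown plus two controls, mirroring an untreated and a
#' non-targeting control) with `n_per_group` samples each. Gene baselines are
#' Gaussian log2 intensities; `n_de` planted genes are shifted by
#' `log2(fc)` with random sign in the knockdown condition only.
#'
#' @param n_genes number of genes (platform scale: 21,448).
#' @param n_per_group samples per condition (>= 2).
#' @param n_de number of planted DE genes.
#' @param fc planted linear fold change (>= 1; `fc = 1` plants nothing).
#' @param sd_log2 per-sample residual SD on the log2 scale.
#' @param seed integer seed.
#' @param conditions condition labels; the first is the knockdown.
#' @param baseline_mean,baseline_sd gene baseline distribution (log2).
#' @return list with `expr` (genes x samples log2 matrix), `samples`
#'   (data.frame `sample, condition`), `truth` (data.frame `gene, sign`).
#' @export
gen_expression <- function(n_genes, n_per_group, n_de, fc, sd_log2 = 0.25,
                           seed = 1, conditions = c("kd", "unt", "nonT"),
                           baseline_mean = 8, baseline_sd = 1.5) {
  n_genes <- check_count(n_genes, "n_genes")
  n_per_group <- check_count(n_per_group, "n_per_group", 2L)
  n_de <- check_count(n_de, "n_de", 0L)
  if (n_de > n_genes) stop("`n_de` must be <= `n_genes`", call. = FALSE)
  if (!is.numeric(fc) || fc < 1) stop("`fc` must be >= 1", call. = FALSE)
  if (sd_log2 < 0) stop("`sd_log2` must be >= 0", call. = FALSE)

  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    samples <- data.frame(
      sample = paste0(rep(conditions, each = n_per_group), "_",
                      rep(seq_len(n_per_group), length(conditions))),
      condition = rep(conditions, each = n_per_group),
      stringsAsFactors = FALSE)
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    expr <- base + matrix(stats::rnorm(n_genes * nrow(samples), 0, sd_log2),
                          n_genes, nrow(samples))
    dimnames(expr) <- list(genes, samples$sample)
    de <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
    sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric()
    kd_cols <- samples$condition == conditions[1L]
    if (n_de > 0 && fc > 1) {
      expr[de, kd_cols] <- expr[de, kd_cols] + sign * log2(fc)
    }
    list(expr = expr, samples = samples,
         truth = data.frame(gene = genes[de], sign = sign,
                            stringsAsFactors = FALSE))
  })
}
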