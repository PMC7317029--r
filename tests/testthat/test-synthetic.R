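# synthetic_data module: seeded generators and their ground truth.

test_that("gen_score_db reproduces the screen's structure", {
  sim <- gen_score_db(n_genes = 497, frac_two_lines = 256 / 497,
                      n_categories = 33, n_animals = 5, seed = 11)
  tab <- sim$table
  lines <- unique(tab$line_id)
  expect_gte(length(lines), 753)
  expect_lte(length(lines), 764)
  expect_equal(length(unique(tab$gene_id)), 497)
  expect_equal(length(unique(tab$category)), 33)
  # each line: >= 5 animals x 2 scorers
  per_line <- table(tab$line_id, tab$scorer_id)
  expect_true(all(per_line >= 5))
  counts <- tapply(tab$animal_id, tab$line_id, function(a) length(unique(a)))
  expect_true(all(counts >= 5))
  # 256 genes by two lines
  two <- sum(lengths(sim$truth$pair_map) == 2)
  expect_equal(two, 256)
  # every line under exactly one gene
  all_lines <- unlist(sim$truth$pair_map)
  expect_false(any(duplicated(all_lines)))
})

test_that("gen_score_db trivial cases and determinism", {
  zero <- gen_score_db(n_genes = 10, frac_two_lines = 0.5, n_categories = 4,
                       n_animals = 3, effect_size = 0, scorer_sd = 0,
                       seed = 1)
  expect_true(all(zero$table$score == 0L))

  a <- gen_score_db(n_genes = 15, frac_two_lines = 0.4, n_categories = 5,
                    n_animals = 3, seed = 7)
  b <- gen_score_db(n_genes = 15, frac_two_lines = 0.4, n_categories = 5,
                    n_animals = 3, seed = 7)
  c_ <- gen_score_db(n_genes = 15, frac_two_lines = 0.4, n_categories = 5,
                     n_animals = 3, seed = 8)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$gene_effects, b$truth$gene_effects)
  expect_false(identical(a$table$score, c_$table$score))

  expect_error(gen_score_db(n_genes = 0, frac_two_lines = 0, seed = 1),
               "n_genes")
  expect_error(gen_score_db(n_genes = 5, frac_two_lines = 0,
                            n_animals = 0, seed = 1), "n_animals")
})

test_that("lethal genes generate no scores but are tracked", {
  sim <- gen_score_db(n_genes = 40, frac_two_lines = 0.5, n_categories = 4,
                      n_animals = 3, frac_lethal = 0.2, seed = 3)
  lethal_lines <- unlist(sim$truth$pair_map[sim$truth$lethal_genes])
  expect_length(sim$truth$lethal_genes, 8)
  expect_false(any(sim$table$line_id %in% lethal_lines))
  expect_setequal(attr(sim$table, "lethal_lines"), lethal_lines)
  expect_true(all(sim$truth$gene_effects[sim$truth$lethal_genes, ] == 0))
})

test_that("gen_tracks geometry: sampling, persistence extremes", {
  sim <- gen_tracks(3, 2, dt_min = 3, duration_min = 30, speed_um_min = 1.2,
                    persistence = 1, seed = 5)
  expect_equal(as.integer(table(sim$tracks$track_id)), rep(11L, 5))
  st <- track_stats(sim$tracks)
  dir <- st[st$genotype == "directional", ]
  expect_equal(dir$straightness, rep(1, 3), tolerance = 1e-12)
  # constant speed: length = speed * duration
  expect_equal(st$length_um, rep(1.2 * 30, 5), tolerance = 1e-9)

  expect_error(gen_tracks(2, 2, speed_um_min = -1, seed = 1), "speed")
  expect_error(gen_tracks(2, 2, dt_min = 4, duration_min = 30, seed = 1),
               "multiple")
  a <- gen_tracks(4, 4, seed = 2)
  b <- gen_tracks(4, 4, seed = 2)
  expect_identical(a, b)
})

test_that("persistence orders straightness (Monte-Carlo)", {
  # scaled down from the spec's n = 10,000: the ordering is already decisive
  # at n = 1,500 tracks per level
  s0 <- track_stats(gen_tracks(0, 1500, persistence = 0, seed = 21)$tracks)
  s9 <- track_stats(gen_tracks(1500, 0, persistence = 0.9, seed = 21)$tracks)
  expect_lt(mean(s0$straightness), mean(s9$straightness))
})

test_that("null screens reproduce the analytic IQR hit fraction on a wide scale", {
  # with effect 0 and a scale wide enough that rounding is immaterial, the
  # per-category hit fraction approaches 2 * (1 - pnorm(2 * qnorm(0.75)))
  sim <- gen_score_db(n_genes = 1000, frac_two_lines = 0, n_categories = 3,
                      n_animals = 5, effect_size = 0, scorer_sd = 2,
                      frac_hits = 0, seed = 37, scale = c(-10L, 10L))
  h <- call_hits(aggregate_scores(sim$table))
  frac <- mean(h$call != "none")
  expect_equal(frac, 2 * (1 - pnorm(2 * qnorm(0.75))), tolerance = 0.02 / 0.177)
})

test_that("gen_interactome closed forms and linker construction", {
  hits <- sprintf("h%02d", 1:12)
  clique <- gen_interactome(hits, planted_complexes = list(c(5, 1)),
                            p_background = 0, seed = 4)
  expect_equal(nrow(clique$edges), 10)
  expect_setequal(unique(c(clique$edges$gene_a, clique$edges$gene_b)),
                  clique$truth$complexes[[1]])

  lk <- gen_interactome(hits, planted_complexes = list(), p_background = 0,
                        n_linkers = 3, seed = 4)
  nodes <- unique(c(lk$edges$gene_a, lk$edges$gene_b))
  non_hits <- setdiff(nodes, hits)
  expect_length(non_hits, 3)
  for (l in non_hits) {
    deg <- sum(lk$edges$gene_a == l | lk$edges$gene_b == l)
    expect_gte(deg, 2)
  }

  expect_error(gen_interactome(hits, planted_complexes = list(c(2, 1)),
                               seed = 1), "sizes")
  expect_error(gen_interactome(hits, planted_complexes = list(c(20, 1)),
                               seed = 1), "exceed")
  expect_error(gen_interactome(hits, planted_complexes = list(c(4, 1.2)),
                               seed = 1), "densities")
})

test_that("gen_expression trivial cases, determinism and validation", {
  none <- gen_expression(50, 3, n_de = 0, fc = 2, seed = 1)
  expect_equal(nrow(none$truth), 0)
  flat <- gen_expression(50, 3, n_de = 5, fc = 1, seed = 1)
  base <- gen_expression(50, 3, n_de = 0, fc = 1, seed = 1)
  expect_identical(flat$expr, base$expr)  # fc = 1 plants nothing

  a <- gen_expression(30, 2, 3, 2, seed = 9)
  expect_identical(a, gen_expression(30, 2, 3, 2, seed = 9))
  expect_equal(dim(a$expr), c(30, 6))
  expect_equal(unique(a$samples$condition), c("kd", "unt", "nonT"))

  expect_error(gen_expression(50, 1, 0, 2, seed = 1), "n_per_group")
  expect_error(gen_expression(50, 3, 60, 2, seed = 1), "n_de")
  expect_error(gen_expression(50, 3, 5, 0.5, seed = 1), "fc")
})
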