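# invasion_network module: subnetwork extraction, MCODE, hubs, bipartite.

toy_edges <- function(...) {
  m <- rbind(...)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
}

test_that("build_network keeps linkers with >= 2 hit neighbours", {
  # h1-x-h2 keeps x as linker; y with one hit neighbour is dropped
  edges <- toy_edges(c("h1", "x"), c("x", "h2"), c("h1", "y"))
  g <- build_network(c("h1", "h2"), character(), edges)
  expect_setequal(igraph::V(g)$name, c("h1", "h2", "x"))
  expect_true(igraph::V(g)$linker[igraph::V(g)$name == "x"])
  cn <- igraph::graph_attr(g, "counts")
  expect_equal(cn$n_linkers, 1)
  expect_equal(cn$n_interactions, 2)

  # no edges among hits -> empty graph
  g0 <- build_network(c("h1", "h2"), character(),
                      toy_edges(c("a", "b")))
  expect_equal(igraph::vcount(g0), 0)

  expect_error(build_network(character(), character(), edges), "empty hit")
  expect_error(build_network(c("h1"), c("h1"), edges), "both hit and lethal")
})

test_that("edge rules: strict drops non-hit-touching edges, induced keeps them", {
  edges <- toy_edges(c("h1", "le1"), c("le1", "le2"), c("h1", "h2"),
                     c("h1", "x"), c("h2", "x"), c("x", "le2"))
  strict <- build_network(c("h1", "h2"), c("le1", "le2"), edges)
  drop <- igraph::graph_attr(strict, "dropped")
  expect_true(all(c("no hit endpoint") %in% drop$reason))
  # lethal-lethal and linker-lethal dropped under strict
  expect_equal(igraph::ecount(strict), 4)
  induced <- build_network(c("h1", "h2"), c("le1", "le2"), edges,
                           rule = "induced")
  expect_equal(igraph::ecount(induced), 6)
  cn <- igraph::graph_attr(strict, "counts")
  expect_equal(cn$n_interactions_induced, 6)
  expect_equal(cn$n_interactions_strict, 4)
})

test_that("build_network is invariant to row order and duplicates", {
  edges <- toy_edges(c("h1", "h2"), c("h2", "h3"), c("h1", "x"),
                     c("x", "h3"))
  edges$type <- c("genetic", "physical", "interolog", "physical")
  g1 <- build_network(paste0("h", 1:3), character(), edges)
  shuf <- rbind(edges[c(3, 1, 4, 2), ], edges[2, ])
  g2 <- build_network(paste0("h", 1:3), character(), shuf)
  el1 <- igraph::as_data_frame(g1)[order(igraph::as_data_frame(g1)$from), ]
  el2 <- igraph::as_data_frame(g2)[order(igraph::as_data_frame(g2)$from), ]
  expect_equal(el1$from, el2$from)
  expect_equal(el1$to, el2$to)
  expect_equal(el1$types, el2$types)
})

test_that("duplicate evidence collapses with display precedence", {
  edges <- data.frame(gene_a = c("h1", "h2", "h1"),
                      gene_b = c("h2", "h1", "h2"),
                      type = c("genetic", "interolog", "physical"))
  g <- build_network(c("h1", "h2"), character(), edges)
  expect_equal(igraph::ecount(g), 1)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$types, "genetic,interolog,physical")
  expect_equal(ed$display_type, "physical")
  expect_error(build_network("h1", character(),
                             data.frame(gene_a = "h1", gene_b = "x",
                                        type = "banana")),
               "unknown evidence")
})

test_that("mcode_weights: hand computations on K5, star, empty", {
  g5 <- igraph::make_full_graph(5)
  igraph::V(g5)$name <- letters[1:5]
  expect_equal(unname(mcode_weights(g5)), rep(4, 5))  # k=4 core, density 1

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("ctr", paste0("l", 1:4))
  w <- mcode_weights(star)
  expect_equal(unname(w["ctr"]), 1 * (4 / 10))  # k=1, density of whole star
  expect_equal(unname(w[paste0("l", 1:4)]), rep(1, 4))

  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("a", "b", "c")
  expect_equal(unname(mcode_weights(lone)), c(0, 0, 0))
})

test_that("mcode_weights equals the exhaustive subset oracle on small graphs", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    g <- adj_to_igraph(adj)
    w <- mcode_weights(g)
    for (v in seq_len(n)) {
      expect_equal(unname(w[v]), oracle_mcode_weight(adj, v),
                   tolerance = 1e-12)
    }
  }
})

test_that("mcode_complexes: K5, bridged K4s, edgeless graph", {
  g5 <- igraph::make_full_graph(5)
  igraph::V(g5)$name <- letters[1:5]
  cx <- mcode_complexes(g5)
  expect_length(cx, 1)
  expect_setequal(cx[[1]]$members, letters[1:5])
  expect_equal(cx[[1]]$density, 1)
  expect_equal(cx[[1]]$score, 5)

  # two K4s joined by one edge: two complexes of 4, whichever end seeds
  ed <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)),
              c("a1", "b1"))
  g <- igraph::graph_from_data_frame(
    data.frame(gene_a = ed[, 1], gene_b = ed[, 2]), directed = FALSE)
  cx2 <- mcode_complexes(g, vwp = 0.2, haircut = TRUE)
  expect_length(cx2, 2)
  sizes <- sort(vapply(cx2, `[[`, 0L, "size"))
  expect_equal(sizes, c(4L, 4L))
  members <- lapply(cx2, `[[`, "members")
  expect_setequal(members[[1]],
                  if ("a1" %in% members[[1]]) paste0("a", 1:4)
                  else paste0("b", 1:4))

  lone <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(lone)$name <- paste0("n", 1:4)
  expect_length(mcode_complexes(lone), 0)

  expect_error(mcode_complexes(g5, vwp = 1.2), "vwp")
})

test_that("planted complexes are recovered exactly over sparse background", {
  hits <- sprintf("h%02d", 1:30)
  sim <- gen_interactome(hits, background_genes = 25,
                         planted_complexes = list(c(6, 1), c(6, 1)),
                         p_background = 0.02, n_linkers = 3, seed = 17)
  g <- igraph::graph_from_data_frame(sim$edges[, 1:2], directed = FALSE)
  cx <- mcode_complexes(g)
  expect_gte(length(cx), 2)
  got <- lapply(cx[1:2], `[[`, "members")
  want <- sim$truth$complexes
  expect_setequal(got[[1]],
                  if (want[[1]][1] %in% got[[1]]) want[[1]] else want[[2]])
  expect_setequal(got[[2]],
                  if (want[[1]][1] %in% got[[2]]) want[[1]] else want[[2]])
  # every reported complex is at least as dense as the graph overall
  overall <- igraph::edge_density(g)
  for (c_ in cx) expect_gte(c_$density, overall)
})

test_that("hubs: star centre, ties, sort oracle", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("ctr", paste0("l", 1:5))
  expect_equal(hubs(star, 1), "ctr")

  two <- igraph::graph_from_data_frame(
    toy_edges(c("b", "x"), c("a", "x")), directed = FALSE)
  expect_equal(hubs(two, 3), c("x", "a", "b"))  # tie broken lexicographically

  set.seed(23)
  adj <- random_adjacency(12, 0.3)
  g <- adj_to_igraph(adj)
  deg <- rowSums(adj)
  names(deg) <- igraph::V(g)$name
  want <- names(deg)[order(-deg, names(deg))][1:5]
  expect_equal(hubs(g, 5), want)

  expect_error(hubs(g, 0), "top_n")
  expect_error(hubs(igraph::make_empty_graph(0)), "empty")
})

test_that("bipartite_count: closed forms and enumeration oracle", {
  none <- bipartite_count(c("a1"), c("b1"), toy_edges(c("a1", "a2")))
  expect_equal(none$n_edges, 0)
  expect_equal(none$n_a, 0)

  # complete bipartite 3 x 4
  A <- paste0("a", 1:3); B <- paste0("b", 1:4)
  kb <- expand.grid(gene_a = A, gene_b = B, stringsAsFactors = FALSE)
  r <- bipartite_count(A, B, kb)
  expect_equal(r$n_edges, 12)
  expect_equal(r$n_a, 3)
  expect_equal(r$n_b, 4)

  set.seed(5)
  genes <- sprintf("g%02d", 1:15)
  ed <- data.frame(gene_a = sample(genes, 40, TRUE),
                   gene_b = sample(genes, 40, TRUE))
  sa <- genes[1:6]; sb <- genes[7:12]
  got <- bipartite_count(sa, sb, ed)
  # brute-force double loop over unique undirected pairs
  seen <- character(); cnt <- 0
  for (i in seq_len(nrow(ed))) {
    a <- min(ed$gene_a[i], ed$gene_b[i]); b <- max(ed$gene_a[i], ed$gene_b[i])
    if (a == b || paste(a, b) %in% seen) next
    seen <- c(seen, paste(a, b))
    if ((a %in% sa && b %in% sb) || (a %in% sb && b %in% sa)) cnt <- cnt + 1
  }
  expect_equal(got$n_edges, cnt)

  sh <- bipartite_count(c("a", "b"), c("b", "c"), toy_edges(c("a", "b")))
  expect_equal(sh$shared, "b")
})

test_that("network exports round-trip node roles", {
  edges <- toy_edges(c("h1", "h2"), c("h1", "x"), c("x", "h2"))
  g <- build_network(c("h1", "h2"), character(), edges)
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(g, ep, np)
  nodes <- read.delim(np)
  expect_setequal(nodes$gene_id, c("h1", "h2", "x"))
  expect_equal(sum(nodes$linker), 1)
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, gp)
  expect_gt(file.size(gp), 0)
})
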