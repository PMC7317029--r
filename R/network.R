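# Invasion-suppressor network: subnetwork extraction around hit genes
# (hits + lethals + one-hop linker genes), MCODE-style molecular-complex
# detection, hubs, and bipartite interaction counts.

EDGE_TYPES <- c("genetic", "physical", "interolog")

# Collapse a raw edge table to unique undirected simple edges carrying the
# set of evidence types; display type uses precedence physical > genetic >
# interolog.
collapse_edges <- function(edges) {
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    stop("edge table needs columns `gene_a` and `gene_b`", call. = FALSE)
  }
  type <- if ("type" %in% names(edges)) as.character(edges$type)
          else rep("physical", nrow(edges))
  bad <- setdiff(unique(type), EDGE_TYPES)
  if (length(bad)) {
    stopf("unknown evidence type(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(EDGE_TYPES, collapse = "/"))
  }
  src <- if ("source" %in% names(edges)) as.character(edges$source)
         else rep(NA_character_, nrow(edges))
  a <- pmin(as.character(edges$gene_a), as.character(edges$gene_b))
  b <- pmax(as.character(edges$gene_a), as.character(edges$gene_b))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; type <- type[keep]; src <- src[keep]
  key <- paste(a, b, sep = "\r")
  types <- vapply(split(type, key), function(t)
    paste(sort(unique(t)), collapse = ","), "")
  sources <- vapply(split(src, key), function(s)
    paste(sort(unique(stats::na.omit(s))), collapse = ","), "")
  parts <- strsplit(names(types), "\r", fixed = TRUE)
  display <- vapply(strsplit(unname(types), ",", fixed = TRUE), function(t) {
    for (pref in c("physical", "genetic", "interolog")) {
      if (pref %in% t) return(pref)
    }
    t[[1L]]
  }, "")
  data.frame(gene_a = vapply(parts, `[[`, "", 1L),
             gene_b = vapply(parts, `[[`, "", 2L),
             types = unname(types), display_type = display,
             source = unname(sources), stringsAsFactors = FALSE)
}

#' Build the invasion-suppressor network
#'
#' Retained nodes are the hit genes, the lethal genes, and every "linker": a
#' non-hit, non-lethal gene adjacent to at least two distinct hit genes (so
#' it connects hits by single interactions). Under the default `"strict"`
#' rule a retained edge must touch at least one hit gene (lethal-lethal,
#' lethal-linker and linker-linker edges are dropped and recorded); the
#' `"induced"` rule keeps every edge among retained nodes. Isolated nodes are
#' dropped. Duplicate evidence rows collapse to one edge carrying the type
#' set.
#'
#' @param hit_genes hit gene ids: a character vector or the data.frame from
#'   [combine_hits()] (its `categories` column becomes a node attribute).
#' @param lethal_genes character vector of lethal gene ids (disjoint from
#'   hits).
#' @param edges edge table with columns `gene_a, gene_b` and optionally
#'   `type` (genetic/physical/interolog) and `source`.
#' @param rule `"strict"` or `"induced"` (see above).
#' @return an [igraph::igraph] with node attributes `hit`, `lethal`,
#'   `linker`, `categories`, edge attributes `types`, `display_type`,
#'   `source`; graph attributes `counts` (node/edge tallies under both rules)
#'   and `dropped` (edge drop log).
#' @export
build_network <- function(hit_genes, lethal_genes = character(), edges,
                          rule = c("strict", "induced")) {
  rule <- match.arg(rule)
  if (is.data.frame(hit_genes)) {
    hit_cats <- stats::setNames(hit_genes$categories, hit_genes$gene_id)
    hit_genes <- hit_genes$gene_id
  } else {
    hit_cats <- stats::setNames(rep(NA_character_, length(hit_genes)),
                                hit_genes)
  }
  hit_genes <- unique(as.character(hit_genes))
  lethal_genes <- unique(as.character(lethal_genes))
  if (!length(hit_genes)) stop("empty hit set", call. = FALSE)
  overlap <- intersect(hit_genes, lethal_genes)
  if (length(overlap)) {
    stopf("gene(s) both hit and lethal: %s", paste(overlap, collapse = ", "))
  }
  ce <- collapse_edges(edges)

  a_hit <- ce$gene_a %in% hit_genes
  b_hit <- ce$gene_b %in% hit_genes
  known <- c(hit_genes, lethal_genes)
  # linkers: non-hit, non-lethal genes with >= 2 distinct hit neighbours
  cand <- c(ce$gene_b[a_hit & !(ce$gene_b %in% known)],
            ce$gene_a[b_hit & !(ce$gene_a %in% known)])
  hit_nb <- c(ce$gene_a[a_hit & !(ce$gene_b %in% known)],
              ce$gene_b[b_hit & !(ce$gene_a %in% known)])
  deg_into_hits <- vapply(split(hit_nb, cand), function(h)
    length(unique(h)), 0L)
  linkers <- names(deg_into_hits)[deg_into_hits >= 2L]

  retained <- c(hit_genes, lethal_genes, linkers)
  both_in <- ce$gene_a %in% retained & ce$gene_b %in% retained
  touches_hit <- a_hit | b_hit
  keep <- if (rule == "strict") both_in & touches_hit else both_in
  dropped <- ce[!keep, c("gene_a", "gene_b")]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(!both_in[!keep], "endpoint not retained",
                             "no hit endpoint")
  } else {
    dropped$reason <- character()
  }
  kept <- ce[keep, , drop = FALSE]

  nodes <- sort(unique(c(kept$gene_a, kept$gene_b)))
  vdf <- data.frame(
    name = nodes,
    hit = nodes %in% hit_genes,
    lethal = nodes %in% lethal_genes,
    linker = nodes %in% linkers,
    categories = unname(hit_cats[nodes]),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(kept, directed = FALSE, vertices = vdf)

  counts <- list(
    n_genes = length(nodes), n_interactions = nrow(kept),
    n_hits = sum(vdf$hit), n_lethals = sum(vdf$lethal),
    n_linkers = sum(vdf$linker),
    n_interactions_induced = sum(both_in),
    n_interactions_strict = sum(both_in & touches_hit),
    rule = rule)
  g <- igraph::set_graph_attr(g, "counts", counts)
  g <- igraph::set_graph_attr(g, "dropped", dropped)
  g
}

#' MCODE vertex weights
#'
#' For each vertex, take the subgraph induced by the vertex and its
#' neighbours, find its highest k-core, and set
#' `weight = k_max * density(core)`. Isolated vertices weigh 0.
#'
#' @param graph an igraph (treated as undirected simple).
#' @return named numeric vector of vertex weights.
#' @export
mcode_weights <- function(graph) {
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nm
  }
  w <- stats::setNames(numeric(igraph::vcount(g)), nm)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_along(w)) {
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0L) next
    core <- igraph::coreness(sub)
    k <- max(core)
    csub <- igraph::induced_subgraph(sub, which(core >= k))
    w[i] <- k * igraph::edge_density(csub)
  }
  w
}

# 2-core haircut: iteratively remove members connected to fewer than two
# other members.
haircut_members <- function(g, members) {
  repeat {
    if (length(members) < 2L) return(character())
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2L]
    if (!length(drop)) return(members)
    members <- setdiff(members, drop)
  }
}

#' MCODE molecular-complex detection
#'
#' Complexes are grown greedily from high-weight seed vertices
#' ([mcode_weights()]): starting at the unvisited vertex of highest weight,
#' neighbours with weight above `(1 - vwp) * seed weight` are included.
#' With the default `expand = "neighborhood"` candidates are the seed's
#' direct neighbours; `expand = "recursive"` also expands transitively
#' through included vertices (the classical formulation, which merges dense
#' regions connected by high-weight bridges). `haircut` prunes members
#' connected to fewer than two other members (2-core); pruned vertices are
#' released and may join a later complex. `fluff` adds boundary neighbours
#' whose closed-neighbourhood density exceeds `fluff_density` (fluffed
#' vertices may be shared between complexes). Complexes below `min_size` are
#' discarded; results are ranked by `score = density * size`.
#'
#' @param graph an igraph.
#' @param vwp vertex weight percentage in `[0, 1)`.
#' @param haircut,fluff logical post-processing switches.
#' @param fluff_density density threshold for fluff.
#' @param min_size minimum complex size after post-processing.
#' @param expand `"neighborhood"` (default) or `"recursive"`, see above.
#' @return list of `mcode_complex` objects (`members`, `seed`, `size`,
#'   `density`, `score`), ranked by decreasing score.
#' @export
mcode_complexes <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                            fluff_density = 0.5, min_size = 3,
                            expand = c("neighborhood", "recursive")) {
  expand <- match.arg(expand)
  if (!is.numeric(vwp) || length(vwp) != 1L || vwp < 0 || vwp >= 1) {
    stop("`vwp` must be in [0, 1)", call. = FALSE)
  }
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  w <- mcode_weights(g)
  nm <- names(w)
  visited <- stats::setNames(logical(length(w)), nm)
  complexes <- list()

  seeds <- nm[order(-w, nm)]
  for (seed in seeds) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- (1 - vwp) * w[seed]
    nbrs <- igraph::V(g)$name[as.integer(
      igraph::neighbors(g, seed))]
    members <- seed
    if (expand == "neighborhood") {
      add <- nbrs[!visited[nbrs] & w[nbrs] > thr]
      members <- c(seed, add)
    } else {
      queue <- nbrs
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        if (v %in% members || visited[v] || w[v] <= thr) next
        members <- c(members, v)
        queue <- c(queue, igraph::V(g)$name[as.integer(
          igraph::neighbors(g, v))])
      }
    }
    visited[members] <- TRUE
    core_members <- members
    if (fluff) {
      boundary <- setdiff(unique(unlist(lapply(core_members, function(v)
        igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]))),
        core_members)
      fl <- boundary[vapply(boundary, function(v) {
        nb <- unique(c(v, igraph::V(g)$name[as.integer(
          igraph::neighbors(g, v))]))
        igraph::edge_density(igraph::induced_subgraph(g, nb)) > fluff_density
      }, FALSE)]
      core_members <- c(core_members, fl)
    }
    if (haircut) {
      pruned <- haircut_members(g, core_members)
      visited[setdiff(members, pruned)] <- FALSE  # released for later seeds
      core_members <- pruned
    }
    if (length(core_members) < max(min_size, 2L)) next
    sub <- igraph::induced_subgraph(g, core_members)
    dens <- igraph::edge_density(sub)
    complexes[[length(complexes) + 1L]] <- structure(
      list(members = sort(core_members), seed = seed,
           size = length(core_members), density = dens,
           score = dens * length(core_members)),
      class = "mcode_complex")
  }
  complexes[order(-vapply(complexes, `[[`, 0, "score"))]
}

#' @export
print.mcode_complex <- function(x, ...) {
  cat(sprintf("<mcode_complex> %d nodes | density %.3f | score %.3f | seed %s\n",
              x$size, x$density, x$score, x$seed))
  invisible(x)
}

#' Network hubs by degree
#'
#' @param graph nonempty igraph.
#' @param top_n number of hubs to return (> 0).
#' @return character vector of node names sorted by decreasing degree, ties
#'   broken lexicographically.
#' @export
hubs <- function(graph, top_n = 10) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  top_n <- check_count(top_n, "top_n")
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  deg <- igraph::degree(g)
  nm <- names(deg) %||% as.character(seq_along(deg))
  ord <- order(-deg, nm)
  utils::head(nm[ord], top_n)
}

#' Count interactions between two gene sets
#'
#' Counts unique undirected edges with one endpoint in each set (the
#' bipartite interaction tally between, e.g., differentially expressed genes
#' and a pathway gene set). Genes present in both sets are flagged and each
#' of their qualifying edges is counted once.
#'
#' @param set_a,set_b character gene sets.
#' @param edges edge table with `gene_a`, `gene_b`.
#' @return list: `n_edges`, `n_a` / `n_b` (distinct touched genes per side),
#'   `shared` (genes in both sets).
#' @export
bipartite_count <- function(set_a, set_b, edges) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  a <- pmin(as.character(edges$gene_a), as.character(edges$gene_b))
  b <- pmax(as.character(edges$gene_a), as.character(edges$gene_b))
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  a <- a[keep]; b <- b[keep]
  cross <- (a %in% set_a & b %in% set_b) | (a %in% set_b & b %in% set_a)
  touched <- unique(c(a[cross], b[cross]))
  list(n_edges = sum(cross),
       n_a = length(intersect(touched, set_a)),
       n_b = length(intersect(touched, set_b)),
       shared = shared)
}

#' Export a network as an edge-list TSV with node roles
#'
#' @param graph network from [build_network()].
#' @param edge_path,node_path output TSVs.
#' @export
write_network_tsv <- function(graph, edge_path, node_path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  names(ed)[1:2] <- c("gene_a", "gene_b")
  write_tsv(ed, edge_path)
  nd <- igraph::as_data_frame(graph, what = "vertices")
  names(nd)[1L] <- "gene_id"
  write_tsv(nd, node_path)
  invisible(graph)
}

#' Export a network as GraphML
#' @param graph an igraph.
#' @param path output path.
#' @export
write_network_graphml <- function(graph, path) {
  # GraphML writer rejects list attributes; drop the audit attrs first
  for (at in igraph::graph_attr_names(graph)) {
    graph <- igraph::delete_graph_attr(graph, at)
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a typed edge table
#' @param path TSV with columns `gene_a gene_b` and optionally `type source`.
#' @export
read_edges <- function(path) {
  read_tsv_checked(path, required = c("gene_a", "gene_b"))
}
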