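# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (and igraph) wherever they are used to
# check one: distances come from hand-rolled BFS, betweenness from explicit
# enumeration of every shortest path, the edge rule from a double loop over
# ordered reaction pairs.

# -- edge rule oracle --------------------------------------------------------

# textual rule, one ordered pair at a time
oracle_edges <- function(reactions, excluded = character()) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  prod_set <- function(r)
    setdiff(if (r$reversible) union(r$products, r$substrates) else r$products,
            excluded)
  cons_set <- function(r)
    setdiff(if (r$reversible) union(r$substrates, r$products) else r$substrates,
            excluded)
  from <- to <- character(0)
  for (i in seq_along(reactions)) for (j in seq_along(reactions)) {
    if (i == j) next
    if (length(intersect(prod_set(reactions[[i]]), cons_set(reactions[[j]])))) {
      from <- c(from, ids[i]); to <- c(to, ids[j])
    }
  }
  ed <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  ed[order(ed$from, ed$to), , drop = FALSE]
}

# -- shortest-path oracles ---------------------------------------------------

# adjacency list from an edge data.frame over the node vector
.adj_list <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges)))
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
  adj
}

oracle_distances <- function(nodes, edges) {
  adj <- .adj_list(nodes, edges)
  D <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    D[s, s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

oracle_closeness <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 1) return(stats::setNames(0, nodes))
  D <- oracle_distances(nodes, edges)
  D[is.infinite(D)] <- n
  diag(D) <- 0
  1 / rowSums(D)
}

oracle_apl <- function(nodes, edges) {
  D <- oracle_distances(nodes, edges)
  diag(D) <- Inf
  fin <- D[is.finite(D)]
  if (!length(fin)) 0 else mean(fin)
}

# all shortest s->t paths by depth-first enumeration (tiny graphs only)
.all_shortest_paths <- function(adj, D, s, t) {
  if (is.infinite(D[s, t]) || s == t) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) { paths[[length(paths) + 1L]] <<- acc; return() }
    for (w in adj[[v]])
      if (is.finite(D[w, t]) && D[s, v] + 1 + D[w, t] == D[s, t] &&
          D[s, w] == D[s, v] + 1)
        walk(w, c(acc, w))
  }
  walk(s, s)
  paths
}

oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  btw <- stats::setNames(rep(0, n), nodes)
  if (n < 3) return(btw)
  adj <- .adj_list(nodes, edges)
  D <- oracle_distances(nodes, edges)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- .all_shortest_paths(adj, D, s, t)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]),
                    use.names = FALSE)
    if (length(inner)) {
      tab <- table(inner)
      btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2))
}

# -- random fixtures ---------------------------------------------------------

random_digraph <- function(n, p = 0.25) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = pairs[keep, c("from", "to"), drop = FALSE])
}

digraph_as_igraph <- function(g)
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$nodes))

# random pathway over a small metabolite pool; reversible with prob rev_p
random_pathway <- function(id, n_rxns, n_mets = 8, rev_p = 0.3) {
  mets <- sprintf("m%02d", seq_len(n_mets))
  rxns <- lapply(seq_len(n_rxns), function(i) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- sample(mets, ns)
    prods <- sample(setdiff(mets, subs), np)
    reaction(sprintf("%s_R%02d", id, i), subs, prods,
             reversible = stats::runif(1) < rev_p)
  })
  pathway(id, id, rxns)
}

# -- tiny named fixtures -----------------------------------------------------

chain_pathway <- function(id = "chain", mets = c("A", "B", "C"),
                          reversible = logical(length(mets) - 1)) {
  rxns <- lapply(seq_len(length(mets) - 1), function(i)
    reaction(sprintf("R%d", i), mets[i], mets[i + 1],
             reversible = reversible[i]))
  pathway(id, id, rxns)
}

write_tmp_kgml <- function(body, pid = "map99999") {
  f <- withr::local_tempfile(fileext = ".xml",
                             .local_envir = parent.frame())
  writeLines(c(sprintf('<pathway name="path:%s" title="fixture">', pid),
               body, "</pathway>"), f)
  f
}

kgml_reaction <- function(id, subs, prods, reversible = FALSE) {
  paste0(sprintf('<reaction id="0" name="rn:%s" type="%s">', id,
                 if (reversible) "reversible" else "irreversible"),
         paste(sprintf('<substrate id="0" name="cpd:%s"/>', subs),
               collapse = ""),
         paste(sprintf('<product id="0" name="cpd:%s"/>', prods),
               collapse = ""),
         "</reaction>")
}
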