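#' Default currency metabolites excluded from edge formation
#'
#' Ubiquitous cofactors and small inorganics (ATP, ADP, AMP, NAD(P)(H),
#' water, protons, phosphate, pyrophosphate, CO2) connect most reactions in
#' any pathway; leaving them in makes reaction graphs near-complete and
#' drowns the substrate-product backbone. The default exclusion list is
#' given as KEGG compound ids; pass \code{character()} to
#' [build_reaction_network()] to disable exclusion.
#'
#' @return Character vector of KEGG compound ids.
#' @export
currency_metabolites <- function() {
  c(ATP = "C00002", ADP = "C00008", AMP = "C00020",
    `NAD+` = "C00003", NADH = "C00004", `NADP+` = "C00006", NADPH = "C00005",
    H2O = "C00001", `H+` = "C00080", Pi = "C00009", PPi = "C00013",
    CO2 = "C00011")
}

# produced / consumed metabolite sets under the reversibility-expanded rule
.produced <- function(r, excluded)
  setdiff(if (r$reversible) union(r$products, r$substrates) else r$products,
          excluded)
.consumed <- function(r, excluded)
  setdiff(if (r$reversible) union(r$substrates, r$products) else r$substrates,
          excluded)

#' Build a directed reaction network from pathways
#'
#' Nodes are reactions; a directed edge runs from reaction A to reaction B
#' whenever some non-excluded metabolite produced by A is consumed by B.
#' For a reversible reaction both sides count as producible and consumable,
#' so reversible neighbours yield antiparallel edge pairs (drawn as double
#' edges in pathway maps). Self-loops are never created. Reactions present
#' in several pathways are merged into one node keyed by reaction id, with
#' provenance recording all source pathways.
#'
#' @param pathways A [pathway()] or list of pathways.
#' @param excluded_metabolites Metabolite ids ignored by the edge rule;
#'   defaults to [currency_metabolites()].
#' @return An object of class \code{"reaction_network"}: list with
#'   \code{nodes} (character), \code{edges} (data.frame \code{from},
#'   \code{to}), \code{provenance} (named list node -> pathway ids),
#'   \code{reactions} (merged reaction records) and the exclusion set used.
#' @export
build_reaction_network <- function(pathways,
                                   excluded_metabolites = currency_metabolites()) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  if (!length(pathways)) stop("at least one pathway is required")
  stopifnot(all(vapply(pathways, inherits, logical(1), "pathway")))
  excluded <- unname(excluded_metabolites)

  # merge duplicate reactions across pathways by id
  rxns <- list()
  for (pw in pathways) {
    for (r in pw$reactions) {
      if (is.null(rxns[[r$id]])) {
        rxns[[r$id]] <- r
      } else {
        old <- rxns[[r$id]]
        if (!setequal(old$substrates, r$substrates) ||
            !setequal(old$products, r$products))
          warning("reaction '", r$id,
                  "' has differing chemistry across pathways; merging by union",
                  call. = FALSE)
        old$substrates <- union(old$substrates, r$substrates)
        old$products <- union(old$products, r$products)
        old$reversible <- old$reversible || r$reversible
        old$pathway_ids <- union(old$pathway_ids, r$pathway_ids)
        rxns[[r$id]] <- old
      }
    }
  }
  nodes <- names(rxns)

  # metabolite -> producer/consumer incidence, then per-metabolite cross join
  prod_of <- lapply(rxns, .produced, excluded = excluded)
  cons_of <- lapply(rxns, .consumed, excluded = excluded)
  prod_idx <- split(rep(nodes, lengths(prod_of)),
                    unlist(prod_of, use.names = FALSE))
  cons_idx <- split(rep(nodes, lengths(cons_of)),
                    unlist(cons_of, use.names = FALSE))
  shared <- intersect(names(prod_idx), names(cons_idx))
  from <- to <- character(0)
  for (m in shared) {
    p <- prod_idx[[m]]; q <- cons_idx[[m]]
    from <- c(from, rep(p, each = length(q)))
    to <- c(to, rep(q, times = length(p)))
  }
  keep <- from != to
  edges <- unique(data.frame(from = from[keep], to = to[keep],
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(nodes = nodes, edges = edges,
         provenance = lapply(rxns, `[[`, "pathway_ids"),
         reactions = rxns, excluded_metabolites = excluded),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a reaction network to an igraph graph
#'
#' @param net A [build_reaction_network()] result.
#' @return A directed \pkg{igraph} graph with isolated nodes preserved.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Find pathways connected to a focal pathway
#'
#' A candidate pathway is connected when at least one of its reactions
#' produces or consumes a metabolite that the focal pathway consumes or
#' produces — i.e. their non-excluded metabolite sets intersect.
#'
#' @param focal The focal [pathway()].
#' @param candidates List of candidate pathways (excluding the focal one).
#' @param excluded_metabolites As in [build_reaction_network()].
#' @return Character vector of connected candidate pathway ids (possibly
#'   empty).
#' @export
find_connected_pathways <- function(focal, candidates,
                                    excluded_metabolites = currency_metabolites()) {
  stopifnot(inherits(focal, "pathway"))
  fmets <- pathway_metabolites(focal, excluded_metabolites)
  hit <- vapply(candidates, function(pw)
    length(intersect(pathway_metabolites(pw, excluded_metabolites), fmets)) > 0,
    logical(1))
  vapply(candidates[hit], `[[`, character(1), "id")
}

#' Combine reaction networks
#'
#' Merges a base network with additional networks. With
#' \code{rederive_cross_edges = TRUE} (default) the combined edge set is
#' re-derived by applying the edge rule to the union of underlying
#' reactions, so edges between reactions of previously separate pathways
#' appear; with \code{FALSE} only the node and edge sets are unioned.
#' The operation is commutative and associative in its resulting node and
#' edge sets, and combining a network with itself is the identity.
#'
#' @param base A [build_reaction_network()] result.
#' @param additions A single network or list of networks.
#' @param rederive_cross_edges Re-apply the edge rule over the union of
#'   reactions (default \code{TRUE}).
#' @return A combined \code{reaction_network}.
#' @export
combine_networks <- function(base, additions, rederive_cross_edges = TRUE) {
  stopifnot(inherits(base, "reaction_network"))
  if (inherits(additions, "reaction_network")) additions <- list(additions)
  nets <- c(list(base), additions)
  excluded <- base$excluded_metabolites
  if (rederive_cross_edges) {
    # rebuild from the union of reaction records, preserving provenance
    pws <- lapply(seq_along(nets), function(i)
      structure(list(id = paste0(".combine", i), name = "",
                     reactions = nets[[i]]$reactions), class = "pathway"))
    net <- build_reaction_network(pws, excluded)
    # strip the internal combine-stage pathway ids from provenance
    net$provenance <- lapply(net$provenance, function(p)
      p[!grepl("^\\.combine", p)])
    net$reactions <- lapply(net$reactions, function(r) {
      r$pathway_ids <- r$pathway_ids[!grepl("^\\.combine", r$pathway_ids)]
      r
    })
    return(net)
  }
  nodes <- unique(unlist(lapply(nets, `[[`, "nodes"), use.names = FALSE))
  edges <- unique(do.call(rbind, lapply(nets, `[[`, "edges")))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  prov <- list(); rxns <- list()
  for (nt in nets) {
    for (nd in nt$nodes) {
      prov[[nd]] <- union(prov[[nd]], nt$provenance[[nd]])
      if (is.null(rxns[[nd]])) rxns[[nd]] <- nt$reactions[[nd]]
    }
  }
  structure(list(nodes = nodes, edges = edges, provenance = prov[nodes],
                 reactions = rxns[nodes], excluded_metabolites = excluded),
            class = "reaction_network")
}

#' Reactions common to every network in a collection
#'
#' Intersection of node sets across organisms; the shared core on which
#' cross-organism variation is measured.
#'
#' @param networks Named list (organism -> \code{reaction_network}).
#' @return Character vector of reaction ids.
#' @export
common_core <- function(networks) {
  stopifnot(length(networks) >= 1L)
  Reduce(intersect, lapply(networks, `[[`, "nodes"))
}
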