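#' Per-node network metrics
#'
#' Computes the four node-level parameters used throughout the analysis:
#' \describe{
#'   \item{degree}{total (in + out) degree on the directed graph;}
#'   \item{clustering}{local clustering coefficient on the undirected
#'     projection (triangles over connected triples), 0 for nodes with
#'     fewer than two neighbours;}
#'   \item{closeness}{\code{1 / sum(d(v, u))} over all other nodes, with
#'     unreachable distances replaced by the vertex count \code{n} — the
#'     classic convention for disconnected digraphs. Under it a node that
#'     reaches nothing has closeness exactly \code{1/(n (n-1))};}
#'   \item{betweenness}{directed shortest-path betweenness normalised by
#'     \code{(n-1)(n-2)}, hence in \code{[0, 1]}; 0 for all nodes when
#'     \code{n < 3}.}
#' }
#'
#' @param net A [build_reaction_network()] result or an igraph graph.
#' @return A data.frame with columns \code{node}, \code{degree},
#'   \code{clustering}, \code{closeness}, \code{betweenness}.
#' @export
node_metrics <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))

  deg <- igraph::degree(g, mode = "all", loops = FALSE)
  und <- igraph::as_undirected(g, mode = "collapse")
  clus <- igraph::transitivity(und, type = "local", isolates = "zero")

  if (n == 1L) {
    clo <- 0
  } else {
    D <- igraph::distances(g, mode = "out")
    D[is.infinite(D)] <- n
    diag(D) <- 0
    clo <- 1 / rowSums(D)
  }
  btw <- if (n < 3L) rep(0, n) else
    igraph::betweenness(g, directed = TRUE, normalized = FALSE) /
      ((n - 1) * (n - 2))

  data.frame(node = ids, degree = as.numeric(deg),
             clustering = as.numeric(clus), closeness = as.numeric(clo),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Whole-graph metrics
#'
#' Average degree is \code{2 E / n} (each directed edge counted once at
#' each endpoint); average path length averages shortest-path distance over
#' ordered pairs of distinct nodes with a finite distance.
#'
#' @param net A [build_reaction_network()] result or an igraph graph.
#' @return A one-row data.frame with \code{n_nodes}, \code{n_edges},
#'   \code{average_degree}, \code{average_path_length}.
#' @export
graph_metrics <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  m <- igraph::ecount(g)
  D <- igraph::distances(g, mode = "out")
  diag(D) <- Inf
  finite <- D[is.finite(D)]
  if (!length(finite)) {
    warning("no reachable ordered pairs; average path length set to 0")
    apl <- 0
  } else apl <- mean(finite)
  data.frame(n_nodes = n, n_edges = m, average_degree = 2 * m / n,
             average_path_length = apl)
}

#' Detect hubs as the top fraction of a centrality measure
#'
#' Hubs are the nodes in the top \code{fraction} (default 20\%) of a
#' metric. The cutoff is the metric value at descending rank
#' \code{ceiling(fraction * n)}; all nodes tied at the cutoff value are
#' included, so the hub set can exceed the nominal count.
#'
#' @param metrics A [node_metrics()] data.frame.
#' @param metric One of \code{"degree"}, \code{"betweenness"},
#'   \code{"closeness"} (clustering is not a hub measure).
#' @param fraction Top fraction to keep, in \code{(0, 1]}.
#' @return An object of class \code{"hub_set"}: list with \code{metric},
#'   \code{members}, \code{fraction}, \code{cutoff_value}.
#' @export
detect_hubs <- function(metrics, metric = c("degree", "betweenness", "closeness"),
                        fraction = 0.20) {
  metric <- match.arg(metric)
  stopifnot(fraction > 0, fraction <= 1)
  vals <- metrics[[metric]]
  n <- length(vals)
  if (!n) stop("no nodes in metrics table")
  ord <- order(vals, decreasing = TRUE)
  cutoff <- vals[ord[ceiling(fraction * n)]]
  members <- metrics$node[vals >= cutoff]
  if (length(unique(vals)) == 1L)
    message("all nodes share the same ", metric,
            " value; every node is a hub")
  structure(list(metric = metric, members = members, fraction = fraction,
                 cutoff_value = cutoff),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat("<hub_set> ", x$metric, " (top ", 100 * x$fraction, "%): ",
      length(x$members), " nodes, cutoff ", signif(x$cutoff_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' Hubs common across organisms
#'
#' Intersects per-organism hub memberships, per metric and as a
#' union-of-metrics variant (a reaction counts if it is a hub of any
#' measure in every organism).
#'
#' @param hub_sets Named list (organism -> named list of [detect_hubs()]
#'   results keyed by metric), or, for a single metric, a plain list of
#'   \code{hub_set} objects.
#' @return Named list of character vectors: one per metric present in all
#'   organisms, plus \code{"any_metric"} for the union-of-metrics variant.
#' @export
common_hubs <- function(hub_sets) {
  stopifnot(length(hub_sets) >= 1L)
  if (all(vapply(hub_sets, inherits, logical(1), "hub_set"))) {
    metric <- unique(vapply(hub_sets, `[[`, character(1), "metric"))
    stopifnot(length(metric) == 1L)
    hub_sets <- lapply(hub_sets, function(h) stats::setNames(list(h), metric))
  }
  metrics <- Reduce(intersect, lapply(hub_sets, names))
  out <- lapply(metrics, function(m)
    Reduce(intersect, lapply(hub_sets, function(org) org[[m]]$members)))
  names(out) <- metrics
  out$any_metric <- Reduce(intersect, lapply(hub_sets, function(org)
    unique(unlist(lapply(org, `[[`, "members"), use.names = FALSE))))
  out
}

#' Cross-context variation of node metrics
#'
#' Given per-context metric tables for the same core reactions (contexts
#' are organisms, or the focal pathway combined with each connected
#' pathway), computes per-reaction standard deviation and z-scores of each
#' metric across contexts, and flags reactions with marked variation:
#' standard deviation above \code{sd_threshold} (used for degree and
#' clustering calls) and any context with \code{|z|} above
#' \code{z_threshold} (used for betweenness calls).
#'
#' @param contexts Named list (context -> [node_metrics()] data.frame).
#'   Only reactions present in every context are reported.
#' @param metrics Metric columns to analyse.
#' @param sd_threshold Flag threshold on the standard deviation (default 2).
#' @param z_threshold Flag threshold on \code{max |z|} (default 3).
#' @return A data.frame of class \code{"variation_report"}: \code{node},
#'   \code{metric}, \code{sd}, \code{max_abs_z}, \code{flag_sd},
#'   \code{flag_z}.
#' @export
variation_across <- function(contexts,
                             metrics = c("degree", "clustering",
                                         "closeness", "betweenness"),
                             sd_threshold = 2, z_threshold = 3) {
  if (length(contexts) < 2L)
    stop("at least two contexts are required to measure variation")
  core <- Reduce(intersect, lapply(contexts, `[[`, "node"))
  rows <- list()
  for (m in metrics) {
    vals <- vapply(contexts, function(tab)
      tab[[m]][match(core, tab$node)], numeric(length(core)))
    vals <- matrix(vals, nrow = length(core))
    mu <- rowMeans(vals)
    sdv <- apply(vals, 1, stats::sd)
    z <- abs(vals - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    rows[[m]] <- data.frame(node = core, metric = m, sd = sdv,
                            max_abs_z = apply(z, 1, max),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$flag_sd <- out$sd > sd_threshold
  out$flag_z <- out$max_abs_z > z_threshold
  rownames(out) <- NULL
  class(out) <- c("variation_report", class(out))
  out
}
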