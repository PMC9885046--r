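#' Wilcoxon comparison of a network property between two groups
#'
#' Two-sided throughout. Paired comparisons (e.g. focal pathway vs
#' combined network, per organism) use the signed-rank test; unpaired
#' (e.g. Bacteria vs Archaea) use the rank-sum test. Small paired samples
#' (n <= 15) get an exact two-sided p by full enumeration of sign
#' assignments of the tied-rank statistic, which stays exact under ties;
#' larger samples and unpaired comparisons use [stats::wilcox.test()]
#' (exact where available, otherwise the normal approximation with tie
#' correction).
#'
#' @param values_a,values_b Numeric vectors; equal length when paired.
#' @param paired Paired signed-rank (\code{TRUE}) or unpaired rank-sum.
#' @param labels Length-2 character vector naming the groups.
#' @param metric Name of the property compared (bookkeeping only).
#' @param alpha Significance level for the flag (default 0.05).
#' @return A one-row data.frame of class \code{"group_comparison"}:
#'   \code{metric}, \code{group_a}, \code{group_b}, \code{test},
#'   \code{statistic}, \code{p_value}, \code{significant}.
#' @export
wilcoxon_compare <- function(values_a, values_b, paired = FALSE,
                             labels = c("A", "B"), metric = "value",
                             alpha = 0.05) {
  if (paired) {
    stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
    if (all(values_a == values_b)) {
      warning("all paired differences are zero; p = 1")
      out <- list(statistic = 0, p.value = 1)
    } else if (length(values_a) <= 15) {
      # exact two-sided p by enumerating all sign assignments of the
      # tied-rank statistic; tie-robust where the classic exact test is not
      d <- values_a - values_b
      d <- d[d != 0]
      r <- rank(abs(d))
      v_obs <- sum(r[d > 0])
      v_all <- colSums(r * (t(as.matrix(expand.grid(
        rep(list(c(0, 1)), length(d))))) == 1))
      p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
      out <- list(statistic = v_obs, p.value = p)
    } else {
      out <- suppressWarnings(
        stats::wilcox.test(values_a, values_b, paired = TRUE,
                           exact = length(values_a) <= 25))
    }
  } else {
    stopifnot(length(values_a) >= 1, length(values_b) >= 1)
    out <- suppressWarnings(
      stats::wilcox.test(values_a, values_b,
                         exact = max(length(values_a), length(values_b)) <= 25))
  }
  res <- data.frame(metric = metric, group_a = labels[1], group_b = labels[2],
                    test = if (paired) "paired signed-rank" else
                      "unpaired rank-sum",
                    statistic = unname(out$statistic),
                    p_value = min(1, out$p.value),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_value < alpha
  class(res) <- c("group_comparison", class(res))
  res
}

#' Overlap between network hubs and FBA-essential reactions
#'
#' Quantifies how far topology predicts function: the percentage of hub
#' reactions (per centrality measure) that the deletion scan also flags as
#' essential for the focal pathway's section fluxes. Hub ids are first
#' translated into the model's reaction-id namespace through an explicit
#' mapping table; with \code{strict = FALSE} (default) unmapped ids are
#' reported and dropped from the denominator, with \code{strict = TRUE}
#' they are an error.
#'
#' @param hubs A [detect_hubs()] result, or a plain character vector of
#'   hub reaction ids (then \code{metric} should be given).
#' @param essential An [essentiality_scan()] result, or a character vector
#'   of essential reaction ids.
#' @param id_map Optional named character vector (hub namespace -> model
#'   namespace), as from [read_id_map()].
#' @param strict Error on unmapped hub ids instead of excluding them.
#' @param metric Metric label when \code{hubs} is a bare vector.
#' @return A one-row data.frame of class \code{"overlap_report"}:
#'   \code{metric}, \code{n_hubs}, \code{n_overlap}, \code{percentage}.
#' @export
hub_essential_overlap <- function(hubs, essential, id_map = NULL,
                                  strict = FALSE, metric = NULL) {
  if (inherits(hubs, "hub_set")) {
    metric <- hubs$metric
    members <- hubs$members
  } else {
    members <- as.character(hubs)
    if (is.null(metric)) metric <- "unspecified"
  }
  if (!length(members)) stop("empty hub set")
  ess <- if (inherits(essential, "essential_set")) essential$essential
         else as.character(essential)
  if (!is.null(id_map)) {
    unmapped <- setdiff(members, names(id_map))
    # ids already in the model namespace pass through the lookup unchanged
    unmapped <- setdiff(unmapped, ess)
    if (length(unmapped)) {
      if (strict)
        stop("unmapped hub id(s): ", paste(unmapped, collapse = ", "))
      message(length(unmapped),
              " hub id(s) without a model mapping excluded from the denominator")
      members <- setdiff(members, unmapped)
    }
    members <- unique(apply_id_map(members, id_map))
    if (!length(members)) stop("no hub ids map into the model namespace")
  }
  n_overlap <- length(intersect(members, ess))
  res <- data.frame(metric = metric, n_hubs = length(members),
                    n_overlap = n_overlap,
                    percentage = 100 * n_overlap / length(members),
                    stringsAsFactors = FALSE)
  class(res) <- c("overlap_report", class(res))
  res
}

# polynomial rolling hash of a serialised object, for run-log fingerprints
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pathway-in-context analysis pipeline
#'
#' Drives every stage on a synthetic ensemble plus toy model: generate the
#' ensemble, build per-organism focal and combined networks and the
#' combined connected network, compute node and graph metrics, variation
#' across organisms, hub sets and common hubs, run the FBA essentiality
#' scan on the toy model, and report the hub/essential overlap. All
#' tabular outputs are written as TSV under \code{out_dir} together with a
#' run log carrying the seed and a config fingerprint; identical config
#' and seed give byte-identical outputs.
#'
#' @param config A list (or path to a YAML file) with components:
#'   \describe{
#'     \item{seed}{integer seed;}
#'     \item{ensemble}{arguments for [ensemble_spec()];}
#'     \item{toy_model}{arguments for [toy_model_spec()];}
#'     \item{hub_fraction}{top fraction for [detect_hubs()] (default 0.2);}
#'     \item{id_map}{optional named vector or TSV path mapping network ids
#'       to model ids for the overlap stage;}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a list with the networks, metrics, hubs, variation
#'   report, essentiality scan and overlap table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "pathcontext_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  hub_fraction <- config$hub_fraction %||% 0.2
  cfg_id <- config
  cfg_id$out_dir <- NULL  # output location is not part of the analysis identity
  log_lines <- c(sprintf("seed\t%d", seed),
                 sprintf("config_hash\t%s", .config_hash(cfg_id)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  es_args <- config$ensemble %||% list()
  es_args$seed <- seed
  ens <- stage("ensemble", generate_ensemble(do.call(ensemble_spec, es_args)))
  log_lines <- c(log_lines, sprintf("organisms\t%d", length(ens$organisms)))

  nets <- stage("networks", lapply(ens$organisms, function(pws) {
    focal <- build_reaction_network(pws[[1]], character())
    combined <- build_reaction_network(pws, character())
    list(focal = focal, combined = combined)
  }))
  combined_nets <- lapply(nets, `[[`, "combined")
  core <- common_core(lapply(nets, `[[`, "focal"))
  log_lines <- c(log_lines, sprintf("common_core\t%d", length(core)))

  metrics <- stage("metrics", lapply(combined_nets, node_metrics))
  all_metrics <- do.call(rbind, Map(function(org, tab)
    cbind(organism = org, tab), names(metrics), metrics))
  utils::write.table(all_metrics, file.path(out_dir, "node_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gsum <- do.call(rbind, Map(function(org, nt)
    cbind(organism = org, graph_metrics(nt)), names(combined_nets),
    combined_nets))
  utils::write.table(gsum, file.path(out_dir, "graph_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  variation <- stage("variation", variation_across(
    lapply(metrics, function(tab) tab[tab$node %in% core, , drop = FALSE])))
  utils::write.table(variation, file.path(out_dir, "variation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hubs <- stage("hubs", lapply(metrics, function(tab)
    list(degree = detect_hubs(tab, "degree", hub_fraction),
         betweenness = detect_hubs(tab, "betweenness", hub_fraction),
         closeness = detect_hubs(tab, "closeness", hub_fraction))))
  chubs <- common_hubs(hubs)
  for (m in names(chubs))
    writeLines(sort(chubs[[m]]),
               file.path(out_dir, paste0("common_hubs_", m, ".txt")))

  toy_args <- config$toy_model %||% list()
  toy <- stage("toy_model", generate_toy_model(do.call(toy_model_spec,
                                                       toy_args)))
  scan <- stage("fba_scan", essentiality_scan(toy$model, toy$reporters,
                                              sections = toy$sections))
  utils::write.table(scan$table, file.path(out_dir, "fba_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  id_map <- config$id_map
  if (is.character(id_map) && length(id_map) == 1L && file.exists(id_map))
    id_map <- read_id_map(id_map)
  overlap <- stage("overlap", {
    rows <- lapply(c("degree", "betweenness", "closeness"), function(m) {
      if (!length(chubs[[m]])) return(NULL)
      tryCatch(hub_essential_overlap(chubs[[m]], scan, id_map = id_map,
                                     metric = m),
               error = function(e) NULL)
    })
    do.call(rbind, rows)
  })
  if (!is.null(overlap))
    utils::write.table(overlap, file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(ensemble = ens, networks = nets, metrics = metrics,
                 variation = variation, hubs = hubs, common_hubs = chubs,
                 toy = toy, scan = scan, overlap = overlap,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
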