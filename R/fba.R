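# Linear programming formulation for flux balance analysis.
#
# Fluxes are split into nonnegative forward/reverse parts (v = p - q) so the
# problem fits the standard-form two-phase simplex in lp.R: maximise
# c'(p - q) subject to S(p - q) = 0, variable bounds as inequality rows.
# Infinite bounds are capped at a large finite value.

.FBA_BIG <- 1e6

.solve_lp <- function(S, lb, ub, obj, maximize = TRUE,
                      fixed_row = NULL, fixed_val = NULL,
                      minimize_total = FALSE, eps = 1e-10) {
  n <- ncol(S)
  lb <- pmax(lb, -.FBA_BIG); ub <- pmin(ub, .FBA_BIG)
  pu <- pmax(ub, 0); plow <- pmax(lb, 0)
  qu <- pmax(-lb, 0); qlow <- pmax(-ub, 0)

  # variable layout: forward parts with positive capacity, then reverse parts
  pi_idx <- which(pu > 0)
  qi_idx <- which(qu > 0)
  nv <- length(pi_idx) + length(qi_idx)
  if (nv == 0L) {  # fully clamped model: v = 0 is the only candidate
    feas <- is.null(fixed_row) || abs(fixed_val) < eps
    return(list(solved = if (feas) 1L else -1L, v = numeric(n), value = 0))
  }
  Svar <- cbind(S[, pi_idx, drop = FALSE], -S[, qi_idx, drop = FALSE])

  # upper-capacity rows, positive-lower-bound rows, steady state, optional
  # fixed-objective row for the parsimonious stage
  Aub <- diag(nv)
  bub <- c(pu[pi_idx], qu[qi_idx])
  lo <- c(plow[pi_idx], qlow[qi_idx])
  need <- which(lo > 0)
  Alo <- matrix(0, length(need), nv)
  if (length(need)) Alo[cbind(seq_along(need), need)] <- 1
  A <- rbind(Aub, Alo, Svar)
  b <- c(bub, lo[need], rep(0, nrow(S)))
  ops <- c(rep("<=", nv), rep(">=", length(need)), rep("=", nrow(S)))
  if (!is.null(fixed_row)) {
    A <- rbind(A, c(fixed_row[pi_idx], -fixed_row[qi_idx]))
    b <- c(b, fixed_val)
    ops <- c(ops, "=")
  }
  a <- if (minimize_total) rep(1, nv) else c(obj[pi_idx], -obj[qi_idx])
  res <- .lp_solve(a, A, b, ops,
                   maximize = !minimize_total && maximize, tol = eps)
  if (!identical(res$status, "optimal"))
    return(list(solved = -1L, v = numeric(n), value = NA_real_))
  p <- q <- numeric(n)
  p[pi_idx] <- res$x[seq_along(pi_idx)]
  q[qi_idx] <- res$x[length(pi_idx) + seq_along(qi_idx)]
  list(solved = 1L, v = p - q, value = res$value)
}

#' Flux balance analysis with parsimonious second stage
#'
#' Maximises the biomass objective under steady state (\code{S v = 0}) and
#' the model's flux bounds, then — because plain FBA admits alternate
#' optima — fixes the optimal biomass and minimises total absolute flux
#' (a parsimonious second stage), giving a reproducible flux vector.
#'
#' @param model A [stoich_model()].
#' @param pfba Run the flux-minimising second stage (default \code{TRUE}).
#' @param zero_tol Fluxes smaller than this in magnitude are reported as 0.
#' @return An object of class \code{"fba_solution"}: list with
#'   \code{status} (\code{"optimal"} or \code{"infeasible"}),
#'   \code{objective} (growth rate, 1/h) and \code{fluxes} (named numeric,
#'   mmol/gDW/h). Infeasible models return an empty flux vector.
#' @export
#' @examples
#' m <- generate_toy_model(toy_model_spec(branch_a = 0.3, branch_b = 0.7,
#'                                        uptake = 10))
#' sol <- fba_optimize(m$model)
#' sol$objective
fba_optimize <- function(model, pfba = TRUE, zero_tol = 1e-9) {
  stopifnot(inherits(model, "stoich_model"))
  rxn_ids <- colnames(model$S)
  obj <- as.numeric(rxn_ids == model$objective)
  s1 <- .solve_lp(model$S, model$lb, model$ub, obj, maximize = TRUE)
  if (s1$solved < 0)
    return(structure(list(status = "infeasible", objective = NA_real_,
                          fluxes = stats::setNames(numeric(0), character(0))),
                     class = "fba_solution"))
  growth <- sum(obj * s1$v)
  v <- s1$v
  if (pfba) {
    s2 <- .solve_lp(model$S, model$lb, model$ub, obj,
                    fixed_row = obj, fixed_val = growth,
                    minimize_total = TRUE)
    if (s2$solved >= 0) v <- s2$v
  }
  v[abs(v) < zero_tol] <- 0
  structure(list(status = "optimal", objective = growth,
                 fluxes = stats::setNames(v, rxn_ids)),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status ", x$status,
      if (!is.na(x$objective)) paste0(", growth ", signif(x$objective, 6)),
      "\n", sep = "")
  invisible(x)
}

#' Maximum steady-state violation of a flux solution
#'
#' @param model A [stoich_model()].
#' @param solution An [fba_optimize()] result.
#' @return \code{max |S v|} over metabolites.
#' @export
mass_balance_residual <- function(model, solution) {
  if (!length(solution$fluxes)) return(NA_real_)
  max(abs(model$S %*% solution$fluxes[colnames(model$S)]))
}

#' Flux through each pathway section
#'
#' Each section of the focal pathway is summarised by the absolute flux of
#' one designated reporter reaction (the section's defining linear
#' segment carries a single undivided flux, so any of its reactions is
#' representative; the reporter makes the choice explicit and
#' configurable).
#'
#' @param solution An [fba_optimize()] result.
#' @param reporters Named character vector: section label -> reporter
#'   reaction id.
#' @param sections Optional section map (as from [read_section_map()]) used
#'   to check that each reporter belongs to its section.
#' @return Named numeric vector of section fluxes.
#' @export
section_flux <- function(solution, reporters, sections = NULL) {
  stopifnot(inherits(solution, "fba_solution"), length(reporters) >= 1L,
            !is.null(names(reporters)))
  if (!is.null(sections)) {
    for (sec in names(reporters)) {
      rid <- reporters[[sec]]
      if (rid %in% names(sections) && !identical(unname(sections[[rid]]), sec))
        warning("reporter ", rid, " is mapped to section ", sections[[rid]],
                ", not ", sec, call. = FALSE)
    }
  }
  missing <- !reporters %in% names(solution$fluxes)
  if (any(missing))
    stop("reporter reaction missing from model for section(s): ",
         paste(names(reporters)[missing], collapse = ", "))
  stats::setNames(abs(solution$fluxes[unname(reporters)]), names(reporters))
}

#' Delete genes from a model
#'
#' Reactions whose GPR rule evaluates false once the deleted genes are
#' absent get both bounds set to zero; reactions with no rule, or with a
#' surviving isozyme branch, are untouched.
#'
#' @param model A [stoich_model()].
#' @param genes Gene ids to delete; unknown genes are an error.
#' @return The perturbed model.
#' @export
delete_genes <- function(model, genes) {
  stopifnot(inherits(model, "stoich_model"))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  present <- setdiff(model$genes, genes)
  for (rid in names(model$gpr)) {
    rule <- model$gpr[[rid]]
    if (nzchar(rule) && !eval_gpr(rule, present)) {
      model$lb[rid] <- 0
      model$ub[rid] <- 0
    }
  }
  model
}

#' Delete (knock out) reactions from a model
#'
#' @param model A [stoich_model()].
#' @param rxns Reaction ids to disable; unknown ids are an error.
#' @return The perturbed model with both bounds of each reaction at zero.
#' @export
delete_reactions <- function(model, rxns) {
  stopifnot(inherits(model, "stoich_model"))
  unknown <- setdiff(rxns, colnames(model$S))
  if (length(unknown))
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  model$lb[rxns] <- 0
  model$ub[rxns] <- 0
  model
}

#' Scan single deletions for adverse effect on pathway section fluxes
#'
#' Deletes each candidate in turn, re-runs the two-stage FBA and records
#' the section fluxes. A candidate is essential for the focal pathway when
#' any section flux falls below \code{(1 - epsilon)} times its wild-type
#' value minus a numeric tolerance. With the default \code{epsilon = 0}
#' any reduction beyond tolerance counts as adverse.
#'
#' @param model A [stoich_model()].
#' @param reporters Named section -> reporter reaction id vector, as in
#'   [section_flux()].
#' @param candidates Ids to scan. Default: all non-exchange reactions
#'   except the objective (reaction mode) or all genes (gene mode).
#' @param by Knock out \code{"reaction"}s directly or delete \code{"gene"}s
#'   and let the GPR rules decide which reactions go down.
#' @param epsilon Tolerated fractional reduction in \code{[0, 1)}.
#' @param tol Absolute numeric tolerance on the flux comparison.
#' @param sections Optional section map for reporter validation.
#' @return An object of class \code{"essential_set"}: list with
#'   \code{essential} (ids), \code{epsilon}, \code{wt} (wild-type section
#'   fluxes and growth) and \code{table} (per-candidate growth and section
#'   fluxes with the essential flag).
#' @export
essentiality_scan <- function(model, reporters, candidates = NULL,
                              by = c("reaction", "gene"),
                              epsilon = 0, tol = 1e-6, sections = NULL) {
  by <- match.arg(by)
  stopifnot(epsilon >= 0, epsilon < 1)
  wt <- fba_optimize(model)
  if (wt$status != "optimal") stop("wild-type model is infeasible; aborting scan")
  wt_sec <- section_flux(wt, reporters, sections)
  if (is.null(candidates)) {
    candidates <- if (by == "reaction")
      setdiff(colnames(model$S),
              c(exchange_reactions(model), model$objective))
    else model$genes
  }
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    id <- candidates[i]
    pert <- if (by == "reaction") delete_reactions(model, id) else
      delete_genes(model, id)
    sol <- fba_optimize(pert)
    if (sol$status == "optimal") {
      sec <- section_flux(sol, reporters, sections)
      growth <- sol$objective
    } else {
      sec <- stats::setNames(rep(0, length(reporters)), names(reporters))
      growth <- 0
    }
    ess <- any(sec < (1 - epsilon) * wt_sec - tol)
    rows[[i]] <- data.frame(id = id, growth = growth, t(sec),
                            essential = ess, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(essential = tab$id[tab$essential], epsilon = epsilon,
                 by = by,
                 wt = c(growth = wt$objective, wt_sec), table = tab),
            class = "essential_set")
}

#' @export
print.essential_set <- function(x, ...) {
  cat("<essential_set> ", length(x$essential), " of ", nrow(x$table),
      " ", x$by, "s adversely affect section fluxes (epsilon = ",
      x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Constrain a reaction to a fraction of its wild-type flux
#'
#' Models a partial loss of enzymatic efficiency: the bound on the side of
#' the reaction's wild-type flux is scaled to \code{fraction} times that
#' flux, keeping the sign. A forward-running reaction gets its upper bound
#' lowered to \code{fraction * v}; a reverse-running (negative-flux)
#' reaction gets its lower bound raised to \code{fraction * v}, scaling
#' the magnitude while keeping the direction.
#'
#' @param model A [stoich_model()].
#' @param rxn Reaction id.
#' @param fraction Efficiency fraction in \code{[0, 1]}; 1 leaves the
#'   optimum unchanged, 0 is a deletion.
#' @param solution Optional precomputed wild-type [fba_optimize()] result
#'   (computed if absent).
#' @param tol Fluxes below this magnitude count as zero: the constraint is
#'   then a no-op with a warning.
#' @return The constrained model.
#' @export
constrain_efficiency <- function(model, rxn, fraction, solution = NULL,
                                 tol = 1e-9) {
  stopifnot(inherits(model, "stoich_model"),
            fraction >= 0, fraction <= 1)
  if (!rxn %in% colnames(model$S)) stop("unknown reaction: ", rxn)
  if (is.null(solution)) solution <- fba_optimize(model)
  if (solution$status != "optimal") stop("wild-type model is infeasible")
  v <- solution$fluxes[[rxn]]
  if (abs(v) < tol) {
    warning("reaction ", rxn, " carries no wild-type flux; no constraint applied")
    return(model)
  }
  if (v >= 0) {
    model$ub[rxn] <- fraction * v
    model$lb[rxn] <- min(model$lb[rxn], fraction * v)
  } else {
    model$lb[rxn] <- fraction * v
    model$ub[rxn] <- max(model$ub[rxn], fraction * v)
  }
  model
}
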