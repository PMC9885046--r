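#' Construct a stoichiometric model
#'
#' The constraint-based container used by the flux balance analysis core:
#' a metabolites-by-reactions stoichiometric matrix, flux bounds in
#' mmol/gDW/h, gene-protein-reaction rules and a biomass objective.
#'
#' @param S Numeric matrix (metabolites x reactions) with dimnames; column
#'   names are reaction ids, row names metabolite ids (compartment suffixes
#'   retained, e.g. \code{"glc__D_e"}).
#' @param lb,ub Numeric vectors of lower/upper flux bounds, one per
#'   reaction (recycled names from \code{colnames(S)} if unnamed).
#' @param objective Reaction id of the biomass (objective) reaction.
#' @param gpr Named character vector of GPR rule strings per reaction;
#'   missing entries mean "no rule".
#' @param genes Character vector of gene ids; defaults to the union of
#'   genes referenced by the GPR rules. Every gene used in a rule must be
#'   listed.
#' @param compartments Optional named character vector mapping metabolite
#'   id to compartment.
#' @param name Model name.
#'
#' @return An object of class \code{"stoich_model"}.
#' @export
stoich_model <- function(S, lb, ub, objective, gpr = character(),
                         genes = NULL, compartments = NULL, name = "model") {
  S <- as.matrix(S)
  if (is.null(colnames(S)) || is.null(rownames(S)))
    stop("S must have reaction column names and metabolite row names")
  rxn_ids <- colnames(S)
  n <- length(rxn_ids)
  lb <- stats::setNames(as.numeric(lb), rxn_ids)
  ub <- stats::setNames(as.numeric(ub), rxn_ids)
  if (any(lb > ub))
    stop("bound violation (lower > upper) for: ",
         paste(rxn_ids[lb > ub], collapse = ", "))
  if (!objective %in% rxn_ids)
    stop("objective reaction '", objective, "' not in model")
  full_gpr <- stats::setNames(rep("", n), rxn_ids)
  if (length(gpr)) {
    unknown <- setdiff(names(gpr), rxn_ids)
    if (length(unknown))
      stop("GPR for unknown reaction(s): ", paste(unknown, collapse = ", "))
    full_gpr[names(gpr)] <- gpr
  }
  used <- unique(unlist(lapply(full_gpr, function(g)
    if (nzchar(g)) gpr_genes(g) else character()), use.names = FALSE))
  if (is.null(genes)) genes <- used
  extra <- setdiff(used, genes)
  if (length(extra))
    stop("GPR gene(s) not in gene list: ", paste(extra, collapse = ", "))
  structure(
    list(name = name, S = S, lb = lb, ub = ub, objective = objective,
         gpr = full_gpr, genes = genes, compartments = compartments),
    class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", x$name, ": ", ncol(x$S), " reactions, ",
      nrow(x$S), " metabolites, ", length(x$genes), " genes; objective ",
      x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model A [stoich_model()].
#' @return Character vector of reaction ids.
#' @export
model_reactions <- function(model) colnames(model$S)

#' Exchange reactions of a model
#'
#' Exchanges are reactions touching exactly one metabolite (pure
#' import/export across the system boundary).
#'
#' @param model A [stoich_model()].
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- colSums(model$S != 0)
  colnames(model$S)[nz == 1L]
}

#' Growth medium implied by the model bounds
#'
#' For every exchange reaction written in export orientation (metabolite
#' leaves the system at positive flux), a negative lower bound permits
#' uptake; the medium is the map exchange id -> maximum uptake rate.
#'
#' @param model A [stoich_model()].
#' @return Named numeric vector of maximum uptake rates (positive numbers).
#' @export
model_medium <- function(model) {
  ex <- exchange_reactions(model)
  up <- -model$lb[ex]
  up[up > 0]
}

# --- SBML reading ----------------------------------------------------------

# attribute lookup tolerant of namespace prefixes ("fbc:reaction" vs "reaction")
.sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, names(at))
  if (is.na(hit)) hit <- grep(paste0("(^|:)", name, "$"), names(at))[1]
  if (is.na(hit) || !length(hit)) NA_character_ else unname(at[hit])
}

.ln <- function(node, name, all = FALSE) {
  xp <- paste0(".//*[local-name()='", name, "']")
  if (all) xml2::xml_find_all(node, xp) else xml2::xml_find_first(node, xp)
}

.strip_sbml_prefix <- function(ids, prefix) sub(paste0("^", prefix, "_"), "", ids)

# fbc geneProductAssociation subtree -> GPR string, using gene labels
.fbc_gpr <- function(node, label_of) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- .sbml_attr(node, "geneProduct")
    return(if (gp %in% names(label_of)) label_of[[gp]] else
             .strip_sbml_prefix(gp, "G"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .fbc_gpr, character(1), label_of = label_of)
  if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
  else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
  else if (length(parts) == 1L) parts  # geneProductAssociation wrapper
  else paste0("(", paste(parts, collapse = " or "), ")")
}

#' Read a stoichiometric model from SBML
#'
#' Supports SBML Level 3 with the \code{fbc} package (flux bounds as
#' parameter references, objectives and gene products as fbc elements) and
#' Level 2 with COBRA-style notes (bounds in \code{kineticLaw} parameters
#' \code{LOWER_BOUND}/\code{UPPER_BOUND}, rules in
#' \code{GENE_ASSOCIATION} note lines). Standard \code{R_}/\code{M_}/
#' \code{G_} id prefixes are stripped; boundary-condition species are
#' dropped from the stoichiometric matrix. Bounds are read as stored:
#' loading the same file twice yields identical models.
#'
#' @param sbml_file Path to the SBML file.
#' @return A [stoich_model()].
#' @export
read_sbml_model <- function(sbml_file) {
  doc <- xml2::read_xml(sbml_file)
  model_node <- .ln(doc, "model")
  if (is.na(model_node)) stop("no <model> element in ", sbml_file)
  mname <- .sbml_attr(model_node, "id")
  if (is.na(mname)) mname <- basename(sbml_file)

  # global parameters (fbc bound references)
  pars <- .ln(doc, "parameter", all = TRUE)
  par_val <- stats::setNames(
    as.numeric(vapply(pars, .sbml_attr, character(1), name = "value")),
    vapply(pars, .sbml_attr, character(1), name = "id"))

  sp_nodes <- .ln(doc, "species", all = TRUE)
  sp_id <- vapply(sp_nodes, .sbml_attr, character(1), name = "id")
  sp_comp <- vapply(sp_nodes, .sbml_attr, character(1), name = "compartment")
  sp_bnd <- vapply(sp_nodes, .sbml_attr, character(1), name = "boundaryCondition")
  keep <- is.na(sp_bnd) | sp_bnd != "true"
  met_ids <- .strip_sbml_prefix(sp_id[keep], "M")
  comp <- stats::setNames(sp_comp[keep], met_ids)

  # fbc gene products: internal id -> label
  gp_nodes <- .ln(doc, "geneProduct", all = TRUE)
  label_of <- list()
  if (length(gp_nodes)) {
    gid <- vapply(gp_nodes, .sbml_attr, character(1), name = "id")
    glab <- vapply(gp_nodes, .sbml_attr, character(1), name = "label")
    glab[is.na(glab)] <- .strip_sbml_prefix(gid[is.na(glab)], "G")
    label_of <- as.list(stats::setNames(glab, gid))
  }

  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  nrx <- length(rx_nodes)
  if (!nrx) stop("no reactions in ", sbml_file)
  rxn_ids <- .strip_sbml_prefix(
    vapply(rx_nodes, .sbml_attr, character(1), name = "id"), "R")

  S <- matrix(0, nrow = length(met_ids), ncol = nrx,
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(nrx)
  gpr <- stats::setNames(rep("", nrx), rxn_ids)
  obj_coef <- numeric(nrx)

  for (i in seq_len(nrx)) {
    node <- rx_nodes[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", side,
                     "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- .strip_sbml_prefix(.sbml_attr(ref, "species"), "M")
        st <- .sbml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sp %in% met_ids) S[sp, i] <- S[sp, i] + sgn * st
      }
    }
    rev_attr <- .sbml_attr(node, "reversible")
    lfb <- .sbml_attr(node, "lowerFluxBound")
    ufb <- .sbml_attr(node, "upperFluxBound")
    if (!is.na(lfb) && !is.na(ufb)) {           # L3 + fbc
      lb[i] <- par_val[[lfb]]; ub[i] <- par_val[[ufb]]
    } else {                                    # L2: kineticLaw parameters
      kl <- xml2::xml_find_all(
        node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      kid <- vapply(kl, .sbml_attr, character(1), name = "id")
      kval <- as.numeric(vapply(kl, .sbml_attr, character(1), name = "value"))
      lb[i] <- if ("LOWER_BOUND" %in% kid) kval[match("LOWER_BOUND", kid)] else
        if (identical(rev_attr, "false")) 0 else -1000
      ub[i] <- if ("UPPER_BOUND" %in% kid) kval[match("UPPER_BOUND", kid)] else 1000
      if ("OBJECTIVE_COEFFICIENT" %in% kid)
        obj_coef[i] <- kval[match("OBJECTIVE_COEFFICIENT", kid)]
    }
    gpa <- .ln(node, "geneProductAssociation")
    rule <- NA_character_
    if (!is.na(gpa)) {
      rule <- .fbc_gpr(gpa, label_of)
    } else {
      notes <- .ln(node, "notes")
      if (!is.na(notes)) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
        if (length(m)) rule <- trimws(sub("GENE_ASSOCIATION:", "", m))
      }
    }
    if (!is.na(rule) && nzchar(rule)) {
      ok <- tryCatch({ .gpr_parse(rule); TRUE }, error = function(e) e)
      if (!isTRUE(ok))
        stop("unparsable GPR for reaction '", rxn_ids[i], "': ",
             conditionMessage(ok))
      gpr[i] <- rule
    }
  }

  # objective: fbc active objective, else L2 OBJECTIVE_COEFFICIENT
  fo <- .ln(doc, "fluxObjective", all = TRUE)
  objective <- NULL
  if (length(fo)) {
    objective <- .strip_sbml_prefix(.sbml_attr(fo[[1]], "reaction"), "R")
  } else if (any(obj_coef != 0)) {
    objective <- rxn_ids[which(obj_coef != 0)[1]]
  }
  if (is.null(objective) || is.na(objective))
    stop("no objective (biomass) reaction declared in ", sbml_file)

  genes <- if (length(label_of)) unique(unlist(label_of, use.names = FALSE))
           else NULL
  stoich_model(S, lb, ub, objective = objective,
               gpr = gpr[nzchar(gpr)], genes = genes,
               compartments = comp, name = mname)
}
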