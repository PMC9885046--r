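#' Specification for a synthetic pathway ensemble
#'
#' Describes an ensemble of pseudo-organisms, each carrying the same mostly
#' linear focal pathway (the backbone) plus side pathways of varied
#' topology that share metabolites with it. Defaults emulate the study
#' conditions of the cross-organism analysis: 29 organisms, a focal
#' backbone of 20 reactions (mid-range of the 15-25 observed across real
#' organisms) and 17 connected side pathways, with a small per-organism
#' reaction dropout standing in for lineage-specific gene loss.
#'
#' @param n_organisms Number of pseudo-organisms.
#' @param backbone_length Reactions in the focal linear pathway.
#' @param n_side_pathways Number of side pathways.
#' @param topologies Side-pathway topologies sampled from
#'   \code{c("linear", "branched", "dense")}.
#' @param side_size Integer range (min, max) of reactions per side pathway.
#' @param attachment_focus Probability that a side pathway attaches at the
#'   designated bridge metabolite (the rest attach uniformly elsewhere on
#'   the backbone); concentrating attachments plants a known
#'   high-betweenness bridge reaction.
#' @param dropout Per-organism, per-reaction dropout probability. On the
#'   backbone, dropout only touches the variable input and terminal
#'   segments (first three and last two reactions), mirroring real focal
#'   pathways whose organisms differ mainly at the input region; the
#'   conserved interior — including the planted bridge — is present in
#'   every organism, so the ground truth stays defined and the spine is
#'   never severed. Side-pathway reactions drop anywhere.
#' @param reversible_prob Probability that a reaction is reversible.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class \code{"ensemble_spec"}.
#' @export
ensemble_spec <- function(n_organisms = 29, backbone_length = 20,
                          n_side_pathways = 17,
                          topologies = c("linear", "branched", "dense"),
                          side_size = c(3L, 8L),
                          attachment_focus = 0.6,
                          dropout = 0.05, reversible_prob = 0.2, seed = 1L) {
  stopifnot(n_organisms >= 1, backbone_length >= 3, n_side_pathways >= 1,
            dropout >= 0, dropout <= 1,
            attachment_focus >= 0, attachment_focus <= 1,
            reversible_prob >= 0, reversible_prob <= 1,
            length(side_size) == 2L, side_size[1] >= 2,
            side_size[2] >= side_size[1])
  structure(list(n_organisms = as.integer(n_organisms),
                 backbone_length = as.integer(backbone_length),
                 n_side_pathways = as.integer(n_side_pathways),
                 topologies = topologies,
                 side_size = as.integer(side_size),
                 attachment_focus = attachment_focus,
                 dropout = dropout, reversible_prob = reversible_prob,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a synthetic pathway ensemble with planted ground truth
#'
#' Builds the backbone and side pathways once, then derives each organism
#' by independent reaction dropout. Metabolite ids are synthetic
#' (\code{"M0001"} ...) and reaction ids \code{"S<pathway>_<index>"}, a
#' namespace deliberately distinct from KEGG so id-mapping code paths get
#' exercised. The ground truth records the planted bridge: the backbone
#' reaction adjacent to the largest number of side-pathway attachment
#' points, which should surface as a betweenness hub in every organism's
#' combined network.
#'
#' @param spec An [ensemble_spec()].
#' @return List with \code{organisms} (named list: organism -> list of
#'   [pathway()] objects, focal pathway first) and \code{truth} (list with
#'   \code{bridge_reaction}, \code{bridge_metabolite}, \code{focal_id},
#'   \code{attachments}).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  L <- spec$backbone_length
  met_counter <- L  # M0000..M<L> are backbone metabolites
  new_met <- function() {
    met_counter <<- met_counter + 1L
    sprintf("M%04d", met_counter)
  }
  bb_met <- sprintf("M%04d", 0:L)
  focal_id <- "SFOC"
  bb_rxns <- lapply(seq_len(L), function(i)
    reaction(sprintf("SFOC_%02d", i), bb_met[i], bb_met[i + 1],
             reversible = stats::runif(1) < spec$reversible_prob))
  names(bb_rxns) <- vapply(bb_rxns, `[[`, character(1), "id")

  bridge_pos <- max(2L, L %/% 2L)
  bridge_met <- bb_met[bridge_pos + 1L]  # product of reaction bridge_pos
  # off-bridge attachments avoid the bridge's flanking metabolites, so the
  # "most attachment points" rule resolves to the bridge unambiguously
  off_bridge <- setdiff(bb_met[2:L],
                        bb_met[bridge_pos:min(L + 1L, bridge_pos + 2L)])

  side_pws <- list()
  attachments <- character(spec$n_side_pathways)
  for (j in seq_len(spec$n_side_pathways)) {
    attach <- if (stats::runif(1) < spec$attachment_focus) bridge_met else
      sample(off_bridge, 1L)
    attachments[j] <- attach
    topo <- sample(spec$topologies, 1L)
    size <- sample(spec$side_size[1]:spec$side_size[2], 1L)
    pid <- sprintf("S%03d", j)
    mets <- attach  # growing pool of side metabolites
    rxns <- list()
    # pathways planted at the bridge metabolite consume it, so traffic into
    # them is mediated by the backbone reaction producing that metabolite —
    # the planted bridge the recovery analysis must find
    consume_first <- attach == bridge_met || stats::runif(1) < 0.5
    for (i in seq_len(size)) {
      if (i == 1L) {
        other <- new_met()
        rxns[[i]] <- if (consume_first)
          reaction(sprintf("%s_%02d", pid, i), attach, other,
                   reversible = stats::runif(1) < spec$reversible_prob)
        else
          reaction(sprintf("%s_%02d", pid, i), other, attach,
                   reversible = stats::runif(1) < spec$reversible_prob)
        mets <- c(mets, other)
      } else {
        from <- if (topo == "linear") mets[length(mets)] else
          sample(setdiff(mets, attach), 1L)
        prod <- new_met()
        rxns[[i]] <- reaction(sprintf("%s_%02d", pid, i), from, prod,
                              reversible = stats::runif(1) < spec$reversible_prob)
        mets <- c(mets, prod)
      }
    }
    if (topo == "dense" && length(mets) >= 4L) {
      extra <- max(1L, size %/% 2L)
      for (e in seq_len(extra)) {
        pair <- sample(setdiff(mets, attach), 2L)
        rxns[[length(rxns) + 1L]] <-
          reaction(sprintf("%s_%02d", pid, length(rxns) + 1L),
                   pair[1], pair[2],
                   reversible = stats::runif(1) < spec$reversible_prob)
      }
    }
    side_pws[[pid]] <- pathway(pid, sprintf("side pathway %d (%s)", j, topo),
                               rxns)
  }

  # planted bridge: backbone reaction touching the most attachment points
  touch <- vapply(bb_rxns, function(r)
    sum(attachments %in% c(r$substrates, r$products)), integer(1))
  bridge_rxn <- names(bb_rxns)[which.max(touch)]
  # backbone dropout only touches the variable input and terminal segments
  # (as in real organisms, whose focal pathways differ mainly at the input
  # region); the conserved interior, including the bridge, is kept intact so
  # dropout never severs the spine between the bridge and its traffic
  variable_bb <- unique(c(seq_len(min(3L, L)), max(1L, L - 1L):L))
  variable_bb <- setdiff(variable_bb, bridge_pos + (-1L:1L))

  organisms <- vector("list", spec$n_organisms)
  names(organisms) <- sprintf("org%02d", seq_len(spec$n_organisms))
  for (o in seq_len(spec$n_organisms)) {
    keep_bb <- rep(TRUE, L)
    keep_bb[variable_bb] <- stats::runif(length(variable_bb)) >= spec$dropout
    if (!any(keep_bb)) stop("dropout removed the whole backbone")
    focal <- pathway(focal_id, "focal backbone pathway", bb_rxns[keep_bb])
    pws <- list(focal)
    for (pid in names(side_pws)) {
      pw <- side_pws[[pid]]
      keep <- stats::runif(length(pw$reactions)) >= spec$dropout
      if (any(keep))
        pws[[length(pws) + 1L]] <- pathway(pid, pw$name, pw$reactions[keep])
    }
    organisms[[o]] <- pws
  }

  list(organisms = organisms,
       truth = list(bridge_reaction = bridge_rxn,
                    bridge_metabolite = bridge_met,
                    focal_id = focal_id,
                    attachments = stats::setNames(attachments,
                                                  names(side_pws))))
}

#' Write an ensemble to disk as reaction tables plus a ground-truth sidecar
#'
#' One TSV per organism and pathway (the dialect of
#' [write_reaction_table()]) under \code{dir/<organism>/<pathway>.tsv}, and
#' the ground truth as \code{dir/truth.json}.
#'
#' @param ens A [generate_ensemble()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, \code{dir}.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (org in names(ens$organisms)) {
    odir <- file.path(dir, org)
    dir.create(odir, showWarnings = FALSE)
    for (pw in ens$organisms[[org]])
      write_reaction_table(pw, file.path(odir, paste0(pw$id, ".tsv")))
  }
  jsonlite::write_json(ens$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Specification for a toy stoichiometric model
#'
#' A linear uptake chain feeding a branch point whose two products are
#' consumed by the biomass reaction with coefficients \code{(a, b)} — the
#' minimal structure in which flux splits between branches according to the
#' biomass coefficients, as in a pathway where chorismate feeds both the
#' tryptophan branch and the phenylalanine/tyrosine branch. Optional
#' isozyme duplicates add an alternate route for chosen chain steps.
#'
#' @param chain_length Number of chain reactions from the imported
#'   metabolite to the branch point (>= 1).
#' @param branch_a,branch_b Biomass coefficients of the two branch
#'   products (both > 0).
#' @param uptake Maximum uptake rate U of the feed metabolite
#'   (mmol/gDW/h).
#' @param isozymes Integer indices of chain reactions to duplicate as
#'   isozyme pairs.
#' @return A list of class \code{"toy_model_spec"}.
#' @export
toy_model_spec <- function(chain_length = 4L, branch_a = 0.3, branch_b = 0.7,
                           uptake = 10, isozymes = integer()) {
  stopifnot(chain_length >= 1, branch_a > 0, branch_b > 0, uptake > 0,
            all(isozymes >= 1), all(isozymes <= chain_length))
  structure(list(chain_length = as.integer(chain_length),
                 branch_a = branch_a, branch_b = branch_b,
                 uptake = uptake, isozymes = as.integer(isozymes)),
            class = "toy_model_spec")
}

#' Generate a toy stoichiometric model with its analytic optimum
#'
#' The chain carries the full uptake U; at the branch point the flux
#' splits in proportion to the biomass coefficients. Writing g for growth,
#' the biomass reaction consumes \code{a g} of one branch product and
#' \code{b g} of the other, so total branch-point demand is
#' \code{(a + b) g = U}, giving \code{g = U / (a + b)} and branch fluxes
#' \code{a g} and \code{b g}. These closed forms are returned alongside
#' the model as the independent record the solver must reproduce.
#'
#' Every internal reaction carries a single dedicated gene
#' (\code{"g_<id>"}); isozyme duplicates get their own gene, so deleting
#' either member of a pair leaves the conversion available.
#'
#' @param spec A [toy_model_spec()].
#' @return List with \code{model} (a [stoich_model()]), \code{truth}
#'   (analytic growth, branch and chain fluxes), \code{reporters}
#'   (section -> reporter reaction) and \code{sections} (reaction ->
#'   section map in the style of [read_section_map()]).
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  k <- spec$chain_length
  a <- spec$branch_a; b <- spec$branch_b; U <- spec$uptake
  mets <- c("A", if (k > 1) sprintf("C%d", seq_len(k - 1)), "X", "P1", "P2")
  chain_ids <- sprintf("T%02d", seq_len(k))
  iso_ids <- if (length(spec$isozymes))
    sprintf("T%02db", spec$isozymes) else character()
  rxn_ids <- c("EX_A", chain_ids, iso_ids, "RP1", "RP2", "BIOMASS")
  S <- matrix(0, length(mets), length(rxn_ids),
              dimnames = list(mets, rxn_ids))
  S["A", "EX_A"] <- -1  # export orientation: uptake is negative flux
  chain_mets <- c("A", if (k > 1) sprintf("C%d", seq_len(k - 1)), "X")
  for (i in seq_len(k)) {
    S[chain_mets[i], chain_ids[i]] <- -1
    S[chain_mets[i + 1], chain_ids[i]] <- 1
  }
  for (j in seq_along(spec$isozymes)) {
    i <- spec$isozymes[j]
    S[chain_mets[i], iso_ids[j]] <- -1
    S[chain_mets[i + 1], iso_ids[j]] <- 1
  }
  S["X", "RP1"] <- -1; S["P1", "RP1"] <- 1
  S["X", "RP2"] <- -1; S["P2", "RP2"] <- 1
  S["P1", "BIOMASS"] <- -a
  S["P2", "BIOMASS"] <- -b
  lb <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
  ub <- stats::setNames(rep(1000, length(rxn_ids)), rxn_ids)
  lb["EX_A"] <- -U
  internal <- c(chain_ids, iso_ids, "RP1", "RP2")
  gpr <- stats::setNames(paste0("g_", internal), internal)
  model <- stoich_model(S, lb, ub, objective = "BIOMASS", gpr = gpr,
                        name = "toy_branch_model")
  g <- U / (a + b)
  truth <- list(growth = g,
                branch_fluxes = c(RP1 = a * g, RP2 = b * g),
                chain_flux = U)
  plain_chain <- setdiff(chain_ids, sprintf("T%02d", spec$isozymes))
  reporter_in <- if (length(plain_chain)) plain_chain[length(plain_chain)]
                 else chain_ids[k]
  reporters <- c(Input = reporter_in, Tryptophan = "RP1", PheTyr = "RP2")
  sections <- stats::setNames(
    c(rep("Input", length(chain_ids) + length(iso_ids)),
      "Tryptophan", "PheTyr"),
    c(chain_ids, iso_ids, "RP1", "RP2"))
  list(model = model, truth = truth, reporters = reporters,
       sections = sections)
}

# GPR string AST -> fbc association XML
.gpr_to_fbc <- function(ast, gene_xml_id) {
  if (is.character(ast))
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   gene_xml_id(ast)))
  tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
  inner <- paste(vapply(ast$args, .gpr_to_fbc, character(1),
                        gene_xml_id = gene_xml_id), collapse = "")
  sprintf("<%s>%s</%s>", tag, inner, tag)
}

#' Write a small model as SBML Level 3 with the fbc package
#'
#' Intended for the toy models of [generate_toy_model()] and test
#' fixtures; bounds become shared parameters, GPR rules become fbc gene
#' product associations and the objective an fbc flux objective, so the
#' file round-trips through [read_sbml_model()].
#'
#' @param model A [stoich_model()].
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_toy_sbml <- function(model, file) {
  stopifnot(inherits(model, "stoich_model"))
  rxn_ids <- colnames(model$S)
  mets <- rownames(model$S)
  bounds <- sort(unique(c(model$lb, model$ub)))
  fmt <- function(v) vapply(v, function(x) format(x, digits = 15), character(1))
  par_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), fmt(bounds))
  pid <- function(v) par_id[[fmt(v)]]
  gene_xml_id <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('<model id="%s" fbc:strict="true">', model$name),
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    sprintf('<species id="M_%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            mets),
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            unname(par_id), fmt(bounds)),
    '</listOfParameters>',
    '<listOfReactions>')
  for (rid in rxn_ids) {
    col <- model$S[, rid]
    subs <- names(col)[col < 0]; prods <- names(col)[col > 0]
    open <- sprintf(paste0('<reaction id="R_%s" reversible="%s" fast="false" ',
                           'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
                    rid, if (model$lb[rid] < 0) "true" else "false",
                    pid(model$lb[rid]), pid(model$ub[rid]))
    body <- character()
    if (length(subs))
      body <- c(body, '<listOfReactants>',
                sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                        subs, fmt(-col[subs])),
                '</listOfReactants>')
    if (length(prods))
      body <- c(body, '<listOfProducts>',
                sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                        prods, fmt(col[prods])),
                '</listOfProducts>')
    rule <- model$gpr[[rid]]
    if (nzchar(rule))
      body <- c(body, '<fbc:geneProductAssociation>',
                .gpr_to_fbc(.gpr_parse(rule), gene_xml_id),
                '</fbc:geneProductAssociation>')
    lines <- c(lines, open, body, '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            model$objective),
    '</fbc:listOfFluxObjectives>', '</fbc:objective>',
    '</fbc:listOfObjectives>')
  if (length(model$genes))
    lines <- c(lines, '<fbc:listOfGeneProducts>',
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       vapply(model$genes, gene_xml_id, character(1)),
                       model$genes),
               '</fbc:listOfGeneProducts>')
  lines <- c(lines, '</model>', '</sbml>')
  writeLines(lines, file)
  invisible(file)
}
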