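#' Construct a reaction record
#'
#' A reaction is the atomic unit of a pathway definition: a set of substrate
#' metabolites converted into a set of product metabolites, optionally
#' reversible, and annotated with the pathway(s) it belongs to. Metabolite
#' identity is by id string only; pathway-level reactions carry no
#' compartment suffixes.
#'
#' @param id Reaction identifier (KEGG-style \code{"R01073"} or model-style
#'   \code{"PHETA1"}). Must be a nonempty string.
#' @param substrates Character vector of substrate metabolite ids (nonempty).
#' @param products Character vector of product metabolite ids (nonempty).
#' @param reversible Logical flag; reversible reactions act as producer and
#'   consumer on both sides when networks are built.
#' @param pathway_ids Character vector of pathway ids this reaction belongs to.
#' @param allow_two_sided Permit a metabolite to appear as both substrate and
#'   product (rare degenerate inputs, e.g. polymerisation shorthands).
#'   Default \code{FALSE}: such input is an error.
#'
#' @return An object of class \code{"reaction"}: a list with fields
#'   \code{id}, \code{substrates}, \code{products}, \code{reversible},
#'   \code{pathway_ids}.
#' @export
#' @examples
#' reaction("R1", "A", "B")
reaction <- function(id, substrates, products, reversible = FALSE,
                     pathway_ids = character(), allow_two_sided = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (length(substrates) == 0L || !all(nzchar(substrates)))
    stop("reaction '", id, "': substrates must be a nonempty set of ids")
  if (length(products) == 0L || !all(nzchar(products)))
    stop("reaction '", id, "': products must be a nonempty set of ids")
  both <- intersect(substrates, products)
  if (length(both) && !allow_two_sided)
    stop("reaction '", id, "': metabolite(s) ", paste(both, collapse = ", "),
         " appear on both sides; set allow_two_sided = TRUE if intended")
  structure(
    list(id = id, substrates = substrates, products = products,
         reversible = isTRUE(reversible),
         pathway_ids = unique(as.character(pathway_ids))),
    class = "reaction")
}

#' Construct a pathway
#'
#' @param id Pathway identifier (e.g. \code{"map00400"}).
#' @param name Human-readable pathway name.
#' @param reactions List of [reaction()] objects; ids must be unique.
#'
#' @return An object of class \code{"pathway"} with fields \code{id},
#'   \code{name} and \code{reactions} (a named list keyed by reaction id).
#' @export
pathway <- function(id, name = id, reactions = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(reactions)) {
    ok <- vapply(reactions, inherits, logical(1), what = "reaction")
    if (!all(ok)) stop("all elements of 'reactions' must be reaction objects")
    ids <- vapply(reactions, `[[`, character(1), "id")
    if (anyDuplicated(ids))
      stop("duplicate reaction id(s) in pathway '", id, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    # tag each reaction with its pathway membership
    reactions <- lapply(reactions, function(r) {
      r$pathway_ids <- unique(c(r$pathway_ids, id))
      r
    })
    names(reactions) <- ids
  }
  structure(list(id = id, name = name, reactions = reactions),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", x$id, if (!identical(x$name, x$id)) paste0(" (", x$name, ")"),
      ": ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' @export
print.reaction <- function(x, ...) {
  arrow <- if (x$reversible) "<=>" else "-->"
  cat("<reaction> ", x$id, ": ",
      paste(x$substrates, collapse = " + "), " ", arrow, " ",
      paste(x$products, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' All metabolites touched by a pathway or set of reactions
#'
#' Union of substrates and products over all reactions, minus any excluded
#' (currency) metabolites.
#'
#' @param x A \code{pathway} or a list of \code{reaction} objects.
#' @param excluded Character vector of metabolite ids to drop.
#' @return Character vector of metabolite ids.
#' @export
pathway_metabolites <- function(x, excluded = character()) {
  rxns <- if (inherits(x, "pathway")) x$reactions else x
  mets <- unlist(lapply(rxns, function(r) c(r$substrates, r$products)),
                 use.names = FALSE)
  setdiff(unique(mets), excluded)
}

#' Read a pathway section map
#'
#' A section map assigns pathway reactions to named sections of the focal
#' pathway (for the aromatic amino acid pathway: Input, Shikimate,
#' Tryptophan, and the joint Phenylalanine/Tyrosine section). The file is a
#' two-column TSV with header \code{reaction_id<TAB>section}.
#'
#' @param file Path to the TSV file.
#' @param sections Allowed section labels.
#' @return Named character vector mapping reaction id to section label.
#' @export
read_section_map <- function(file,
                             sections = c("Input", "Shikimate",
                                          "Tryptophan", "PheTyr")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "section") %in% names(tab)))
    stop("section map must have columns 'reaction_id' and 'section'")
  bad <- setdiff(unique(tab$section), sections)
  if (length(bad))
    stop("unknown section label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$reaction_id))
    stop("reaction(s) mapped to more than one section: ",
         paste(unique(tab$reaction_id[duplicated(tab$reaction_id)]),
               collapse = ", "))
  stats::setNames(tab$section, tab$reaction_id)
}
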