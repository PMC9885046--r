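#' Parse a KGML pathway file
#'
#' Reads a KEGG KGML XML file and returns the pathway's reactions. Only
#' \code{<reaction>} elements create reactions; \code{<entry>} elements of
#' type \code{"map"} (hyperlinks to other pathways) are ignored, since
#' network edges must come from shared chemistry and not cross-references.
#' Compound ids are normalised by stripping the \code{"cpd:"} prefix and
#' reaction ids by stripping \code{"rn:"}. A KGML reaction whose
#' \code{name} attribute carries several space-separated ids yields one
#' reaction per id, sharing the same substrates and products.
#'
#' @param xml_file Path to a KGML file.
#' @return A [pathway()] object. Reversibility follows the KGML
#'   \code{type} attribute (\code{"reversible"} vs \code{"irreversible"}).
#'   Reaction entries lacking substrates or products are skipped with a
#'   warning.
#' @export
parse_kgml <- function(xml_file) {
  doc <- xml2::read_xml(xml_file)  # malformed XML errors here
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML file (no <pathway> root): ", xml_file)
  pid <- sub("^path:", "", xml2::xml_attr(root, "name"))
  if (is.na(pid)) pid <- basename(xml_file)
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  rxn_nodes <- xml2::xml_find_all(doc, "//reaction")
  rxns <- list()
  for (node in rxn_nodes) {
    ids <- strsplit(xml2::xml_attr(node, "name"), "\\s+")[[1]]
    ids <- sub("^rn:", "", ids[nzchar(ids)])
    subs <- .kgml_compounds(node, "substrate")
    prods <- .kgml_compounds(node, "product")
    if (!length(subs) || !length(prods)) {
      warning("KGML reaction '", paste(ids, collapse = " "),
              "' lacks substrates or products; skipped", call. = FALSE)
      next
    }
    rev <- identical(xml2::xml_attr(node, "type"), "reversible")
    for (id in ids)
      rxns[[length(rxns) + 1L]] <- reaction(id, subs, prods, reversible = rev)
  }
  pathway(pid, pname, rxns)
}

.kgml_compounds <- function(node, what) {
  kids <- xml2::xml_find_all(node, what)
  ids <- xml2::xml_attr(kids, "name")
  unique(sub("^cpd:", "", ids[!is.na(ids) & nzchar(ids)]))
}

#' Read a pathway from a tabular reaction file
#'
#' The tabular dialect is a TSV with header columns \code{reaction_id},
#' \code{substrates}, \code{products}, \code{reversible}, \code{pathway_id};
#' metabolite lists are semicolon-separated and reversibility is the literal
#' \code{"1"} or \code{"0"}.
#'
#' @param tsv_file Path to the TSV file.
#' @return A [pathway()] object equivalent to what [parse_kgml()] would
#'   return for the same content.
#' @export
parse_reaction_table <- function(tsv_file) {
  tab <- utils::read.delim(tsv_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("reaction_id", "substrates", "products", "reversible", "pathway_id")
  if (!all(need %in% names(tab)))
    stop("reaction table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$reaction_id))
    stop("duplicate reaction id(s): ",
         paste(unique(tab$reaction_id[duplicated(tab$reaction_id)]),
               collapse = ", "))
  bad <- setdiff(unique(tab$reversible), c("0", "1"))
  if (length(bad))
    stop("unknown reversibility token(s): ", paste(bad, collapse = ", "),
         " (expected '0' or '1')")
  pid <- if (nrow(tab)) tab$pathway_id[1] else
    sub("\\.tsv$", "", basename(tsv_file))
  rxns <- lapply(seq_len(nrow(tab)), function(i)
    reaction(tab$reaction_id[i],
             strsplit(tab$substrates[i], ";", fixed = TRUE)[[1]],
             strsplit(tab$products[i], ";", fixed = TRUE)[[1]],
             reversible = tab$reversible[i] == "1"))
  pathway(pid, pid, rxns)
}

#' Write a pathway in the tabular reaction dialect
#'
#' Inverse of [parse_reaction_table()]: parse-write-parse round trips are
#' the identity.
#'
#' @param pw A [pathway()] object.
#' @param tsv_file Output path.
#' @return Invisibly, the output path.
#' @export
write_reaction_table <- function(pw, tsv_file) {
  stopifnot(inherits(pw, "pathway"))
  rows <- lapply(pw$reactions, function(r)
    data.frame(reaction_id = r$id,
               substrates = paste(r$substrates, collapse = ";"),
               products = paste(r$products, collapse = ";"),
               reversible = if (r$reversible) "1" else "0",
               pathway_id = pw$id,
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), substrates = character(),
               products = character(), reversible = character(),
               pathway_id = character())
  utils::write.table(tab, tsv_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_file)
}

#' Write a network edge list
#'
#' One \code{source<TAB>target} line per directed edge; antiparallel pairs
#' (reversible-reaction double edges) appear as two lines.
#'
#' @param net A [build_reaction_network()] result.
#' @param file Output path.
#' @return Invisibly, the output path.
#' @export
write_edge_list <- function(net, file) {
  stopifnot(inherits(net, "reaction_network"))
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a reaction id mapping table
#'
#' Maps one reaction-id namespace onto another (e.g. KEGG R-numbers to
#' model BiGG-style ids) via a two-column TSV with header
#' \code{from<TAB>to}. No name matching is attempted: the mapping is a pure
#' lookup, so applying it twice equals applying it once for ids outside the
#' target namespace overlap.
#'
#' @param file Path to the TSV file.
#' @return Named character vector (names = source ids, values = target ids).
#' @export
read_id_map <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("from", "to") %in% names(tab)))
    stop("id map must have columns 'from' and 'to'")
  if (anyDuplicated(tab$from))
    stop("duplicate source id(s) in id map")
  stats::setNames(tab$to, tab$from)
}

#' Apply an id mapping to a vector of ids
#'
#' Ids present in the map are translated; all others pass through
#' unchanged.
#'
#' @param ids Character vector.
#' @param map Named character vector as from [read_id_map()].
#' @return Character vector of the same length.
#' @export
apply_id_map <- function(ids, map) {
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  ids
}
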