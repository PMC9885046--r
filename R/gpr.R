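# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR is a boolean expression over gene ids with operators "and"/"or"
# (case-insensitive) and parentheses, e.g. "(b0001 and b0002) or b0003".
# "and" encodes an enzyme complex (all subunits required), "or" encodes
# isozymes (alternate catalysts).

.gpr_tokenize <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parse into nested list AST:
#   gene -> character scalar; list(op = "and"/"or", args = list(...))
# expr := term ("or" term)* ; term := factor ("and" factor)*
.gpr_parse <- function(s) {
  toks <- .gpr_tokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR expression")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("unexpected token '", t, "' in GPR")
    t
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  if (!length(toks)) return(NULL)
  e <- parse_expr()
  if (pos <= length(toks))
    stop("trailing token '", toks[pos], "' in GPR")
  e
}

.gpr_genes_ast <- function(ast) {
  if (is.null(ast)) return(character())
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, .gpr_genes_ast)))
}

.gpr_eval_ast <- function(ast, present) {
  if (is.null(ast)) return(TRUE)  # no rule: always catalyzable
  if (is.character(ast)) return(ast %in% present)
  vals <- vapply(ast$args, .gpr_eval_ast, logical(1), present = present)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR string
#'
#' @param gpr GPR rule string; \code{""} means no rule.
#' @return Character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(gpr) .gpr_genes_ast(.gpr_parse(gpr))

#' Evaluate a GPR rule against a set of present genes
#'
#' @param gpr GPR rule string; the empty rule evaluates \code{TRUE}
#'   (spontaneous / unannotated reactions stay active).
#' @param present Character vector of genes still present.
#' @return \code{TRUE} if the reaction can be catalysed.
#' @export
#' @examples
#' eval_gpr("(g1 and g2) or g3", present = "g3")   # TRUE
#' eval_gpr("g1 and g2", present = "g1")           # FALSE
eval_gpr <- function(gpr, present) .gpr_eval_ast(.gpr_parse(gpr), present)
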