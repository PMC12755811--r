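## Gene-protein-reaction (GPR) rules.
##
## Infix boolean grammar over gene ids with the usual COBRA semantics:
## AND joins subunits of a complex (all genes required), OR joins
## isozymes (any gene suffices), parentheses group. The empty rule means
## "no known gene": the reaction is unaffected by any knockout.

.gprTokenize <- function(gpr) {
  toks <- regmatches(gpr,
    gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+|&+|\\|+", gpr))[[1]]
  norm <- tolower(toks)
  toks[norm %in% c("and", "&", "&&")] <- "AND"
  toks[norm %in% c("or", "|", "||")] <- "OR"
  toks
}

## recursive descent:  expr := term (OR term)* ; term := fac (AND fac)* ;
## fac := gene | "(" expr ")".  Returns a nested list tree.
.gprParse <- function(gpr) {
  toks <- .gprTokenize(gpr)
  if (length(toks) == 0L) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "OR") {
      advance()
      node <- list(op = "OR", args = list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_fac()
    while (!is.na(peek()) && peek() == "AND") {
      advance()
      node <- list(op = "AND", args = list(node, parse_fac()))
    }
    node
  }
  parse_fac <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: unexpected end in '", gpr, "'")
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        stop("malformed GPR rule: missing ')' in '", gpr, "'")
      advance()
      return(node)
    }
    if (t %in% c(")", "AND", "OR"))
      stop("malformed GPR rule: unexpected '", t, "' in '", gpr, "'")
    advance()
    list(op = "GENE", gene = t)
  }
  tree <- parse_expr()
  if (pos <= length(toks))
    stop("malformed GPR rule: trailing tokens in '", gpr, "'")
  tree
}

.gprEvalTree <- function(tree, present) {
  switch(tree$op,
    GENE = tree$gene %in% present,
    AND = .gprEvalTree(tree$args[[1]], present) &&
          .gprEvalTree(tree$args[[2]], present),
    OR  = .gprEvalTree(tree$args[[1]], present) ||
          .gprEvalTree(tree$args[[2]], present))
}

#' Evaluate a GPR rule
#'
#' @param gpr infix boolean rule string, e.g. \code{"(g1 and g2) or g3"};
#'   the empty string always evaluates TRUE (no known gene, so no
#'   knockout can silence the reaction).
#' @param present character vector of genes still present.
#' @return logical: is the reaction still catalyzed?
#' @examples
#' gprEval("(g1 and g2) or g3", c("g2", "g3"))  # TRUE via isozyme g3
#' gprEval("g1 and g2", "g1")                   # FALSE, complex broken
#' @export
gprEval <- function(gpr, present) {
  tree <- .gprParse(gpr)
  if (is.null(tree)) return(TRUE)
  .gprEvalTree(tree, present)
}

#' Genes referenced by a GPR rule
#'
#' @param gpr rule string.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gprGenes <- function(gpr) {
  if (is.na(gpr) || !nzchar(gpr)) return(character(0))
  toks <- .gprTokenize(gpr)
  unique(toks[!toks %in% c("AND", "OR", "(", ")")])
}
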