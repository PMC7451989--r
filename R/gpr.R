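## Gene-protein-reaction (GPR) boolean logic.
##
## Grammar: parenthesised infix expressions over gene identifiers with
## case-insensitive `and` / `or`; `and` binds tighter than `or`.  An empty
## string is a valid GPR meaning "no gene requirement".  Trees are nested
## lists: a leaf is a character scalar (gene id), an inner node is
## list(op = "and"|"or", args = list(...)).

#' Parse a gene-protein-reaction expression
#'
#' Parses a boolean GPR string such as \code{"(ZMO1500 and ZMO1502) or
#' ZMO0000"} into a tree. \code{and} denotes protein-complex subunits (all
#' required), \code{or} denotes isozymes (any suffices).
#'
#' @param x character scalar; may be \code{""} or \code{NA} (no GPR).
#' @return A GPR tree (nested list), or \code{NULL} for an empty GPR.
#' @examples
#' parseGPR("a and (b or c)")
#' @export
parseGPR <- function(x) {
  if (length(x) != 1L) stop("parseGPR: expected a single string")
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gprTokenize(x)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop("parseGPR: unexpected token '", st$toks[st$pos], "' in: ", x)
  tree
}

gprTokenize <- function(x) {
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gprParseOr <- function(st) {
  args <- list(gprParseAnd(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gprParseAnd(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gprParseAnd <- function(st) {
  args <- list(gprParseAtom(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gprParseAtom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gprParseAtom <- function(st) {
  tk <- gprPeek(st)
  if (is.na(tk)) stop("parseGPR: unexpected end of expression")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st)
    if (is.na(gprPeek(st)) || gprPeek(st) != ")")
      stop("parseGPR: missing closing parenthesis")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("parseGPR: unexpected token '", tk, "'")
  st$pos <- st$pos + 1L
  tk
}

#' Evaluate a GPR tree under a set of gene deletions
#'
#' @param gpr a GPR tree from \code{\link{parseGPR}} (or \code{NULL}).
#' @param deleted character vector of deleted gene ids.
#' @return \code{TRUE} if the reaction remains active, \code{FALSE} otherwise.
#'   A reaction with no GPR is unaffected by deletions (always active).
#' @examples
#' evaluateGPR(parseGPR("a and b"), "a")   # FALSE
#' evaluateGPR(parseGPR("a or b"), "a")    # TRUE
#' @export
evaluateGPR <- function(gpr, deleted = character()) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) return(!(gpr %in% deleted))
  vals <- vapply(gpr$args, evaluateGPR, logical(1), deleted = deleted)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR tree
#'
#' @param gpr a GPR tree (or \code{NULL}).
#' @return Character vector of unique gene ids (empty for no GPR).
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gprGenes)))
}

## Genes that sit under a top-level OR, i.e. isozyme alternatives for the
## whole reaction.  Used when mapping coupled-reaction modules to genes,
## where isozyme-bearing mutants are excluded (their deletion phenotype is
## masked by the alternative enzyme).
gprIsozymeGenes <- function(gpr) {
  if (is.null(gpr) || is.character(gpr)) return(character())
  if (gpr$op == "or") gprGenes(gpr) else character()
}

## Render a GPR tree back to its string form.
deparseGPR <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- deparseGPR(a)
    if (!is.character(a) && a$op != gpr$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}
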