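#' Parse a gene-protein-reaction (GPR) rule
#'
#' Rules are boolean expressions over gene identifiers with `and` / `or`
#' (case-insensitive; `&`/`&&` and `|`/`||` also accepted) and parentheses.
#' `and` binds tighter than `or`, as in COBRA-style rules. An empty rule
#' denotes a spontaneous or orphan reaction.
#'
#' @param rule character scalar.
#' @return a parse tree: either a gene id (character scalar) or a list
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$tokens))
    stop("trailing input in gene rule at token '", st$tokens[st$pos], "': ", rule)
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("&&", " and ", rule, fixed = TRUE)
  rule <- gsub("||", " or ", rule, fixed = TRUE)
  rule <- gsub("&", " and ", rule, fixed = TRUE)
  rule <- gsub("|", " or ", rule, fixed = TRUE)
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  if (!length(tokens)) stop("empty gene rule after tokenization")
  tokens
}

gpr_peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("unexpected end of gene rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("unbalanced parenthesis in gene rule")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("unexpected token '", tk, "' in gene rule")
  st$pos <- st$pos + 1L
  tk
}

#' Genes referenced by a rule
#' @param rule character scalar (GPR rule).
#' @return character vector of gene ids (empty for an empty rule).
#' @export
gene_rule_genes <- function(rule) {
  tree <- parse_gene_rule(rule)
  collect <- function(t) {
    if (is.null(t)) return(character())
    if (is.character(t)) return(t)
    unlist(lapply(t$args, collect))
  }
  unique(collect(tree))
}

#' Evaluate a gene rule against a set of inactive genes
#'
#' A gene is active iff it is not in `inactive_genes`. `and` is conjunction,
#' `or` disjunction. An empty rule evaluates to `TRUE` (the reaction is not
#' gene-gated). Genes in `inactive_genes` that do not occur in the rule are
#' ignored: deleting a gene a reaction does not depend on never disables it.
#'
#' @param rule character scalar or pre-parsed tree from [parse_gene_rule()].
#' @param inactive_genes character vector of deleted / switched-off genes.
#' @return logical scalar: can the reaction still be catalysed?
#' @export
evaluate_gene_rule <- function(rule, inactive_genes = character()) {
  tree <- if (is.character(rule) && length(rule) == 1L &&
              !rule %in% c("and", "or")) parse_gene_rule(rule) else rule
  if (is.null(tree)) return(TRUE)
  ev <- function(t) {
    if (is.character(t)) return(!(t %in% inactive_genes))
    vals <- vapply(t$args, ev, logical(1))
    if (t$op == "and") all(vals) else any(vals)
  }
  ev(tree)
}

#' Deparse a gene-rule tree back to its string form
#' @param tree result of [parse_gene_rule()].
#' @return character scalar ("" for NULL).
#' @keywords internal
deparse_gene_rule <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gene_rule(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
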