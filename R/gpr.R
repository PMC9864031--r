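# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR is stored as its infix string ("g1 and (g2 or g3)") and parsed on
# demand into a nested list tree: list(op = "and"/"or", args = list(...)) with
# leaves list(op = "gene", gene = "g1"). The empty string is the constitutive
# rule (no gene control).

#' Parse a GPR rule string
#'
#' Parses an infix gene-protein-reaction rule using `and`/`or` (case
#' insensitive) and parentheses into a boolean expression tree. `or` binds
#' less tightly than `and`, as in the conventions used by SBML-FBC and the
#' COBRA toolbox.
#'
#' @param rule Character scalar, e.g. `"(HK1 or HK2) and GAPDH"`. The empty
#'   string (or `NA`) denotes a constitutive reaction with no gene control.
#' @return A GPR tree (nested list), or `NULL` for the constitutive rule.
#' @examples
#' parse_gpr("(HK1 or HK2) and GAPDH")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$tokens)) {
    stop("GPR parse error near '", st$tokens[st$pos], "' in rule: ", rule)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  tokens[nzchar(tokens)]
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
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("GPR parse error: missing ')'")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'")
  }
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Evaluate a GPR rule under a gene knockout set
#'
#' A reaction is active when its rule evaluates `TRUE` with every gene present
#' except those in `knocked_out`. The constitutive (empty) rule is always
#' active. Evaluation is pure and monotone: enlarging the knockout set can
#' only deactivate reactions.
#'
#' @param gpr A rule string or a tree from [parse_gpr()].
#' @param knocked_out Character vector of deleted gene identifiers.
#' @param genes Optional character vector of genes declared in the model;
#'   knockout ids outside it trigger a warning and are ignored.
#' @return Logical scalar: is the reaction active?
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", knocked_out = "g1")
#' @export
evaluate_gpr <- function(gpr, knocked_out = character(), genes = NULL) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.null(genes) && length(knocked_out)) {
    unknown <- setdiff(knocked_out, genes)
    if (length(unknown)) {
      warning("ignoring unknown gene id(s) in knockout set: ",
              paste(unknown, collapse = ", "))
      knocked_out <- intersect(knocked_out, genes)
    }
  }
  if (is.null(gpr)) return(TRUE)
  gpr_eval(gpr, knocked_out)
}

gpr_eval <- function(node, ko) {
  switch(node$op,
    gene = !(node$gene %in% ko),
    and  = all(vapply(node$args, gpr_eval, logical(1), ko = ko)),
    or   = any(vapply(node$args, gpr_eval, logical(1), ko = ko)),
    stop("invalid GPR node op: ", node$op)
  )
}

#' List the gene identifiers appearing in a GPR rule
#'
#' @param gpr A rule string or parsed tree.
#' @return Character vector of unique gene ids (empty for constitutive rules).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character())
  if (identical(gpr$op, "gene")) return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}
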