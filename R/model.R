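# Metabolic model data structures.
#
# A `metabolic_model` is a list with:
#   metabolites : data.frame(id, name, formula, smiles)
#   reactions   : data.frame(id, name, lower_bound, upper_bound, gpr, pathway,
#                            is_exchange, atp_yield, paper_id)
#   stoich      : named list, one named numeric vector per reaction
#                 (metabolite id -> signed coefficient, negative = consumed)
#   genes       : character vector
#   biomass_id  : reaction id of the growth pseudo-reaction
#
# Metabolite ids follow the two-cell naming convention: a trailing tag letter
# N (neuron), A (astrocyte) or C (cerebellum / extracellular pool).

#' Construct a metabolic model
#'
#' Assembles and validates the container used by every analysis in the
#' package: a stoichiometric network with flux bounds in mmol/gDW/h, GPR
#' rules, pathway labels and a designated biomass reaction.
#'
#' @param metabolites `data.frame` with columns `id`, `name` and optionally
#'   `formula`, `smiles`.
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and optionally `gpr`, `pathway`, `is_exchange`,
#'   `atp_yield`, `paper_id`.
#' @param stoich Named list mapping each reaction id to a named numeric
#'   vector of metabolite coefficients (negative = consumed).
#' @param genes Character vector of gene identifiers. Defaults to the union
#'   of genes appearing in the GPR rules.
#' @param biomass_id Reaction id of the biomass reaction.
#' @return A validated object of class `metabolic_model`.
#' @seealso [validate_model()], [load_model()], [build_stoichiometric_matrix()]
#' @export
metabolic_model <- function(metabolites, reactions, stoich, genes = NULL,
                            biomass_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("formula", "smiles")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  }
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$pathway)) reactions$pathway <- "unassigned"
  if (is.null(reactions$is_exchange)) reactions$is_exchange <- FALSE
  if (is.null(reactions$atp_yield)) reactions$atp_yield <- 0L
  if (is.null(reactions$paper_id)) reactions$paper_id <- NA_character_
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoich = stoich[reactions$id], genes = genes,
         biomass_id = biomass_id),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty ids, legal compartment
#' tags, ordered bounds, non-empty stoichiometries (exchanges excepted),
#' exchange reactions touching exactly one metabolite, GPR leaves declared in
#' the gene list, ATP yields consistent with the stoichiometry of the ATP
#' species, a present biomass reaction, and every metabolite used by at
#' least one reaction.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite id(s): ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (any(!nzchar(mets$id))) stop("empty metabolite id")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction id(s)")
  bad <- rxns$lower_bound > rxns$upper_bound
  if (any(bad)) stop("lower_bound > upper_bound for reaction(s): ",
                     paste(rxns$id[bad], collapse = ", "))
  if (!model$biomass_id %in% rxns$id) {
    stop("biomass reaction '", model$biomass_id, "' not present in model")
  }
  if (!setequal(names(model$stoich), rxns$id)) {
    stop("stoichiometry list does not match reaction ids")
  }
  for (i in seq_len(nrow(rxns))) {
    sto <- model$stoich[[rxns$id[i]]]
    if (length(sto) == 0L && !rxns$is_exchange[i]) {
      stop("empty stoichiometry for non-exchange reaction ", rxns$id[i])
    }
    if (rxns$is_exchange[i] && length(sto) != 1L) {
      stop("exchange reaction ", rxns$id[i],
           " must touch exactly one metabolite")
    }
    unknown <- setdiff(names(sto), mets$id)
    if (length(unknown)) stop("reaction ", rxns$id[i],
      " references undeclared metabolite(s): ", paste(unknown, collapse = ", "))
    atp <- sum(sto[grepl("^atp[NAC]$", names(sto))])
    if (abs(atp - rxns$atp_yield[i]) > 1e-9 && rxns$atp_yield[i] != 0) {
      stop("atp_yield of ", rxns$id[i],
           " disagrees with the ATP stoichiometric coefficient")
    }
    rule_genes <- gpr_genes(rxns$gpr[i])
    if (length(setdiff(rule_genes, model$genes))) {
      stop("GPR of ", rxns$id[i], " uses undeclared gene(s)")
    }
  }
  used <- unique(unlist(lapply(model$stoich, names)))
  orphan <- setdiff(mets$id, used)
  if (length(orphan)) stop("metabolite(s) in no reaction: ",
                           paste(orphan, collapse = ", "))
  tags <- metabolite_tag(mets$id)
  if (any(!is.na(tags) & !tags %in% c("N", "A", "C"))) {
    stop("illegal compartment tag (must be N, A or C)")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  biomass: ", x$biomass_id, "\n", sep = "")
  pw <- sort(table(x$reactions$pathway), decreasing = TRUE)
  cat("  pathways: ", paste(names(pw), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compartment tag of metabolite ids
#'
#' The trailing letter of an id encodes the cell compartment: `N` neuron,
#' `A` astrocyte, `C` cerebellum (extracellular). Ids without a legal
#' trailing tag return `NA`.
#'
#' @param ids Character vector of metabolite ids.
#' @return Character vector of tags (`"N"`, `"A"`, `"C"` or `NA`).
#' @export
metabolite_tag <- function(ids) {
  tag <- substring(ids, nchar(ids))
  ifelse(tag %in% c("N", "A", "C"), tag, NA_character_)
}

# Base species name of a metabolite id (tag stripped): "glcN" -> "glc".
metabolite_base <- function(ids) {
  tag <- metabolite_tag(ids)
  ifelse(is.na(tag), ids, substring(ids, 1L, nchar(ids) - 1L))
}

#' Build the stoichiometric matrix S
#'
#' Returns the sparse metabolite-by-reaction matrix with `S[i, j]` the signed
#' coefficient of metabolite `i` in reaction `j`; steady state is `S v = 0`.
#' Row order follows `model$metabolites`, column order `model$reactions`.
#'
#' @param model A validated `metabolic_model`.
#' @return A `dgCMatrix` of dimension n_metabolites x n_reactions.
#' @export
build_stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    sto <- model$stoich[[j]]
    if (!length(sto)) next
    ii <- c(ii, match(names(sto), met_ids))
    jj <- c(jj, rep.int(j, length(sto)))
    xx <- c(xx, unname(sto))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Map a gene knockout to the reactions it disables
#'
#' Evaluates every GPR under the knockout set; reactions whose rule turns
#' inactive are the disabled set (their flux is pinned to zero downstream).
#'
#' @param model A `metabolic_model`.
#' @param knocked_out Character vector of gene ids.
#' @return Character vector of disabled reaction ids.
#' @export
reactions_disabled_by <- function(model, knocked_out) {
  if (!length(knocked_out)) return(character())
  unknown <- setdiff(knocked_out, model$genes)
  if (length(unknown)) {
    warning("ignoring unknown gene id(s): ", paste(unknown, collapse = ", "))
    knocked_out <- intersect(knocked_out, model$genes)
  }
  rxns <- model$reactions
  has_any <- vapply(rxns$gpr, function(g) {
    length(intersect(gpr_genes(g), knocked_out)) > 0L
  }, logical(1))
  off <- vapply(which(has_any), function(i) {
    !evaluate_gpr(rxns$gpr[i], knocked_out)
  }, logical(1))
  rxns$id[which(has_any)[off]]
}

#' Index of reactions by pathway label
#'
#' @param model A `metabolic_model`.
#' @return Named list mapping each pathway label to its reaction ids.
#' @export
pathway_index <- function(model) {
  split(model$reactions$id, model$reactions$pathway)
}
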