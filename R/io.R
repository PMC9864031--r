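# Model input/output: the package JSON dialect and SBML Level 3 FBC.

#' Load a metabolic model from file
#'
#' Reads either the package JSON dialect (a flat schema with `metabolites`,
#' `reactions`, `genes` and `biomass_id`, GPRs as infix `and`/`or` strings)
#' or SBML Level 3 with the FBC package (flux bounds and gene-product
#' associations). The returned model is validated; bounds, GPR strings and
#' annotations round-trip through [save_model()] without loss.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension by
#'   default.
#' @return A `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Save a metabolic model to file
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"json"` (canonical key order, UTF-8) or `"sbml"`
#'   (Level 3 Version 1 with FBC v2 bounds and GPRs).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# -- JSON dialect -------------------------------------------------------------

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e)))
  need <- c("metabolites", "reactions", "biomass_id")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("model JSON missing element(s): ",
                         paste(miss, collapse = ", "))
  grab <- function(x, f, default) if (is.null(x[[f]])) default else x[[f]]
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) data.frame(
    id = m$id, name = grab(m, "name", m$id),
    formula = grab(m, "formula", NA_character_),
    smiles = grab(m, "smiles", NA_character_),
    stringsAsFactors = FALSE)))
  stoich <- list()
  rxns <- do.call(rbind, lapply(obj$reactions, function(r) {
    sto <- unlist(r$stoichiometry)
    stoich[[r$id]] <<- sto
    data.frame(
      id = r$id, name = grab(r, "name", r$id),
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound),
      gpr = grab(r, "gpr", ""), pathway = grab(r, "pathway", "unassigned"),
      is_exchange = isTRUE(r$is_exchange),
      atp_yield = as.integer(grab(r, "atp_yield", 0L)),
      paper_id = grab(r, "paper_id", NA_character_),
      stringsAsFactors = FALSE)
  }))
  genes <- if (is.null(obj$genes)) NULL else unlist(obj$genes)
  metabolic_model(mets, rxns, stoich, genes, obj$biomass_id)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$smiles)) out$smiles <- m$smiles
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    sto <- model$stoich[[r$id]]
    out <- list(id = r$id, name = r$name,
                stoichiometry = as.list(sto[order(names(sto))]),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gpr = r$gpr, pathway = r$pathway,
                is_exchange = r$is_exchange, atp_yield = r$atp_yield)
    if (!is.na(r$paper_id)) out$paper_id <- r$paper_id
    out
  })
  obj <- list(metabolites = mets, reactions = rxns,
              genes = as.list(model$genes), biomass_id = model$biomass_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# -- SBML Level 3 + FBC -------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)

  unsupported <- xml2::xml_find_all(doc, ".//s:kineticLaw | .//s:listOfRules",
                                    ns)
  if (length(unsupported)) {
    warning("ignoring ", length(unsupported),
            " unsupported SBML construct(s) (kinetic laws / rules)")
  }

  params <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//s:species", ns)
  strip <- function(x) sub("^M_", "", x)
  notes_field <- function(node, key) {
    txt <- xml2::xml_text(xml2::xml_find_all(node, ".//s:notes//*[not(*)]", ns))
    hit <- grep(paste0("^", key, ":"), trimws(txt), value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1])) else
      NA_character_
  }
  mets <- data.frame(
    id = strip(xml2::xml_attr(species, "id")),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  strip(xml2::xml_attr(species, "id")),
                  xml2::xml_attr(species, "name")),
    formula = xml2::xml_attr(species, "chemicalFormula"),
    smiles = vapply(species, notes_field, character(1), key = "SMILES"),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  stoich <- list()
  biomass_id <- NA_character_
  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:objective//fbc:fluxObjective", ns)
  if (!inherits(obj_node, "xml_missing")) {
    biomass_id <- sub("^R_", "", xml2::xml_attr(obj_node, "reaction"))
  }
  rxns <- do.call(rbind, lapply(rx_nodes, function(node) {
    rid <- sub("^R_", "", xml2::xml_attr(node, "id"))
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference",
                               ns)
    sto <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip(xml2::xml_attr(reac, "species"))),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip(xml2::xml_attr(prod, "species"))))
    stoich[[rid]] <<- sto
    gpr_node <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpr_node, "xml_missing")) "" else sbml_gpa_to_infix(
      xml2::xml_find_first(gpr_node, "./*", ns))
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    data.frame(
      id = rid, name = ifelse(is.na(xml2::xml_attr(node, "name")), rid,
                              xml2::xml_attr(node, "name")),
      lower_bound = unname(pval[lb_ref]), upper_bound = unname(pval[ub_ref]),
      gpr = gpr, pathway = {
        pw <- notes_field(node, "PATHWAY"); if (is.na(pw)) "unassigned" else pw
      },
      is_exchange = grepl("^EX_", rid),
      atp_yield = {
        ay <- notes_field(node, "ATP_YIELD")
        if (is.na(ay)) 0L else as.integer(ay)
      },
      paper_id = notes_field(node, "PAPER_ID"),
      stringsAsFactors = FALSE)
  }))
  gp <- xml2::xml_find_all(doc, ".//fbc:geneProduct", ns)
  genes <- sub("^G_", "", xml2::xml_attr(gp, "id"))
  if (!length(genes)) genes <- NULL
  if (is.na(biomass_id)) stop("validation error: no FBC objective ",
                              "(biomass reaction) declared in ", path)
  metabolic_model(mets, rxns, stoich, genes, biomass_id)
}

sbml_gpa_to_infix <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, sbml_gpa_to_infix, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(gsub("[^A-Za-z0-9_]", "_", model$biomass_id)),
    '_model" fbc:strict="true">')

  bounds <- unique(c(model$reactions$lower_bound, model$reactions$upper_bound))
  bid <- function(v) paste0("b_", match(v, bounds))
  w("    <listOfParameters>")
  for (i in seq_along(bounds)) {
    w('      <parameter id="b_', i, '" value="',
      format(bounds[i], digits = 17), '" constant="true"/>')
  }
  w("    </listOfParameters>")

  w("    <listOfCompartments>")
  w('      <compartment id="cell" constant="true"/>')
  w("    </listOfCompartments>")

  w("    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- if (!is.na(m$smiles)) paste0(
      "><notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>SMILES: ",
      esc(m$smiles), "</p></body></notes></species>") else "/>"
    w('      <species id="M_', esc(m$id), '" name="', esc(m$name),
      '" compartment="cell" hasOnlySubstanceUnits="false"',
      ' boundaryCondition="false" constant="false"', extra)
  }
  w("    </listOfSpecies>")

  w("    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    sto <- model$stoich[[r$id]]
    w('      <reaction id="R_', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" fbc:lowerFluxBound="', bid(r$lower_bound),
      '" fbc:upperFluxBound="', bid(r$upper_bound), '">')
    notes <- c(paste0("PATHWAY: ", r$pathway),
               if (r$atp_yield != 0) paste0("ATP_YIELD: ", r$atp_yield),
               if (!is.na(r$paper_id)) paste0("PAPER_ID: ", r$paper_id))
    w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      paste0("<p>", esc(notes), "</p>", collapse = ""), "</body></notes>")
    neg <- sto[sto < 0]; pos <- sto[sto > 0]
    if (length(neg)) {
      w("        <listOfReactants>")
      for (k in seq_along(neg)) {
        w('          <speciesReference species="M_', esc(names(neg)[k]),
          '" stoichiometry="', format(-unname(neg[k]), digits = 17),
          '" constant="true"/>')
      }
      w("        </listOfReactants>")
    }
    if (length(pos)) {
      w("        <listOfProducts>")
      for (k in seq_along(pos)) {
        w('          <speciesReference species="M_', esc(names(pos)[k]),
          '" stoichiometry="', format(unname(pos[k]), digits = 17),
          '" constant="true"/>')
      }
      w("        </listOfProducts>")
    }
    if (nzchar(r$gpr)) {
      w("        <fbc:geneProductAssociation>")
      w("          ", gpr_tree_to_sbml(parse_gpr(r$gpr)))
      w("        </fbc:geneProductAssociation>")
    }
    w("      </reaction>")
  }
  w("    </listOfReactions>")

  w("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w("        <fbc:listOfFluxObjectives>")
  w('          <fbc:fluxObjective fbc:reaction="R_', esc(model$biomass_id),
    '" fbc:coefficient="1"/>')
  w("        </fbc:listOfFluxObjectives>")
  w("      </fbc:objective>")
  w("    </fbc:listOfObjectives>")

  w("    <fbc:listOfGeneProducts>")
  for (g in model$genes) {
    w('      <fbc:geneProduct fbc:id="G_', esc(g), '" fbc:label="', esc(g),
      '"/>')
  }
  w("    </fbc:listOfGeneProducts>")
  w("  </model>")
  w("</sbml>")
  invisible(path)
}

gpr_tree_to_sbml <- function(node) {
  if (identical(node$op, "gene")) {
    return(paste0('<fbc:geneProductRef fbc:geneProduct="G_', node$gene, '"/>'))
  }
  inner <- paste(vapply(node$args, gpr_tree_to_sbml, character(1)),
                 collapse = "")
  paste0("<fbc:", node$op, ">", inner, "</fbc:", node$op, ">")
}

# -- Expression matrices and compound tables ---------------------------------

#' Read a gene-expression matrix with condition labels
#'
#' Expects a series-matrix-style TSV (first column gene ids, header row
#' sample ids, linear-scale values) plus a sidecar YAML mapping samples to
#' condition labels (`samples: {S1: healthy, S2: MB, ...}`).
#'
#' @param path TSV path.
#' @param conditions_path YAML path; defaults to `<path>.yaml`.
#' @return An `expression_matrix` object (see [expression_matrix()]).
#' @export
read_expression_tsv <- function(path, conditions_path = paste0(path, ".yaml")) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  cond <- yaml::read_yaml(conditions_path)$samples
  expression_matrix(as.matrix(tab),
                    conditions = unlist(cond)[colnames(tab)])
}

#' Write an expression matrix and its condition sidecar
#'
#' @param expr An `expression_matrix`.
#' @param path TSV output path; the condition map goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  tab <- data.frame(gene = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(samples = as.list(
    stats::setNames(expr$samples$condition, expr$samples$sample))),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a compound table for the antimetabolite screen
#'
#' @param path TSV with columns `id`, `name`, `smiles`.
#' @return A `data.frame`.
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "smiles")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("compound table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
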