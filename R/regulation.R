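# ZF/ZG scoring and transcriptional-regulation classification.
#
# ZF standardizes the change of a reaction's sampled flux distribution
# between two conditions; ZG standardizes the change of a controlling gene's
# expression between the conditions' sample groups (Welch-type standardized
# mean difference). A reaction's ZG_total sums the ZG scores of all genes in
# its GPR, following the convention of the source analysis (a mean-normalized
# variant is available). Reactions are then classed as transcriptionally
# regulated (TR: both |ZF| and |ZG_total| exceed the critical value) or not
# transcriptionally regulated (NTR: flux changes, expression does not).

#' Z-scores for flux and expression changes
#'
#' @param flux_a,flux_b `sampling_result` objects for the two conditions
#'   (e.g. healthy and MB). ZF is computed on their shared reactions as
#'   `(mean_b - mean_a) / sqrt(var_a + var_b)` from the sampled flux
#'   distributions (0 when the pooled variance is zero).
#' @param expr An [expression_matrix()] covering both conditions.
#' @param cond_a,cond_b Condition labels in `expr`.
#' @param model The `metabolic_model` supplying GPR gene sets.
#' @param log2_expression Standardize on the log2 scale instead of linear.
#' @param zg_aggregate `"sum"` (the reported convention) or `"mean"`
#'   (magnitude-normalized variant for large GPRs).
#' @return `data.frame` with `reaction`, `ZF`, `ZG_total`, `genes`
#'   (semicolon-joined), `n_genes`, `sign_concordant`.
#' @export
compute_z_scores <- function(flux_a, flux_b, expr, cond_a, cond_b, model,
                             log2_expression = FALSE,
                             zg_aggregate = c("sum", "mean")) {
  zg_aggregate <- match.arg(zg_aggregate)
  shared <- intersect(rownames(flux_a$samples), rownames(flux_b$samples))
  xa <- flux_a$samples[shared, , drop = FALSE]
  xb <- flux_b$samples[shared, , drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  zf <- ifelse(va + vb > 0, (mb - ma) / sqrt(va + vb), 0)

  zg_gene <- gene_z_scores(expr, cond_a, cond_b, log2_expression)
  rxns <- model$reactions[match(shared, model$reactions$id), ]
  zg_tot <- numeric(length(shared))
  gene_list <- character(length(shared))
  n_genes <- integer(length(shared))
  for (i in seq_along(shared)) {
    gs <- gpr_genes(rxns$gpr[i])
    n_genes[i] <- length(gs)
    gene_list[i] <- paste(gs, collapse = ";")
    if (!length(gs)) next
    z <- zg_gene[gs]
    miss <- is.na(z)
    if (any(miss)) {
      message("ZG: no expression for gene(s) ",
              paste(gs[miss], collapse = ", "), " - contributing 0")
      z[miss] <- 0
    }
    zg_tot[i] <- if (zg_aggregate == "sum") sum(z) else mean(z)
  }
  data.frame(reaction = shared, ZF = unname(zf), ZG_total = zg_tot,
             genes = gene_list, n_genes = n_genes,
             sign_concordant = sign(zf) == sign(zg_tot) | zg_tot == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Welch-type standardized difference of expression per gene.
gene_z_scores <- function(expr, cond_a, cond_b, log2_expression = FALSE) {
  ia <- expr$samples$condition == cond_a
  ib <- expr$samples$condition == cond_b
  if (!any(ia) || !any(ib)) stop("conditions not found in expression data")
  va <- expr$values[, ia, drop = FALSE]
  vb <- expr$values[, ib, drop = FALSE]
  if (log2_expression) {
    va <- log2(va + 1); vb <- log2(vb + 1)
  }
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa2 <- apply(va, 1L, stats::var) / ncol(va)
  sb2 <- apply(vb, 1L, stats::var) / ncol(vb)
  z <- ifelse(sa2 + sb2 > 0, (mb - ma) / sqrt(sa2 + sb2), 0)
  stats::setNames(z, rownames(expr$values))
}

#' Classify reactions as transcriptionally regulated or not
#'
#' Applies the +/- z_crit decision rule: reactions with `|ZF| > z_crit` are
#' flux-altered; among them, those with `|ZG_total| > z_crit` are
#' transcriptionally regulated (TR) and the rest are not transcriptionally
#' regulated (NTR). Reactions below the flux criterion are classed `none`.
#' The default critical value 1.96 is the two-sided 5% standard-normal
#' quantile. Sign concordance between ZF and ZG is recorded but not required
#' for TR.
#'
#' @param records Output of [compute_z_scores()].
#' @param z_crit Positive critical value (default 1.96).
#' @param model Optional model for per-pathway summary counts.
#' @return The records with a `class` column; when `model` is given, the
#'   result carries a `pathway_counts` attribute (TR/NTR per pathway).
#' @export
classify_regulation <- function(records, z_crit = 1.96, model = NULL) {
  stopifnot(z_crit > 0)
  flux_alt <- abs(records$ZF) > z_crit
  expr_alt <- abs(records$ZG_total) > z_crit
  records$class <- ifelse(flux_alt & expr_alt, "TR",
                          ifelse(flux_alt, "NTR", "none"))
  if (!is.null(model)) {
    pw <- model$reactions$pathway[match(records$reaction,
                                        model$reactions$id)]
    records$pathway <- pw
    tab <- table(pathway = pw, class = factor(records$class,
                                              c("TR", "NTR", "none")))
    attr(records, "pathway_counts") <- tab
  }
  records
}
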