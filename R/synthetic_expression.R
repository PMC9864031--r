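# Synthetic expression-series generator: two-condition gene x sample
# matrices with planted over/under-expressed gene sets and lognormal
# replicate noise, emulating the series-matrix datasets integrated into the
# models (gene-level; no probe structure).

#' Specification for a synthetic expression series
#'
#' @param genes Character vector of gene ids to include (typically the model
#'   genes); filler genes are appended up to `n_genes`.
#' @param n_genes Total number of genes (default 200).
#' @param samples_per_condition Replicates per condition (default 10).
#' @param conditions Two condition labels, reference first.
#' @param planted_up,planted_down Named numeric vectors (or plain character
#'   vectors) of genes whose condition-B mean is multiplied by a fold change
#'   (defaults 4 and 0.05). The two sets must be disjoint and drawn from
#'   `genes`.
#' @param base_mean Mean expression of the listed (model) genes.
#' @param sigma Lognormal replicate noise (sdlog, default 0.3).
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(genes, n_genes = 200L,
                            samples_per_condition = 10L,
                            conditions = c("healthy", "MB"),
                            planted_up = NULL, planted_down = NULL,
                            base_mean = 300, sigma = 0.3) {
  as_folds <- function(x, default) {
    if (is.null(x)) return(numeric(0))
    if (is.numeric(x)) return(x)
    stats::setNames(rep(default, length(x)), x)
  }
  planted_up <- as_folds(planted_up, 4)
  planted_down <- as_folds(planted_down, 0.05)
  if (any(c(planted_up, planted_down) <= 0)) {
    stop("fold changes must be positive")
  }
  if (length(intersect(names(planted_up), names(planted_down)))) {
    stop("planted up/down gene sets must be disjoint")
  }
  unknown <- setdiff(c(names(planted_up), names(planted_down)), genes)
  if (length(unknown)) {
    stop("planted set references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  if (length(conditions) != 2L) stop("exactly two conditions are required")
  structure(list(genes = genes, n_genes = as.integer(n_genes),
                 samples_per_condition = as.integer(samples_per_condition),
                 conditions = conditions, planted_up = planted_up,
                 planted_down = planted_down, base_mean = base_mean,
                 sigma = sigma),
            class = "expression_spec")
}

#' Generate a synthetic two-condition expression series
#'
#' Per-gene baseline means are `base_mean` for the listed genes and drawn
#' from a broad lognormal for filler genes; condition-B means are multiplied
#' by the planted fold changes; every measurement gets lognormal replicate
#' noise. Reproducible for a fixed seed.
#'
#' @param spec An [expression_spec()].
#' @param seed Integer seed.
#' @return List with `expr` (an [expression_matrix()]) and `truth`
#'   (baseline means, folds, and the planted gene sets).
#' @export
generate_expression_series <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(seed)
  n_fill <- max(0L, spec$n_genes - length(spec$genes))
  fill_ids <- sprintf("gene_%04d", seq_len(n_fill))
  gene_ids <- c(spec$genes, fill_ids)
  base <- c(stats::setNames(rep(spec$base_mean, length(spec$genes)),
                            spec$genes),
            stats::setNames(stats::rlnorm(n_fill, log(100), 1), fill_ids))
  fold <- stats::setNames(rep(1, length(gene_ids)), gene_ids)
  fold[names(spec$planted_up)] <- spec$planted_up
  fold[names(spec$planted_down)] <- spec$planted_down

  nsamp <- spec$samples_per_condition
  mk <- function(means, label, offset) {
    vals <- means * matrix(stats::rlnorm(length(means) * nsamp,
                                         -spec$sigma^2 / 2, spec$sigma),
                           nrow = length(means))
    colnames(vals) <- sprintf("%s_%02d", label, seq_len(nsamp))
    vals
  }
  va <- mk(base, spec$conditions[1])
  vb <- mk(base * fold, spec$conditions[2])
  values <- cbind(va, vb)
  rownames(values) <- gene_ids
  expr <- expression_matrix(values,
                            conditions = rep(spec$conditions, each = nsamp))
  truth <- list(base_mean = base, fold = fold,
                planted_up = names(spec$planted_up),
                planted_down = names(spec$planted_down), seed = seed)
  list(expr = expr, truth = truth)
}
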