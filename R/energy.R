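# ATP production accounting and Warburg-effect summary ratios.

#' Energy accounting of a flux state
#'
#' Attributes gross ATP production to pathways and computes the two
#' Warburg-effect indicators: the ratio of ATP produced in glycolysis over
#' ATP produced in OXPHOS (ATPG/ATPOP) and the ratio of lactate excretion to
#' oxygen uptake rate (LacR/OCR). A pathway's ATP production is
#' `sum over its reactions of max(0, atp_yield * flux)`, i.e. only reactions
#' running in their ATP-producing direction contribute.
#'
#' @param model A `metabolic_model` with `atp_yield` annotations.
#' @param v A [flux_vector()] (or named numeric vector of fluxes).
#' @return List with `atp_total`, `atp_by_pathway`, `atp_share_by_pathway`,
#'   `atpg_over_atpop` and `lacr_over_ocr`. Ratios with a zero denominator
#'   are reported as `Inf`.
#' @export
energy_accounting <- function(model, v) {
  if (inherits(v, "flux_vector")) v <- v$fluxes
  rxns <- model$reactions
  prod <- pmax(0, rxns$atp_yield * v[rxns$id])
  atp_by_pathway <- tapply(prod, rxns$pathway, sum)
  atp_by_pathway <- atp_by_pathway[atp_by_pathway > 0 | names(atp_by_pathway)
                                   %in% c("glycolysis", "OXPHOS")]
  atp_by_pathway[is.na(atp_by_pathway)] <- 0
  atp_total <- sum(prod)
  shares <- if (atp_total > 0) atp_by_pathway / atp_total else
    atp_by_pathway * 0
  gly <- if ("glycolysis" %in% names(atp_by_pathway))
    atp_by_pathway[["glycolysis"]] else 0
  oxp <- if ("OXPHOS" %in% names(atp_by_pathway))
    atp_by_pathway[["OXPHOS"]] else 0
  lac <- sum(v[lactate_exchange_ids(model)])
  o2 <- sum(v[oxygen_exchange_ids(model)])
  list(
    atp_total = atp_total,
    atp_by_pathway = as.list(atp_by_pathway),
    atp_share_by_pathway = as.list(shares),
    atpg_over_atpop = if (oxp > 0) gly / oxp else Inf,
    lacr_over_ocr = if (o2 > 0) lac / o2 else if (lac > 0) Inf else 0
  )
}
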