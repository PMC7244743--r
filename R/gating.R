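#' Gate one nodule zone's reaction space with expression calls
#'
#' A reaction of the zone is closed (both bounds set to 0) iff its gene
#' rule is non-empty and evaluates to `FALSE` when the zone's "off" genes
#' are inactive. Exchange and transport reactions and reactions without a
#' gene rule are never gated (gating follows gene evidence; orphan
#' reactions have none). Gating affects only the zone's own copy of each
#' reaction, is monotone (more off genes can only close more reactions) and
#' idempotent.
#'
#' @param holo a `holobiont_model`.
#' @param zone_tag a tissue tag present in the holobiont (e.g.
#'   `"BacteroidIII"`).
#' @param calls an `expression_call_set`; the zone must have an entry
#'   (explicit opt-out requires an empty entry, not a missing one).
#' @return list with `holobiont` (gated) and `report` (a `gating_report`:
#'   `zone`, `closed_reaction_ids`, `kept_ungated`, `calls_used`).
#' @export
gate_zone <- function(holo, zone_tag, calls) {
  if (!zone_tag %in% names(holo$tissue_index))
    stop("unknown zone: ", zone_tag)
  if (!zone_tag %in% names(calls$calls))
    stop("no expression calls for zone ", zone_tag,
         " (an explicit empty entry is required to opt out of gating)")
  inactive <- paste0(zone_tag, "_", off_genes(calls, zone_tag))
  m <- holo$model
  rids <- intersect(holo$tissue_index[[zone_tag]]$reactions, m$reactions$id)
  idx <- match(rids, m$reactions$id)
  closed <- character()
  kept_ungated <- character()
  for (k in seq_along(rids)) {
    i <- idx[k]
    sub <- m$reactions$subsystem[i]
    if (sub %in% c("exchange", "transport")) next
    rule <- m$reactions$gene_rule[i]
    if (!nzchar(rule)) { kept_ungated <- c(kept_ungated, rids[k]); next }
    if (!evaluate_gene_rule(rule, inactive)) closed <- c(closed, rids[k])
  }
  if (length(closed)) m <- close_reactions(m, closed)
  holo$model <- m
  report <- structure(list(zone = zone_tag,
                           closed_reaction_ids = closed,
                           kept_ungated = kept_ungated,
                           calls_used = calls$calls[[zone_tag]]),
                      class = "gating_report")
  list(holobiont = holo, report = report)
}

#' @export
print.gating_report <- function(x, ...) {
  cat("gating of", x$zone, "-", length(x$closed_reaction_ids),
      "reactions closed,", length(x$kept_ungated), "kept ungated\n")
  if (length(x$closed_reaction_ids))
    cat("  closed:", paste(x$closed_reaction_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Derive on/off calls from an abundance matrix
#'
#' A gene is called on in a zone iff its abundance is at least the given
#' quantile of that zone's nonzero abundances. A zone with no nonzero
#' abundance has every gene off. Deterministic.
#'
#' @param table numeric matrix, genes (rows, named) x zones (columns,
#'   named); non-negative.
#' @param threshold_quantile quantile in `[0, 1]`.
#' @return an `expression_call_set`.
#' @export
call_from_abundance <- function(table, threshold_quantile = 0.1) {
  if (!is.matrix(table) || !length(table)) stop("abundance matrix is empty")
  if (any(table < 0)) stop("abundances must be non-negative")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("abundance matrix needs gene row names and zone column names")
  calls <- lapply(colnames(table), function(z) {
    v <- table[, z]
    nz <- v[v > 0]
    if (!length(nz)) return(stats::setNames(rep("off", length(v)), names(v)))
    thr <- stats::quantile(nz, threshold_quantile, names = FALSE)
    stats::setNames(ifelse(v >= thr, "on", "off"), names(v))
  })
  expression_call_set(stats::setNames(calls, colnames(table)))
}
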