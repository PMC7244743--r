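#' Locate the published reconstruction files, when supplied
#'
#' The package's published-model benchmarks (whole-plant growth, cost
#' decomposition ratios, the substrate screen, gene counts) run against the
#' deposited single-organism and integrated reconstructions. Those files
#' are distributed as the study's supplementary data and are not shipped
#' with this package; point `options(vnod.reference_dir = ...)` or the
#' environment variable `VNOD_REFERENCE_DIR` at a directory containing:
#'
#' * `iGD1348.xml` - the rhizobium reconstruction (SBML)
#' * `m_truncatula.xml` - the plant reconstruction (SBML)
#' * `vine.xml` - the integrated nodulated-plant model (SBML)
#' * `substrates.tsv` - the growth-screen substrate table
#'   (columns `exchange`, `experimental_growth`)
#'
#' @return list with `available` (logical), `dir`, and absolute `paths`.
#' @export
reference_models <- function() {
  dir <- getOption("vnod.reference_dir",
                   Sys.getenv("VNOD_REFERENCE_DIR", unset = ""))
  paths <- c(iGD1348 = "iGD1348.xml", m_truncatula = "m_truncatula.xml",
             vine = "vine.xml", substrates = "substrates.tsv")
  if (!nzchar(dir) || !dir.exists(dir))
    return(list(available = FALSE, dir = dir, paths = NULL))
  full <- stats::setNames(file.path(dir, paths), names(paths))
  list(available = all(file.exists(full)), dir = dir, paths = full)
}

#' Unique gene count of a model, ignoring tissue prefixes
#'
#' Multi-tissue models carry one renamed copy of each gene per tissue or
#' zone; this strips a leading `<Tag>_` prefix and counts distinct genes,
#' optionally filtered by a pattern identifying the organism's locus tags.
#'
#' @param model a `metabolic_model`.
#' @param pattern regular expression a gene id (after prefix stripping)
#'   must match, e.g. `"^SM"` for *S. meliloti* locus tags; `NULL` counts all.
#' @return integer count.
#' @export
unique_gene_count <- function(model, pattern = NULL) {
  stripped <- sub("^[A-Za-z0-9]+_", "", model$genes)
  if (!is.null(pattern)) stripped <- grep(pattern, stripped, value = TRUE)
  length(unique(stripped))
}
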