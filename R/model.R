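#' Construct a constraint-based metabolic model
#'
#' The central container of the package. A `metabolic_model` holds
#' metabolites, reactions (with stoichiometry, flux bounds and
#' gene-protein-reaction rules), the gene list, and a linear objective.
#' All fluxes are expressed in umol h-1 (g plant dry weight)-1 unless a
#' reaction is a biomass drain, in which case its flux is in
#' g biomass h-1 (g dry weight)-1.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`. `formula` follows Hill notation; an empty
#'   string denotes a deliberately massless species (photon,
#'   proton-motive quantum, electron), `NA` an unknown formula.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`.
#' @param stoichiometry named list (by reaction id) of named numeric
#'   vectors (by metabolite id); negative coefficients are consumed.
#' @param genes character vector of gene identifiers.
#' @param objective named numeric vector of reaction weights.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = character(), objective = numeric()) {
  m <- structure(
    list(id = id,
         metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
         reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
         stoichiometry = stoichiometry,
         genes = as.character(genes),
         objective = objective),
    class = "metabolic_model")
  validate_model(m)
  m
}

empty_model <- function(id = "empty") {
  metabolic_model(
    id,
    data.frame(id = character(), name = character(), formula = character(),
               charge = numeric(), compartment = character(),
               stringsAsFactors = FALSE),
    data.frame(id = character(), name = character(), lower_bound = numeric(),
               upper_bound = numeric(), gene_rule = character(),
               subsystem = character(), stringsAsFactors = FALSE),
    stats::setNames(list(), character()))
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks identifier uniqueness, bound ordering, resolution of every
#' stoichiometry key and objective key, non-empty compartments, and that
#' every gene referenced by a gene rule is present in the gene list.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending ids.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicated metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicated reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (nrow(mets) && any(!nzchar(mets$compartment) | is.na(mets$compartment)))
    stop("metabolites with empty compartment: ",
         paste(mets$id[!nzchar(mets$compartment) | is.na(mets$compartment)],
               collapse = ", "))
  bad <- rxns$lower_bound > rxns$upper_bound
  if (any(bad))
    stop("lower_bound > upper_bound for: ", paste(rxns$id[bad], collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns$id))
    stop("stoichiometry list does not match reaction ids")
  dangling <- setdiff(unique(unlist(lapply(model$stoichiometry, names))), mets$id)
  if (length(dangling))
    stop("dangling metabolite references: ", paste(dangling, collapse = ", "))
  if (any(vapply(model$stoichiometry, length, 1L) == 0L))
    stop("reactions with empty stoichiometry: ",
         paste(rxns$id[vapply(model$stoichiometry, length, 1L) == 0L],
               collapse = ", "))
  if (length(model$objective)) {
    bad <- setdiff(names(model$objective), rxns$id)
    if (length(bad))
      stop("objective references unknown reactions: ", paste(bad, collapse = ", "))
  }
  rule_genes <- unique(unlist(lapply(rxns$gene_rule, function(r)
    if (is.na(r) || !nzchar(r)) character() else gene_rule_genes(r))))
  missing <- setdiff(rule_genes, model$genes)
  if (length(missing))
    stop("gene rules reference genes absent from the gene list: ",
         paste(missing, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " in ", length(unique(x$metabolites$compartment)), " compartments\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(exchange_reactions(x) %in% x$reactions$id), " exchanges)\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  if (length(x$objective))
    cat("  objective:   ", paste(sprintf("%g %s", x$objective, names(x$objective)),
                                 collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  comp <- table(object$metabolites$compartment)
  cat("model", object$id, "-", nrow(object$reactions), "reactions,",
      nrow(object$metabolites), "metabolites,", length(object$genes), "genes\n")
  cat("metabolites per compartment:\n")
  print(comp)
  rev <- sum(object$reactions$lower_bound < 0 & object$reactions$upper_bound > 0)
  cat("reversible reactions:", rev, "\n")
  invisible(object)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Reactions with exactly one participating metabolite (exchanges, demands,
#' sinks)
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  names(model$stoichiometry)[vapply(model$stoichiometry, length, 1L) == 1L]
}

## --- small mutators used throughout assembly -------------------------------

add_reaction <- function(model, id, stoich, lb = 0, ub = 1000, gene_rule = "",
                         name = id, subsystem = "") {
  if (id %in% model$reactions$id) stop("reaction id exists: ", id)
  missing <- setdiff(names(stoich), model$metabolites$id)
  if (length(missing)) stop("unknown metabolites in ", id, ": ",
                            paste(missing, collapse = ", "))
  model$reactions <- rbind(model$reactions, data.frame(
    id = id, name = name, lower_bound = lb, upper_bound = ub,
    gene_rule = gene_rule, subsystem = subsystem, stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoich
  new_genes <- setdiff(if (nzchar(gene_rule)) gene_rule_genes(gene_rule)
                       else character(), model$genes)
  model$genes <- c(model$genes, new_genes)
  model
}

add_metabolite <- function(model, id, name = id, formula = NA_character_,
                           charge = 0, compartment) {
  if (id %in% model$metabolites$id) stop("metabolite id exists: ", id)
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, formula = formula, charge = charge,
    compartment = compartment, stringsAsFactors = FALSE))
  model
}

#' Set flux bounds of a reaction
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction: ", paste(id[is.na(i)], collapse = ", "))
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}

get_bounds <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction: ", paste(id[is.na(i)], collapse = ", "))
  cbind(lower = model$reactions$lower_bound[i],
        upper = model$reactions$upper_bound[i])
}

close_reactions <- function(model, ids) set_bounds(model, ids, lb = 0, ub = 0)

drop_reactions <- function(model, ids) {
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

drop_orphan_metabolites <- function(model) {
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  model$metabolites <-
    model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  model
}
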