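#' Remove reactions producing or consuming dead-end metabolites
#'
#' A metabolite is a dead end when, given the current flux bounds, no
#' reaction can produce it or no reaction can consume it (a reversible
#' reaction counts on both sides; exchange and sink reactions count as
#' producers/consumers like any other). All reactions touching a dead-end
#' metabolite can never carry steady-state flux, so they are removed, and
#' the scan is iterated to a fixpoint. The result is independent of removal
#' order and the operation is idempotent.
#'
#' Reactions carrying objective weight are never removed; if the fixpoint
#' would remove one, an error identifies it.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` (pruned) and `removed` (character vector of
#'   removed reaction ids, in removal order).
#' @export
remove_dead_ends <- function(model) {
  removed <- character()
  repeat {
    rx <- model$reactions
    producers <- new.env(parent = emptyenv())
    consumers <- new.env(parent = emptyenv())
    touching <- new.env(parent = emptyenv())
    for (j in seq_len(nrow(rx))) {
      st <- model$stoichiometry[[j]]
      fwd <- rx$upper_bound[j] > 0
      rev <- rx$lower_bound[j] < 0
      for (k in seq_along(st)) {
        met <- names(st)[k]
        pos <- st[k] > 0
        assign(met, c(get0(met, touching, ifnotfound = character()), rx$id[j]), touching)
        can_produce <- (pos && fwd) || (!pos && rev)
        can_consume <- (!pos && fwd) || (pos && rev)
        if (can_produce) assign(met, c(get0(met, producers, ifnotfound = character()), rx$id[j]), producers)
        if (can_consume) assign(met, c(get0(met, consumers, ifnotfound = character()), rx$id[j]), consumers)
      }
    }
    dead <- character()
    for (met in model$metabolites$id) {
      if (!length(get0(met, touching, ifnotfound = character()))) next  # orphan
      p <- get0(met, producers, ifnotfound = character())
      co <- get0(met, consumers, ifnotfound = character())
      if (length(p) == 0L || length(co) == 0L) dead <- c(dead, met)
    }
    if (!length(dead)) break
    to_remove <- unique(unlist(lapply(dead, function(met)
      get0(met, touching, ifnotfound = character()))))
    hit_obj <- intersect(to_remove, names(model$objective)[model$objective != 0])
    if (length(hit_obj))
      stop("dead-end pruning would remove objective reaction(s): ",
           paste(hit_obj, collapse = ", "),
           " (dead-end metabolite upstream of the objective)")
    model <- drop_reactions(model, to_remove)
    removed <- c(removed, to_remove)
  }
  model <- drop_orphan_metabolites(model)
  list(model = model, removed = removed)
}
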