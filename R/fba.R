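## Flux balance analysis on top of the bounded-variable simplex in src/.
## Closed reactions (both bounds zero) are dropped from the linear program
## and reported as zero flux; metabolite rows without entries are dropped.

as_model <- function(x) {
  if (inherits(x, "holobiont_model")) x$model
  else if (inherits(x, "metabolic_model")) x
  else stop("expected a metabolic_model or holobiont_model")
}

build_lp <- function(model, extra_cols = NULL) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  act <- !(lb == 0 & ub == 0)
  S <- S[, act, drop = FALSE]
  lb <- lb[act]; ub <- ub[act]
  rows <- rowSums(S != 0) > 0
  S <- S[rows, , drop = FALSE]
  list(S = S, lb = lb, ub = ub, active = model$reactions$id[act])
}

lp_status <- function(code) {
  switch(as.character(code), "0" = "optimal", "1" = "infeasible",
         "2" = "unbounded", "numerical")
}

make_solution <- function(model, lp, res) {
  status <- lp_status(res$status)
  if (status != "optimal") {
    sol <- list(objective_value = NA_real_, fluxes = NULL, status = status)
  } else {
    fl <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
    fl[lp$active] <- res$x
    sol <- list(objective_value = res$objective, fluxes = fl,
                status = "optimal")
  }
  class(sol) <- "flux_solution"
  sol
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 6))
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the model objective subject to steady state (`S v = 0`) and
#' the flux bounds. The objective value is the unique LP optimum; the flux
#' vector may be one of several degenerate optima (see [pfba()] for
#' reproducible flux routes).
#'
#' @param x a `metabolic_model` or `holobiont_model`.
#' @return a `flux_solution`: `objective_value`, named `fluxes`, `status`
#'   in `optimal` / `infeasible` / `unbounded` / `numerical`.
#' @export
fba <- function(x) {
  model <- as_model(x)
  if (!length(model$objective)) stop("model has no objective")
  lp <- build_lp(model)
  cc <- stats::setNames(rep(0, length(lp$active)), lp$active)
  keep <- intersect(names(model$objective), lp$active)
  cc[keep] <- model$objective[keep]
  res <- .simplex_solve(lp$S, numeric(nrow(lp$S)), as.numeric(cc),
                        lp$lb, lp$ub, TRUE)
  make_solution(model, lp, res)
}

#' Parsimonious FBA
#'
#' Fixes the objective at `fraction` of its optimum and minimises the total
#' absolute flux, giving a reproducible flux vector among the degenerate
#' optima (each reaction is split into forward and reverse non-negative
#' components).
#'
#' @param x model or holobiont.
#' @param fraction objective floor as a fraction of the optimum
#'   (default 0.9999).
#' @return a `flux_solution`; `objective_value` is the original (biomass)
#'   objective at the parsimonious solution.
#' @export
pfba <- function(x, fraction = 0.9999) {
  model <- as_model(x)
  base <- fba(model)
  if (base$status != "optimal") return(base)
  lp <- build_lp(model)
  n <- ncol(lp$S)
  cc <- stats::setNames(rep(0, length(lp$active)), lp$active)
  keep <- intersect(names(model$objective), lp$active)
  cc[keep] <- model$objective[keep]
  ## split v = vf - vr, vf, vr >= 0; add the objective floor row
  A <- rbind(cbind(lp$S, -lp$S), c(as.numeric(cc), -as.numeric(cc)))
  b <- c(numeric(nrow(lp$S)), 0)
  ## floor via a slack column on the objective row
  A <- cbind(A, c(numeric(nrow(lp$S)), -1))
  zstar <- base$objective_value
  floor <- if (zstar >= 0) fraction * zstar else (2 - fraction) * zstar
  lbf <- pmax(lp$lb, 0); ubf <- pmax(lp$ub, 0)
  lbr <- pmax(-lp$ub, 0); ubr <- pmax(-lp$lb, 0)
  lbx <- c(lbf, lbr, floor)
  ubx <- c(ubf, ubr, Inf)
  cost <- c(rep(1, 2 * n), 0)
  res <- .simplex_solve(A, b, cost, lbx, ubx, FALSE)
  if (res$status != 0) {
    sol <- list(objective_value = NA_real_, fluxes = NULL,
                status = lp_status(res$status))
    class(sol) <- "flux_solution"
    return(sol)
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fl <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  fl[lp$active] <- v
  sol <- list(objective_value = sum(cc * v), fluxes = fl, status = "optimal")
  class(sol) <- "flux_solution"
  sol
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being at
#' least `fraction` of its optimum (default 0.99, the published setting).
#'
#' @param x model or holobiont.
#' @param fraction objective floor fraction.
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame `reaction_id`, `min`, `max` (an `fva_result`);
#'   attribute `optimum` carries the base optimum.
#' @export
fva <- function(x, fraction = 0.99, reactions = NULL) {
  model <- as_model(x)
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  lp <- build_lp(model)
  cc <- stats::setNames(rep(0, length(lp$active)), lp$active)
  keep <- intersect(names(model$objective), lp$active)
  cc[keep] <- model$objective[keep]
  ## objective floor row with slack column whose lower bound is tightened
  A <- rbind(cbind(lp$S, 0), c(as.numeric(cc), -1))
  b <- numeric(nrow(A))
  lbx <- c(lp$lb, -Inf); ubx <- c(lp$ub, Inf)
  cols <- match(reactions, lp$active)
  live <- !is.na(cols)
  res <- .simplex_fva(A, b, c(as.numeric(cc), 0), lbx, ubx,
                      floor_col = length(lbx), frac = fraction,
                      cols = as.integer(cols[live]))
  if (res$status != 0)
    stop("flux variability analysis failed: base problem ", lp_status(res$status))
  out <- data.frame(reaction_id = reactions,
                    min = 0, max = 0, stringsAsFactors = FALSE)
  out$min[live] <- res$min
  out$max[live] <- res$max
  attr(out, "optimum") <- res$optimum
  attr(out, "fraction") <- fraction
  class(out) <- c("fva_result", "data.frame")
  out
}

## prefixed copies of a gene across tissues (holobiont), or the gene itself
gene_copies <- function(holo, gene, scope = "global") {
  if (scope == "global") {
    tags <- names(holo$tissue_index)
  } else {
    if (!scope %in% names(holo$tissue_index)) stop("unknown tissue: ", scope)
    tags <- scope
  }
  copies <- paste0(tags, "_", gene)
  copies <- copies[copies %in% unlist(lapply(holo$tissue_index[tags], `[[`, "genes"),
                                      use.names = FALSE)]
  copies
}

#' Simulate a gene deletion
#'
#' Marks all tissue copies of the gene(s) inactive (`scope = "global"`) or
#' only one tissue's copy, closes every reaction whose gene rule evaluates
#' to false, and re-solves the FBA problem. Pass two genes for a double
#' deletion (global scope only, per the published procedure).
#'
#' @param holo a `holobiont_model`.
#' @param genes one or more unprefixed gene ids.
#' @param scope `"global"` or a tissue tag.
#' @return a `flux_solution`; attribute `closed` lists the reactions closed
#'   by the deletion.
#' @export
delete_gene <- function(holo, genes, scope = "global") {
  if (length(genes) > 1L && scope != "global")
    stop("double deletions are global-only")
  inactive <- unlist(lapply(genes, gene_copies, holo = holo, scope = scope))
  if (!length(inactive)) {
    warning("gene(s) not present in any tissue: ", paste(genes, collapse = ", "),
            "; model unchanged")
  }
  m <- holo$model
  closed <- character()
  if (length(inactive)) {
    affected <- vapply(m$reactions$gene_rule, function(r)
      nzchar(r) && any(gene_rule_genes(r) %in% inactive), logical(1),
      USE.NAMES = FALSE)
    for (i in which(affected)) {
      if (!evaluate_gene_rule(m$reactions$gene_rule[i], inactive))
        closed <- c(closed, m$reactions$id[i])
    }
    if (length(closed)) m <- close_reactions(m, closed)
  }
  sol <- fba(m)
  attr(sol, "closed") <- closed
  sol
}

#' Remove (close) one reaction in one zone and re-solve
#'
#' @param holo a `holobiont_model`.
#' @param reaction reaction id, either already prefixed or unprefixed with
#'   `zone` given.
#' @param zone optional tissue tag owning the reaction copy.
#' @return a `flux_solution`.
#' @export
remove_reaction <- function(holo, reaction, zone = NULL) {
  rid <- if (!is.null(zone)) paste0(zone, "_", reaction) else reaction
  if (!rid %in% holo$model$reactions$id) stop("unknown reaction: ", rid)
  fba(close_reactions(holo$model, rid))
}

#' Robustness analysis of one reaction
#'
#' Phase 1 brackets the flux interval over which the objective stays
#' positive (bisection to a tolerance of 1e-4 times the feasible range);
#' phase 2 fixes the reaction flux at `n_points` evenly spaced values in
#' that interval and records the maximised objective.
#'
#' @param x model or holobiont.
#' @param reaction reaction id.
#' @param n_points grid size (default 20).
#' @return data.frame `flux`, `objective`, `status` (a `robustness_curve`).
#' @export
robustness_scan <- function(x, reaction, n_points = 20) {
  model <- as_model(x)
  if (!reaction %in% model$reactions$id) stop("unknown reaction: ", reaction)
  rng <- fva(model, fraction = 0, reactions = reaction)
  lo <- rng$min; hi <- rng$max
  if (abs(lo) < 1e-9 && abs(hi) < 1e-9) {
    out <- data.frame(flux = 0, objective = obj_at(model, reaction, 0),
                      status = "optimal")
    class(out) <- c("robustness_curve", "data.frame")
    return(out)
  }
  pos <- function(t) {
    o <- obj_at(model, reaction, t)
    !is.na(o) && o > 1e-9
  }
  tol <- 1e-4 * (hi - lo)
  base <- fba(model)
  t0 <- base$fluxes[[reaction]]
  if (!pos(t0)) t0 <- (lo + hi) / 2
  bisect <- function(a, b) {   # pos(a) TRUE, boundary towards b
    if (pos(b)) return(b)
    while (abs(b - a) > tol) {
      mid <- (a + b) / 2
      if (pos(mid)) a <- mid else b <- mid
    }
    a
  }
  lo2 <- if (pos(lo)) lo else bisect(t0, lo)
  hi2 <- if (pos(hi)) hi else bisect(t0, hi)
  grid <- seq(lo2, hi2, length.out = n_points)
  objs <- vapply(grid, function(t) obj_at(model, reaction, t), numeric(1))
  out <- data.frame(flux = grid,
                    objective = ifelse(is.na(objs), 0, objs),
                    status = ifelse(is.na(objs), "infeasible", "optimal"))
  class(out) <- c("robustness_curve", "data.frame")
  out
}

obj_at <- function(model, reaction, t) {
  sol <- fba(set_bounds(model, reaction, lb = t, ub = t))
  if (sol$status == "optimal") sol$objective_value else NA_real_
}

#' Classify a zone's reactions as inactive, active or central
#'
#' A reaction is inactive when its flux variability range at 99% of the
#' optimum is {0}; otherwise active; a reaction is central when its removal
#' reduces growth by more than 10% relative to the full model. For the
#' differentiation super-zone use [classify_differentiation_zone()], which
#' marks a reaction central only if it is central in each of zones IId,
#' IIp and IZ.
#'
#' @param holo a `holobiont_model`.
#' @param zone tissue tag.
#' @param zero flux threshold for "inactive" (default 1e-9).
#' @return data.frame `reaction_id`, `zone`, `class`, `growth_after_removal`.
#' @export
classify_reactions <- function(holo, zone, zero = 1e-9) {
  if (!zone %in% names(holo$tissue_index)) stop("unknown zone: ", zone)
  base <- fba(holo)
  if (base$status != "optimal") stop("model infeasible; cannot classify")
  rids <- intersect(holo$tissue_index[[zone]]$reactions,
                    holo$model$reactions$id)
  fv <- fva(holo, fraction = 0.99, reactions = rids)
  cls <- character(length(rids))
  growth <- rep(NA_real_, length(rids))
  for (k in seq_along(rids)) {
    if (abs(fv$min[k]) < zero && abs(fv$max[k]) < zero) {
      cls[k] <- "inactive"
      next
    }
    sol <- remove_reaction(holo, rids[k])
    g <- if (sol$status == "optimal") sol$objective_value else 0
    growth[k] <- g
    cls[k] <- if (g < (1 - 0.10) * base$objective_value) "central" else "active"
  }
  data.frame(reaction_id = rids, zone = zone, class = cls,
             growth_after_removal = growth, stringsAsFactors = FALSE)
}

#' @rdname classify_reactions
#' @export
classify_differentiation_zone <- function(holo, zero = 1e-9) {
  zones <- c("BacteroidIId", "BacteroidIIp", "BacteroidIZ")
  per <- lapply(zones, function(z) classify_reactions(holo, z, zero))
  strip <- function(df, z) {
    df$base_id <- sub(paste0("^", z, "_"), "", df$reaction_id)
    df
  }
  per <- Map(strip, per, zones)
  ids <- Reduce(intersect, lapply(per, `[[`, "base_id"))
  cls <- vapply(ids, function(id) {
    k <- vapply(per, function(df) df$class[match(id, df$base_id)], character(1))
    if (all(k == "central")) "central"
    else if (all(k == "inactive")) "inactive"
    else "active"
  }, character(1))
  data.frame(reaction_id = ids, zone = "differentiation", class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Largest steady-state violation of a flux solution
#'
#' @param x model or holobiont.
#' @param sol a `flux_solution`.
#' @return max over metabolites of `|S v|`.
#' @export
solution_mass_balance <- function(x, sol) {
  model <- as_model(x)
  if (sol$status != "optimal" || is.null(sol$fluxes)) return(NA_real_)
  S <- stoich_matrix(model)
  max(abs(S %*% sol$fluxes[colnames(S)]))
}

#' Total and plant growth rates of a holobiont solution
#'
#' Growth is the flux of the composite biomass reaction converted to grams
#' of biomass: for the default objective the weights sum to 0.99999 g total
#' (0.97999 g plant); for a rescaled model the objective produces 1 g plant
#' and the sink adds `f/(1-f)` g nodule per g plant.
#'
#' @param holo a `holobiont_model`.
#' @param sol a `flux_solution` from [fba()] or [pfba()].
#' @return named vector: `total`, `plant` (g biomass h-1 gDW-1).
#' @export
growth_rate <- function(holo, sol) {
  if (sol$status != "optimal") return(c(total = 0, plant = 0))
  v <- sol$fluxes[["BIOMASS_holobiont"]]
  if (isTRUE(holo$rescaled)) {
    f <- holo$nodulation
    c(total = v / (1 - f), plant = v)
  } else {
    w <- holo$objective_terms
    plant <- v * sum(w[c("Shoot", "Root")])
    c(total = v * sum(w), plant = plant)
  }
}
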