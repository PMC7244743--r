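## The named in-silico experiments: scenario scans over the holobiont, each
## returning a scan_result data.frame. Growth is reported in g biomass
## day-1 (g plant dry weight)-1 (hourly LP objective x 24).

scan_result <- function(df, scenario) {
  attr(df, "scenario") <- scenario
  class(df) <- c("scan_result", "data.frame")
  df
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan:", attr(x, "scenario"), "-", nrow(x), "points\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

tracked_fluxes <- function(holo, sol) {
  gv <- function(id) if (!is.null(sol$fluxes) && id %in% names(sol$fluxes))
    sol$fluxes[[id]] else NA_real_
  dic <- sum(vapply(paste0("PLNK_III_", c("succ", "mal", "fum")), gv, 1))
  co2 <- sum(vapply(paste0(PLANT_ZONES, "_EX_co2"), gv, 1))
  c(fixation = 2 * gv("BacteroidIII_NIT"),
    sucrose_uptake = gv("PLNK_III_sucr"),
    dicarboxylate_uptake = dic,
    plant_oxidase = gv("NoduleIII_MITOOX"),
    bacteroid_oxidase = gv("BacteroidIII_RESP"),
    nodule_co2_export = co2)
}

scan_point <- function(holo, parsimonious = FALSE) {
  sol <- if (parsimonious) pfba(holo) else fba(holo)
  if (sol$status != "optimal") {
    c(growth = 0, status_ok = 0,
      tracked_fluxes(holo, list(fluxes = NULL, status = sol$status)))
  } else {
    g <- growth_rate(holo, sol)
    c(growth = unname(g["total"]) * 24, status_ok = 1, tracked_fluxes(holo, sol))
  }
}

finish_scan <- function(rows, grid_cols, scenario) {
  df <- as.data.frame(do.call(rbind, rows))
  df$status <- ifelse(df$status_ok == 1, "optimal", "infeasible")
  df$status_ok <- NULL
  df <- df[do.call(order, df[, grid_cols, drop = FALSE]), , drop = FALSE]
  rownames(df) <- NULL
  scan_result(df, scenario)
}

## golden-section maximisation of a unimodal function on [lo, hi]
golden_max <- function(fn, lo, hi, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  while (b - a > tol) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - phi * (b - a); f1 <- fn(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + phi * (b - a); f2 <- fn(x2) }
  }
  x <- (a + b) / 2
  list(x = x, value = fn(x))
}

#' Growth response to exogenous soil ammonium
#'
#' For each root ammonium uptake cap, either the nitrogen-fixation
#' efficiency varies at a fixed 2% nodulation (`vary_efficiency`: the
#' nitrogenase is left free) or the nodulation rate varies at a fixed
#' efficiency of 150 umol N h-1 gNoduleDW-1 (`vary_nodulation`: inner
#' golden-section maximisation of growth over f).
#'
#' @param holo a built `holobiont_model` (default spec).
#' @param mode `"vary_efficiency"` or `"vary_nodulation"`.
#' @param nh4_grid root ammonium uptake caps (umol h-1 gDW-1).
#' @param efficiency fixed efficiency for `vary_nodulation` (default 150).
#' @param f_max upper bound of the nodulation search (default 0.25).
#' @return a `scan_result` with columns `nh4_cap`, `growth`
#'   (g day-1 gDW-1), tracked fluxes, `status` (and `f_opt` for
#'   `vary_nodulation`).
#' @export
ammonium_titration <- function(holo, mode = c("vary_efficiency", "vary_nodulation"),
                               nh4_grid = seq(0, 50, 1), efficiency = 150,
                               f_max = 0.25) {
  mode <- match.arg(mode)
  stopifnot(all(nh4_grid >= 0))
  rows <- lapply(nh4_grid, function(cap) {
    if (mode == "vary_efficiency") {
      h <- apply_constraints(holo, "ammonium", nh4_cap = cap)
      pt <- scan_point(h)
      c(nh4_cap = cap, pt)
    } else {
      gfun <- function(f) {
        h <- rescale_nodulation(holo, f)
        h <- apply_constraints(h, "ammonium", nh4_cap = cap)
        h <- rescale_nodulation_bounds_fix(h, f)
        h <- if (f > 0) set_fixation_efficiency(h, efficiency, f = f) else h
        s <- fba(h)
        if (s$status == "optimal") growth_rate(h, s)[["total"]] else 0
      }
      opt <- golden_max(gfun, 0, f_max)
      h <- rescale_nodulation(holo, opt$x)
      h <- apply_constraints(h, "ammonium", nh4_cap = cap)
      h <- rescale_nodulation_bounds_fix(h, opt$x)
      h <- if (opt$x > 0) set_fixation_efficiency(h, efficiency, f = opt$x) else h
      pt <- scan_point(h)
      c(nh4_cap = cap, pt, f_opt = opt$x)
    }
  })
  finish_scan(rows, "nh4_cap", paste0("ammonium_titration_", mode))
}

## apply_constraints resets maintenance and the zone III O2 cap to the
## f = 0.02 defaults; restore the f-scaling after changing the scenario
rescale_nodulation_bounds_fix <- function(holo, f) {
  spec <- holo$spec
  scale <- f / 0.02
  m <- holo$model
  for (tag in c(PLANT_ZONES, BACTEROID_ZONES)) {
    rid <- paste0(tag, "_ATPM")
    if (rid %in% m$reactions$id && tag %in% names(spec$maintenance))
      m <- set_bounds(m, rid, lb = spec$maintenance[[tag]] * scale, ub = 1000)
  }
  if ("NoduleIII_EX_o2" %in% m$reactions$id)
    m <- set_bounds(m, "NoduleIII_EX_o2",
                    lb = -spec$uptake_caps$zone3_o2 * scale, ub = 0)
  holo$model <- m
  holo
}

#' Pareto scan: nitrogen-fixation efficiency versus plant growth
#'
#' Nodulation is fixed at the spec default (2%); for each efficiency e the
#' zone III nitrogenase flux is fixed at e*f and growth maximised under
#' nitrogen fixation as the sole nitrogen source. With the default zone III
#' oxygen cap the curve rises linearly and collapses shortly past the
#' optimum; without the cap the decline past the optimum is gradual and
#' shallower than the rise before it.
#'
#' @param holo a built `holobiont_model`.
#' @param efficiency_grid e values (umol N h-1 gNoduleDW-1).
#' @param zone3_o2_cap `"default"` or `"none"`.
#' @return a `scan_result` with columns `efficiency`, `growth`, fluxes,
#'   `status`.
#' @export
pareto_fixation <- function(holo, efficiency_grid = seq(0, 600, 10),
                            zone3_o2_cap = c("default", "none")) {
  zone3_o2_cap <- match.arg(zone3_o2_cap)
  if (zone3_o2_cap == "none")
    holo$model <- set_bounds(holo$model, "NoduleIII_EX_o2", lb = -1000, ub = 0)
  f <- holo$nodulation
  rows <- lapply(efficiency_grid, function(e) {
    h <- set_fixation_efficiency(holo, e, f = f)
    c(efficiency = e, scan_point(h))
  })
  finish_scan(rows, "efficiency", paste0("pareto_fixation_o2_", zone3_o2_cap))
}

#' Pareto scan: nodulation rate versus plant growth
#'
#' The nitrogen-fixation efficiency is held constant (150 umol N h-1
#' gNoduleDW-1 by default); for each nodulation fraction f the model is
#' rescaled with [rescale_nodulation()] and growth maximised under
#' fixation-only nitrogen.
#'
#' @param holo a built `holobiont_model`.
#' @param f_grid nodulation fractions in `[0, 0.5)`.
#' @param efficiency fixed e.
#' @return a `scan_result` with columns `f`, `growth`, fluxes, `status`.
#' @export
pareto_nodulation <- function(holo, f_grid = seq(0, 0.25, 0.005),
                              efficiency = 150) {
  stopifnot(all(f_grid >= 0), all(f_grid < 0.5))
  rows <- lapply(f_grid, function(f) {
    h <- rescale_nodulation(holo, f)
    h <- if (f > 0) set_fixation_efficiency(h, efficiency, f = f)
         else set_fixation_efficiency(h, 0, f = 1)  # f=0: no fixation
    c(f = f, scan_point(h))
  })
  finish_scan(rows, "f", "pareto_nodulation")
}

#' Optimal-nodulation growth curve over fixation efficiencies
#'
#' For each efficiency the nodule biomass fraction is optimised (inner
#' golden-section search over f) to maximise plant growth, optionally with
#' a cap on f. Run without the zone III oxygen cap by default, matching the
#' published scan.
#'
#' @param holo a built `holobiont_model`.
#' @param efficiency_grid e values.
#' @param f_cap upper bound on nodulation (`Inf`, 0.10, 0.05, ...).
#' @param o2_cap keep the zone III oxygen cap? (default `FALSE`).
#' @param f_search_max search interval end when `f_cap` is infinite.
#' @return a `scan_result` with columns `efficiency`, `growth`, `f_opt`,
#'   `status`.
#' @export
optimize_nodulation_curve <- function(holo, efficiency_grid = seq(20, 600, 20),
                                      f_cap = Inf, o2_cap = FALSE,
                                      f_search_max = 0.4) {
  cap <- if (is.finite(f_cap)) f_cap else f_search_max
  rows <- lapply(efficiency_grid, function(e) {
    gfun <- function(f) {
      h <- rescale_nodulation(holo, f)
      if (!o2_cap)
        h$model <- set_bounds(h$model, "NoduleIII_EX_o2",
                              lb = -1000, ub = 0)
      h <- set_fixation_efficiency(h, e, f = f)
      s <- fba(h)
      if (s$status == "optimal") growth_rate(h, s)[["total"]] else 0
    }
    opt <- golden_max(gfun, 0, cap)
    c(efficiency = e, growth = opt$value * 24, f_opt = opt$x, status_ok = 1)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$status <- "optimal"; df$status_ok <- NULL
  scan_result(df, sprintf("optimize_nodulation_f_cap_%s", f_cap))
}

#' Metabolic cost decomposition of symbiotic nitrogen fixation
#'
#' Four growth maximisations: (1) the default nodulated, N2-fixing system;
#' (2) as (1) with all nodule and bacteroid maintenance removed; (3)
#' non-nodulated but N2-fixing (nodule biomass excluded from the objective,
#' nodule maintenance removed; fixation is unlinked from nodulation); (4)
#' non-nodulated with unlimited exogenous ammonium. Plant growth rates are
#' reported relative to scenario (4), and the growth gap of scenario (1) is
#' decomposed into a fixation-energy share `(1-r3)/(1-r1)`, a maintenance
#' share `(r2-r1)/(1-r1)` and a nodule-synthesis share `(r3-r2)/(1-r1)`.
#'
#' @param holo a built `holobiont_model` (default spec, N2-only).
#' @return object of class `cost_decomposition`: list with `growth`
#'   (4 absolute plant growth rates, g day-1 gDW-1), `ratios` (r1, r2, r3,
#'   r4 = 1) and `shares`.
#' @export
cost_decomposition <- function(holo) {
  plant_growth <- function(h) {
    s <- fba(h)
    if (s$status != "optimal")
      stop("cost decomposition scenario infeasible")
    growth_rate(h, s)[["plant"]] * 24
  }
  zero_maint <- function(h) {
    for (tag in c(PLANT_ZONES, BACTEROID_ZONES)) {
      rid <- paste0(tag, "_ATPM")
      if (rid %in% h$model$reactions$id)
        h$model <- set_bounds(h$model, rid, lb = 0, ub = 1000)
    }
    h
  }
  restore_o2 <- function(h) {
    ## non-nodulated scenarios still fix nitrogen: the zone III oxygen
    ## supply keeps its default cap rather than scaling with f = 0
    if ("NoduleIII_EX_o2" %in% h$model$reactions$id)
      h$model <- set_bounds(h$model, "NoduleIII_EX_o2",
                            lb = -h$spec$uptake_caps$zone3_o2, ub = 0)
    h
  }
  g1 <- plant_growth(holo)
  g2 <- plant_growth(zero_maint(holo))
  g3 <- plant_growth(restore_o2(zero_maint(rescale_nodulation(holo, 0))))
  g4 <- plant_growth(zero_maint(apply_constraints(rescale_nodulation(holo, 0),
                                                  "ammonium")))
  r <- c(r1 = g1 / g4, r2 = g2 / g4, r3 = g3 / g4, r4 = 1)
  gap <- 1 - r[["r1"]]
  shares <- c(fixation_energy = (1 - r[["r3"]]) / gap,
              maintenance = (r[["r2"]] - r[["r1"]]) / gap,
              nodule_synthesis = (r[["r3"]] - r[["r2"]]) / gap)
  structure(list(growth = c(nodulated = g1, no_maintenance = g2,
                            non_nodulated_fixing = g3, ammonium = g4),
                 ratios = r, shares = shares),
            class = "cost_decomposition")
}

#' @export
print.cost_decomposition <- function(x, ...) {
  cat("relative plant growth rates (ammonium scenario = 1):\n")
  print(round(x$ratios, 3))
  cat("shares of the growth gap:\n")
  print(round(x$shares, 3))
  invisible(x)
}

#' Derive the cost shares from published relative growth rates
#'
#' Pure arithmetic on a vector of the three fixation-scenario ratios
#' (nodulated; nodulated without maintenance; non-nodulated), normalised to
#' the ammonium scenario.
#'
#' @param ratios numeric length 3: r1, r2, r3.
#' @return named shares summing to 1.
#' @export
cost_shares_from_ratios <- function(ratios) {
  stopifnot(length(ratios) == 3)
  r1 <- ratios[[1]]; r2 <- ratios[[2]]; r3 <- ratios[[3]]
  gap <- 1 - r1
  c(fixation_energy = (1 - r3) / gap,
    maintenance = (r2 - r1) / gap,
    nodule_synthesis = (r3 - r2) / gap)
}

#' Carbon-source switch under plant oxidase limitation
#'
#' On the sucrose-bacteroid variant of the holobiont (zone III bacteroids
#' may take up sucrose as well as C4-dicarboxylates) and with the overall
#' zone III oxygen cap removed, the upper bound of the zone III plant
#' mitochondrial terminal oxidase is scanned. Parsimonious FBA reports the
#' carbon split: as the oxidase cap falls, bacteroid sucrose uptake falls
#' monotonically to zero (plant glycolysis must regenerate ATP and dispose
#' of NADH into malate) and dicarboxylate uptake rises.
#'
#' @param holo a holobiont built with `sucrose_bacteroid_variant = TRUE`.
#' @param oxidase_cap_grid upper bounds for `NoduleIII_MITOOX` (umol h-1
#'   gDW-1); default 21 points, log-spaced from 0.01 to 100 plus 0 and
#'   unlimited.
#' @return a `scan_result` with columns `oxidase_cap`, `growth`, fluxes,
#'   `status`.
#' @export
carbon_switch_scan <- function(holo, oxidase_cap_grid = NULL) {
  if (!"PLNK_III_sucr" %in% holo$model$reactions$id)
    stop("carbon_switch_scan needs the sucrose bacteroid variant ",
         "(spec$sucrose_bacteroid_variant = TRUE)")
  if (is.null(oxidase_cap_grid))
    oxidase_cap_grid <- c(0, 10^seq(-2, 2, length.out = 19), 1000)
  holo$model <- set_bounds(holo$model, "NoduleIII_EX_o2", lb = -1000, ub = 0)
  rows <- lapply(oxidase_cap_grid, function(cap) {
    h <- holo
    h$model <- set_bounds(h$model, "NoduleIII_MITOOX", lb = 0, ub = cap)
    c(oxidase_cap = cap, scan_point(h, parsimonious = TRUE))
  })
  finish_scan(rows, "oxidase_cap", "carbon_switch")
}

#' Peribacteroid proton access test
#'
#' Builds the holobiont twice, differing only in whether zone III
#' bacteroid symporters may draw peribacteroid-space protons, and reports
#' the maximal growth of each under nitrogen fixation as the sole nitrogen
#' source. Without proton access the bacteroid cannot pay the proton cost
#' of ammonium export and the symbiosis yields no growth.
#'
#' @param holo a built `holobiont_model` (its stored inputs are re-used).
#' @return list `access_on`, `access_off` (growth, g day-1 gDW-1).
#' @export
proton_access_test <- function(holo) {
  inp <- holo$inputs
  spec_on <- holo$spec; spec_on$bacteroid_proton_access <- TRUE
  spec_off <- holo$spec; spec_off$bacteroid_proton_access <- FALSE
  g <- function(spec) {
    h <- build_holobiont(inp$plant, inp$bacterium, spec, inp$calls,
                         inp$transport_table)
    s <- fba(h)
    if (s$status == "optimal") growth_rate(h, s)[["total"]] * 24 else 0
  }
  list(access_on = g(spec_on), access_off = g(spec_off))
}

#' Growth screen over carbon substrates
#'
#' For each substrate, its exchange reaction is opened on top of a basal
#' medium (all carbon exchanges closed) and growth tested by FBA. A
#' substrate without an exchange reaction is reported `"untestable"`.
#'
#' @param model a single-organism `metabolic_model`.
#' @param substrates character vector of species names (exchange reactions
#'   `EX_<substrate>` are probed).
#' @param uptake_rate uptake cap applied to the opened exchange.
#' @param growth_threshold objective value above which the substrate counts
#'   as growth-supporting (default 1e-6).
#' @return data.frame `substrate`, `growth_rate`, `call` in
#'   `growth` / `no growth` / `untestable`.
#' @export
substrate_screen <- function(model, substrates, uptake_rate = 10,
                             growth_threshold = 1e-6) {
  carbon_ex <- intersect(paste0("EX_", c("glc", "fru", "sucr", "succ", "mal",
                                         "fum", "ala", "gln", "pyr", "xyl")),
                         model$reactions$id)
  basal <- set_bounds(model, carbon_ex, lb = 0)
  rows <- lapply(substrates, function(s) {
    ex <- paste0("EX_", s)
    if (!ex %in% basal$reactions$id)
      return(data.frame(substrate = s, growth_rate = NA_real_,
                        call = "untestable", stringsAsFactors = FALSE))
    sol <- fba(set_bounds(basal, ex, lb = -uptake_rate))
    g <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(substrate = s, growth_rate = g,
               call = if (g > growth_threshold) "growth" else "no growth",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert a plant-normalised flux to per-gram-bacteroid units
#'
#' Fluxes of the holobiont are expressed per gram plant dry weight;
#' bacteroid-normalised rates divide by the bacteroid mass fraction
#' `f * bacteroid_fraction_of_nodule` (0.005 at the defaults).
#'
#' @param flux plant-normalised flux.
#' @param spec a [holobiont_spec()].
#' @param f nodulation fraction (default from spec).
#' @return bacteroid-normalised flux.
#' @export
per_bacteroid <- function(flux, spec, f = spec$nodulation_fraction) {
  flux / (f * spec$bacteroid_fraction_of_nodule)
}
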