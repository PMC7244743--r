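#' Assembly parameters for a nodulated-plant holobiont
#'
#' Defaults reproduce the published simulation conditions: 2% of total dry
#' biomass is nodule tissue, shoot:root biomass ratio 2:1, bacteroids are
#' 25% of nodule biomass, every single-metabolite diffusion between
#' compartments costs 0.25 mol ATP per mol transported, zone III tissue may
#' take up at most 8.9847 umol O2 h-1 gDW-1, leaves take up at most
#' 1000 umol h-1 gDW-1 each of light and CO2, ATP-hydrolysis maintenance is
#' forced per tissue (shoot 74, root 37 umol h-1 gDW-1; plant nodule zones
#' I/IId/IIp/IZ/III 0.111/0.750/0.750/0.083/0.833 umol; bacteroid zones
#' IId/IIp/IZ/III 5.7/5.7/0.6/6.3 umol, all per g plant dry weight), and
#' zone III bacteroids may only receive succinate, malate and fumarate
#' (at most 1000 umol h-1 gDW-1 each).
#'
#' @param nodulation_fraction share of total dry biomass that is nodule
#'   tissue (f, default 0.02).
#' @param shoot_root_ratio shoot:root biomass ratio (default 2).
#' @param zone_biomass_weights named objective weights of the nodule biomass
#'   terms at f = 0.02 (zone III produces no biomass: terminally
#'   differentiated tissue).
#' @param bacteroid_fraction_of_nodule bacteroid share of nodule dry weight.
#' @param transport_atp_cost mol ATP per mol transported by costed
#'   diffusion reactions.
#' @param maintenance named vector of forced ATP-hydrolysis rates
#'   (umol h-1 per g plant dry weight) by tissue tag.
#' @param uptake_caps named list: `light`, `co2`, `zone3_o2`.
#' @param zone3_carbon_whitelist named vector of per-carbon-source flux caps
#'   for the zone III plant-to-peribacteroid links.
#' @param bacteroid_proton_access may bacteroid symporters draw protons
#'   from the peribacteroid space?
#' @param sucrose_bacteroid_variant add a sucrose route to zone III
#'   bacteroids (carbon-source-switch analysis).
#' @return object of class `holobiont_spec`.
#' @export
holobiont_spec <- function(nodulation_fraction = 0.02,
                           shoot_root_ratio = 2,
                           zone_biomass_weights = c(
                             I = 0.00100,
                             IId_plant = 0.00675, IId_bact = 0.00225,
                             IIp_plant = 0.00675, IIp_bact = 0.00225,
                             IZ_plant = 0.00075, IZ_bact = 0.00025),
                           bacteroid_fraction_of_nodule = 0.25,
                           transport_atp_cost = 0.25,
                           maintenance = c(
                             Shoot = 74, Root = 37,
                             NoduleI = 0.111, NoduleIId = 0.750,
                             NoduleIIp = 0.750, NoduleIZ = 0.083,
                             NoduleIII = 0.833,
                             BacteroidIId = 5.7, BacteroidIIp = 5.7,
                             BacteroidIZ = 0.6, BacteroidIII = 6.3),
                           uptake_caps = list(light = 1000, co2 = 1000,
                                              zone3_o2 = 8.9847),
                           zone3_carbon_whitelist = c(succ = 1000, mal = 1000,
                                                      fum = 1000),
                           bacteroid_proton_access = TRUE,
                           sucrose_bacteroid_variant = FALSE) {
  f <- nodulation_fraction
  stopifnot(f >= 0, f < 1, shoot_root_ratio > 0, all(maintenance >= 0),
            bacteroid_fraction_of_nodule > 0, bacteroid_fraction_of_nodule <= 1)
  structure(list(nodulation_fraction = f,
                 shoot_root_ratio = shoot_root_ratio,
                 zone_biomass_weights = zone_biomass_weights,
                 bacteroid_fraction_of_nodule = bacteroid_fraction_of_nodule,
                 transport_atp_cost = transport_atp_cost,
                 maintenance = maintenance,
                 uptake_caps = uptake_caps,
                 zone3_carbon_whitelist = zone3_carbon_whitelist,
                 bacteroid_proton_access = bacteroid_proton_access,
                 sucrose_bacteroid_variant = sucrose_bacteroid_variant),
            class = "holobiont_spec")
}

#' Objective weights of the holobiont biomass reaction
#'
#' At the default nodulation fraction (f = 0.02) the weights are the
#' published constants: 0.65333 shoot, 0.32666 root, 0.00100 zone I,
#' 0.00675/0.00225 zone IId plant/bacteroid, 0.00675/0.00225 zone IIp,
#' 0.00075/0.00025 interzone (sum 0.99999). For other f the shoot and root
#' terms scale by (1-f)/0.98 and the zone terms by f/0.02, preserving the
#' internal proportions.
#'
#' @param spec a [holobiont_spec()].
#' @return named numeric vector of weights by biomass-term label.
#' @export
build_objective_weights <- function(spec) {
  f <- spec$nodulation_fraction
  if (f >= 1) stop("nodulation fraction must be < 1")
  shoot <- 0.65333 * (1 - f) / 0.98
  root <- 0.32666 * (1 - f) / 0.98
  zw <- spec$zone_biomass_weights * f / 0.02
  if (f == 0) zw <- zw[0]
  c(Shoot = shoot, Root = root, zw)
}

## map biomass-term labels to tissue tags and biomass metabolite ids
biomass_term_tissue <- function(label) {
  switch(label,
         Shoot = "Shoot", Root = "Root", I = "NoduleI",
         IId_plant = "NoduleIId", IId_bact = "BacteroidIId",
         IIp_plant = "NoduleIIp", IIp_bact = "BacteroidIIp",
         IZ_plant = "NoduleIZ", IZ_bact = "BacteroidIZ",
         stop("unknown biomass term: ", label))
}

#' Replicate an organism model under a tissue tag
#'
#' Deep copy with every metabolite, reaction, gene and compartment id
#' prefixed `"<tag>_"`; gene rules are rewritten accordingly. Structure is
#' otherwise identical; the objective is dropped (the holobiont carries a
#' single composite objective).
#'
#' @param model a `metabolic_model`.
#' @param tag tissue tag, e.g. `"Root"`.
#' @return the prefixed `metabolic_model`.
#' @export
replicate_tissue <- function(model, tag) {
  pre <- paste0(tag, "_")
  if (any(startsWith(model$reactions$id, pre)) ||
      any(startsWith(model$metabolites$id, pre)))
    stop("tag collision: ids already carry prefix ", pre)
  m <- model
  m$id <- paste0(tag, "_", model$id)
  m$metabolites$id <- paste0(pre, m$metabolites$id)
  m$metabolites$compartment <- paste0(pre, m$metabolites$compartment)
  m$reactions$id <- paste0(pre, m$reactions$id)
  rename_rule <- function(rule) {
    tree <- parse_gene_rule(rule)
    if (is.null(tree)) return("")
    walk <- function(t) {
      if (is.character(t)) return(paste0(pre, t))
      t$args <- lapply(t$args, walk)
      t
    }
    deparse_gene_rule(walk(tree))
  }
  m$reactions$gene_rule <- vapply(m$reactions$gene_rule, rename_rule,
                                  character(1), USE.NAMES = FALSE)
  m$stoichiometry <- stats::setNames(
    lapply(model$stoichiometry, function(st)
      stats::setNames(as.numeric(st), paste0(pre, names(st)))),
    m$reactions$id)
  m$genes <- paste0(pre, model$genes)
  m$objective <- numeric()
  validate_model(m)
  m
}

## concatenate models that have disjoint id spaces
merge_models <- function(models, id = "holobiont") {
  metabolic_model(
    id,
    do.call(rbind, lapply(models, `[[`, "metabolites")),
    do.call(rbind, lapply(models, `[[`, "reactions")),
    do.call(c, lapply(models, `[[`, "stoichiometry")),
    unlist(lapply(models, `[[`, "genes"), use.names = FALSE))
}

#' Default inter-tissue transport table of the toy holobiont
#'
#' Columns: `metabolite` (species name without compartment suffix), `from`,
#' `to` (tissue tags), `reversible`, `cost` (does the row pay the
#' single-metabolite diffusion ATP cost?). Sucrose flows shoot to root to
#' every nodule zone; ammonia moves reversibly between root and shoot and
#' between root and every zone; nitrate moves root to shoot. Gases and
#' water are exchanged directly by each tissue and need no inter-tissue
#' rows.
#'
#' @return data.frame usable by [link_tissues()].
#' @export
default_transport_table <- function() {
  rows <- list(c("sucr", "Shoot", "Root", FALSE, TRUE),
               c("no3", "Root", "Shoot", FALSE, TRUE),
               c("nh3", "Root", "Shoot", TRUE, TRUE))
  for (z in PLANT_ZONES) {
    rows <- c(rows, list(c("sucr", "Root", z, FALSE, TRUE),
                         c("nh3", "Root", z, TRUE, TRUE),
                         c("ala", z, "Root", TRUE, TRUE),
                         c("pyr", z, "Root", FALSE, TRUE)))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("metabolite", "from", "to", "reversible", "cost")
  df$reversible <- as.logical(df$reversible)
  df$cost <- as.logical(df$cost)
  df
}

## one directed transport reaction, optionally ATP-costed in the source
link_reaction_stoich <- function(met, from, to, cost, atp_cost) {
  st <- stats::setNames(c(-1, 1), paste0(c(from, to), "_", met, "_c"))
  if (cost && atp_cost > 0) {
    st <- c(st, stats::setNames(
      c(-atp_cost, -atp_cost, atp_cost, atp_cost),
      paste0(from, "_", c("atp", "h2o", "adp", "pi"), "_c")))
  }
  st
}

#' Connect tissues with transport reactions
#'
#' One transport reaction per table row; rows flagged `cost` additionally
#' hydrolyse `spec$transport_atp_cost` ATP in the source tissue. A
#' reversible costed row becomes two opposed irreversible reactions so the
#' cost is paid in whichever tissue exports.
#'
#' @param holo a `holobiont_model`.
#' @param transport_table data.frame as from [default_transport_table()].
#' @return the holobiont with link reactions added.
#' @export
link_tissues <- function(holo, transport_table) {
  m <- holo$model
  cost <- holo$spec$transport_atp_cost
  for (i in seq_len(nrow(transport_table))) {
    r <- transport_table[i, ]
    for (side in c("fwd", if (isTRUE(r$reversible)) "rev")) {
      from <- if (side == "fwd") r$from else r$to
      to <- if (side == "fwd") r$to else r$from
      need <- paste0(c(from, to), "_", r$metabolite, "_c")
      missing <- setdiff(need, m$metabolites$id)
      if (length(missing))
        stop("transport table references missing metabolites: ",
             paste(missing, collapse = ", "))
      id <- paste0("LNK_", r$metabolite, "_", from, "_", to)
      st <- link_reaction_stoich(r$metabolite, from, to, isTRUE(r$cost), cost)
      lb <- 0
      if (isTRUE(r$reversible) && !isTRUE(r$cost)) {
        # a single reversible uncosted reaction suffices
        if (side == "rev") next
        lb <- -1000
      }
      m <- add_reaction(m, id, st, lb = lb, ub = 1000, subsystem = "link")
      holo$link_reactions <- c(holo$link_reactions, id)
    }
  }
  holo$model <- m
  holo
}

## nutrients transferred between a zone's plant cytosol and its
## peribacteroid space
pbs_whitelist <- function(zone, spec) {
  zone3 <- zone == "III"
  carbon <- if (zone3) {
    c(names(spec$zone3_carbon_whitelist),
      if (spec$sucrose_bacteroid_variant) "sucr")
  } else c("glc", "fru", "succ", "mal", "fum", "gln")
  list(carbon = carbon,
       gases = c("o2", "co2", "n2", "h2", "h2o"),
       ## differentiating bacteroids receive ammonia by diffusion; the
       ## fixation zone only exports (as NH4+)
       nh3_in = !zone3,
       nh4_reversible = !zone3)
}

#' Embed a bacteroid population into a nodule zone
#'
#' Replicates the bacterium under the `Bacteroid<zone>` tag, renames its
#' external compartment to the peribacteroid space `PBS_<zone>`, removes
#' its environment exchanges (all traffic now passes through the plant),
#' adds plant-to-PBS transfer reactions for the whitelisted nutrients
#' (carbon transfers pay the diffusion ATP cost), free gas/water diffusion,
#' NH4+ return to the plant (reversible in the differentiation zones, where
#' bacteroids still grow and need nitrogen), an alanine return route, and
#' an ATP-driven plant proton pump that acidifies the peribacteroid space.
#' Bacteroid proton-symport transporters draw PBS protons iff
#' `proton_access`; otherwise they are converted to uniporters and the
#' bacteroid has no way to consume plant-derived protons.
#'
#' @param holo a `holobiont_model` already containing the plant zones.
#' @param bacterium the bacterium `metabolic_model`.
#' @param zone_tag one of `"IId"`, `"IIp"`, `"IZ"`, `"III"`.
#' @param proton_access logical; default taken from the spec.
#' @return the extended holobiont.
#' @export
embed_bacteroid <- function(holo, bacterium, zone_tag,
                            proton_access = holo$spec$bacteroid_proton_access) {
  if (!zone_tag %in% c("IId", "IIp", "IZ", "III"))
    stop("unknown zone: ", zone_tag)
  btag <- paste0("Bacteroid", zone_tag)
  if (btag %in% names(holo$tissue_index)) stop("zone already embedded: ", btag)
  ptag <- paste0("Nodule", zone_tag)
  pbs <- paste0("PBS_", zone_tag)

  bm <- replicate_tissue(bacterium, btag)
  ## drop environment exchanges; rename the external compartment to the PBS
  ex <- bm$reactions$id[startsWith(bm$reactions$id, paste0(btag, "_EX_"))]
  bm <- drop_reactions(bm, ex)
  is_e <- bm$metabolites$compartment == paste0(btag, "_e")
  old <- bm$metabolites$id[is_e]
  new <- paste0(pbs, "_", sub(paste0("^", btag, "_"), "", sub("_e$", "", old)))
  map <- stats::setNames(new, old)
  bm$metabolites$id[is_e] <- new
  bm$metabolites$compartment[is_e] <- pbs
  bm$stoichiometry <- lapply(bm$stoichiometry, function(st) {
    hit <- names(st) %in% names(map)
    names(st)[hit] <- map[names(st)[hit]]
    st
  })
  if (!proton_access) {
    ## symporters become uniporters: strip the proton terms from every
    ## bacteroid reaction that consumes PBS protons; pure proton channels
    ## become empty and are dropped
    hpbs <- paste0(pbs, "_h")
    hcyt <- paste0(btag, "_h_c")
    emptied <- character()
    for (rid in names(bm$stoichiometry)) {
      st <- bm$stoichiometry[[rid]]
      if (hpbs %in% names(st) && st[[hpbs]] < 0) {
        st <- st[!(names(st) %in% c(hpbs, hcyt))]
        if (!length(st)) emptied <- c(emptied, rid)
        else bm$stoichiometry[[rid]] <- st
      }
    }
    if (length(emptied)) bm <- drop_reactions(bm, emptied)
  }
  bm <- drop_orphan_metabolites(bm)
  validate_model(bm)

  m <- merge_models(list(holo$model, bm), id = holo$model$id)

  wl <- pbs_whitelist(zone_tag, holo$spec)
  cost <- holo$spec$transport_atp_cost
  add_pbs_link <- function(m, sp, direction = c("in", "out", "rev"),
                           costed = FALSE) {
    direction <- match.arg(direction)
    pid <- paste0(ptag, "_", sp, "_c")
    bid <- paste0(pbs, "_", sp)
    if (!bid %in% m$metabolites$id) return(m)  # species absent from bacterium
    if (!pid %in% m$metabolites$id)
      stop("plant zone lacks metabolite for PBS link: ", pid)
    id <- paste0("PLNK_", zone_tag, "_", sp)
    if (direction == "out") {
      st <- stats::setNames(c(-1, 1), c(bid, pid))
      m <- add_reaction(m, id, st, lb = 0, ub = 1000, subsystem = "pbs_link")
    } else {
      st <- stats::setNames(c(-1, 1), c(pid, bid))
      if (costed && cost > 0)
        st <- c(st, stats::setNames(c(-cost, -cost, cost, cost),
                                    paste0(ptag, "_", c("atp", "h2o", "adp", "pi"), "_c")))
      m <- add_reaction(m, id, st, lb = if (direction == "rev") -1000 else 0,
                        ub = 1000, subsystem = "pbs_link")
    }
    m
  }

  for (sp in wl$carbon) m <- add_pbs_link(m, sp, "in", costed = TRUE)
  for (sp in wl$gases) m <- add_pbs_link(m, sp, "rev")
  if (isTRUE(wl$nh3_in)) m <- add_pbs_link(m, "nh3", "in")
  m <- add_pbs_link(m, "nh4", if (wl$nh4_reversible) "rev" else "out")
  m <- add_pbs_link(m, "ala", "out")
  ## plant H+-ATPase acidifying the peribacteroid space
  m <- add_reaction(m, paste0("PPUMP_", zone_tag),
                    stats::setNames(
                      c(-1, -1, -1, 1, 1, 1),
                      c(paste0(ptag, "_", c("atp", "h2o", "h"), "_c"),
                        paste0(ptag, "_", c("adp", "pi"), "_c"),
                        paste0(pbs, "_h"))),
                    lb = 0, ub = 1000, gene = paste0(ptag, "_ppmaA"),
                    subsystem = "pbs_link")
  if (!paste0(ptag, "_ppmaA") %in% m$genes)
    m$genes <- c(m$genes, paste0(ptag, "_ppmaA"))

  holo$model <- m
  holo$tissue_index[[btag]] <- list(
    reactions = bm$reactions$id,
    genes = bm$genes,
    metabolites = bm$metabolites$id)
  holo$link_reactions <- c(holo$link_reactions,
                           grep(paste0("^(PLNK_", zone_tag, "_|PPUMP_", zone_tag, "$)"),
                                m$reactions$id, value = TRUE))
  holo
}

#' Apply the default simulation constraints
#'
#' Closes every exchange except the physiological ones (light and CO2 at
#' the shoot, soil nutrients at the root, gases at each nodule zone), caps
#' light/CO2 uptake and the zone III oxygen supply, forces per-tissue
#' ATP-hydrolysis maintenance, caps the zone III carbon links, and sets the
#' nitrogen scenario: under `"n2_only"` the root ammonium and nitrate
#' uptakes are 0 (export of surplus fixed nitrogen stays possible).
#'
#' @param holo a `holobiont_model`.
#' @param nitrogen `"n2_only"` (default) or `"ammonium"`.
#' @param nh4_cap root ammonium uptake cap used when `nitrogen ==
#'   "ammonium"` (default unlimited, i.e. 1000).
#' @return the constrained holobiont.
#' @export
apply_constraints <- function(holo, nitrogen = c("n2_only", "ammonium"),
                              nh4_cap = 1000) {
  nitrogen <- match.arg(nitrogen)
  m <- holo$model
  spec <- holo$spec
  ex <- grep("_EX_", m$reactions$id, value = TRUE)
  m <- set_bounds(m, ex, lb = 0, ub = 0)

  want <- function(id) {
    if (!id %in% m$reactions$id) stop("expected exchange reaction absent: ", id)
    id
  }
  m <- set_bounds(m, want("Shoot_EX_photon"), lb = -spec$uptake_caps$light, ub = 0)
  m <- set_bounds(m, want("Shoot_EX_co2"), lb = -spec$uptake_caps$co2, ub = 1000)
  m <- set_bounds(m, want("Shoot_EX_o2"), lb = -1000, ub = 1000)
  m <- set_bounds(m, want("Shoot_EX_h2o"), lb = -1000, ub = 1000)
  for (id in paste0("Root_EX_", c("h2o", "pi", "o2", "co2")))
    m <- set_bounds(m, want(id), lb = -1000, ub = 1000)
  m <- set_bounds(m, want("Root_EX_nh3"), lb = 0, ub = 1000)
  m <- set_bounds(m, want("Root_EX_h"), lb = 0, ub = 1000)
  if (nitrogen == "n2_only") {
    m <- set_bounds(m, want("Root_EX_nh4"), lb = 0, ub = 1000)
    m <- set_bounds(m, want("Root_EX_no3"), lb = 0, ub = 0)
  } else {
    m <- set_bounds(m, want("Root_EX_nh4"), lb = -nh4_cap, ub = 1000)
    m <- set_bounds(m, want("Root_EX_no3"), lb = 0, ub = 0)
  }
  for (z in PLANT_ZONES) {
    o2lb <- if (z == "NoduleIII") -spec$uptake_caps$zone3_o2 else -1000
    m <- set_bounds(m, want(paste0(z, "_EX_o2")), lb = o2lb, ub = 0)
    m <- set_bounds(m, want(paste0(z, "_EX_co2")), lb = -1000, ub = 1000)
    m <- set_bounds(m, want(paste0(z, "_EX_h2o")), lb = -1000, ub = 1000)
    m <- set_bounds(m, want(paste0(z, "_EX_n2")), lb = -1000, ub = 0)
    m <- set_bounds(m, want(paste0(z, "_EX_h2")), lb = 0, ub = 1000)
  }
  ## maintenance: forced ATP hydrolysis
  for (tag in names(spec$maintenance)) {
    rid <- paste0(tag, "_ATPM")
    if (!rid %in% m$reactions$id) {
      if (tag %in% names(holo$tissue_index))
        stop("maintenance reaction absent: ", rid)
      next
    }
    m <- set_bounds(m, rid, lb = spec$maintenance[[tag]], ub = 1000)
  }
  ## zone III carbon caps
  for (sp in names(spec$zone3_carbon_whitelist)) {
    rid <- paste0("PLNK_III_", sp)
    if (rid %in% m$reactions$id)
      m <- set_bounds(m, rid, lb = 0, ub = spec$zone3_carbon_whitelist[[sp]])
  }
  holo$model <- m
  holo$scenario <- list(nitrogen = nitrogen, nh4_cap = nh4_cap)
  holo
}

#' Build a holobiont model from a plant and a bacterium
#'
#' Orchestrates the integration procedure: replicate the plant into shoot,
#' root and five nodule zones; embed bacteroids into zones IId, IIp, IZ and
#' III behind peribacteroid spaces; connect tissues with ATP-costed
#' transport; gate each zone's reaction space with the expression calls;
#' install the composite biomass objective; apply the default constraints;
#' and prune reactions stranded on dead-end metabolites.
#'
#' @param plant,bacterium organism models (e.g. [generate_toy_plant()] and
#'   [generate_toy_bacterium()]).
#' @param spec a [holobiont_spec()].
#' @param calls an `expression_call_set` covering every nodule zone.
#' @param transport_table inter-tissue transport rows
#'   (default [default_transport_table()]).
#' @param nitrogen nitrogen scenario passed to [apply_constraints()].
#' @param prune remove dead-end reactions after assembly (default `TRUE`).
#' @return object of class `holobiont_model`.
#' @export
build_holobiont <- function(plant, bacterium, spec = holobiont_spec(),
                            calls = NULL,
                            transport_table = default_transport_table(),
                            nitrogen = "n2_only", prune = TRUE) {
  if (isTRUE(spec$sucrose_bacteroid_variant) &&
      !"T_sucr" %in% bacterium$reactions$id)
    stop("sucrose_bacteroid_variant requires a bacterium with a sucrose route ",
         "(include_sucrose_bacteroid_path in the toy configuration)")
  tissues <- lapply(TISSUE_TAGS, function(tag) replicate_tissue(plant, tag))
  model <- merge_models(tissues)
  ## tissue biomass drains are replaced by the composite objective
  model <- drop_reactions(model, paste0(TISSUE_TAGS, "_DM_biomass"))

  holo <- structure(
    list(model = model,
         tissue_index = stats::setNames(lapply(seq_along(TISSUE_TAGS), function(i)
           list(reactions = setdiff(tissues[[i]]$reactions$id,
                                    paste0(TISSUE_TAGS[i], "_DM_biomass")),
                genes = tissues[[i]]$genes,
                metabolites = tissues[[i]]$metabolites$id)), TISSUE_TAGS),
         link_reactions = character(),
         objective_terms = numeric(),
         spec = spec,
         scenario = NULL,
         nodulation = spec$nodulation_fraction,
         gating = list(),
         inputs = list(plant = plant, bacterium = bacterium, calls = calls,
                       transport_table = transport_table)),
    class = "holobiont_model")

  for (z in c("IId", "IIp", "IZ", "III"))
    holo <- embed_bacteroid(holo, bacterium, z)
  holo$model <- drop_reactions(holo$model,
                               paste0(BACTEROID_ZONES, "_DM_biomass"))
  for (bz in BACTEROID_ZONES)
    holo$tissue_index[[bz]]$reactions <-
      setdiff(holo$tissue_index[[bz]]$reactions, paste0(bz, "_DM_biomass"))

  holo <- link_tissues(holo, transport_table)

  if (!is.null(calls)) {
    for (z in c(PLANT_ZONES, BACTEROID_ZONES)) {
      gated <- gate_zone(holo, z, calls)
      holo <- gated$holobiont
      holo$gating[[z]] <- gated$report
    }
  }

  ## composite biomass objective
  w <- build_objective_weights(spec)
  st <- stats::setNames(-as.numeric(w),
                        paste0(vapply(names(w), biomass_term_tissue, ""),
                               "_biomass_c"))
  holo$model <- add_reaction(holo$model, "BIOMASS_holobiont", st,
                             lb = 0, ub = 1000, subsystem = "objective")
  holo$model$objective <- c(BIOMASS_holobiont = 1)
  holo$objective_terms <- w

  holo <- apply_constraints(holo, nitrogen = nitrogen)

  if (!prune) return(holo)
  pruned <- remove_dead_ends(holo$model)
  holo$model <- pruned$model
  holo$pruned_reactions <- pruned$removed
  for (tag in names(holo$tissue_index)) {
    holo$tissue_index[[tag]]$reactions <-
      intersect(holo$tissue_index[[tag]]$reactions, holo$model$reactions$id)
    holo$tissue_index[[tag]]$metabolites <-
      intersect(holo$tissue_index[[tag]]$metabolites, holo$model$metabolites$id)
  }
  holo$link_reactions <- intersect(holo$link_reactions, holo$model$reactions$id)
  holo
}

#' @export
print.holobiont_model <- function(x, ...) {
  cat("holobiont model:", nrow(x$model$reactions), "reactions,",
      nrow(x$model$metabolites), "metabolites,",
      length(x$model$genes), "gene copies\n")
  cat("  tissues:", paste(names(x$tissue_index), collapse = ", "), "\n")
  cat("  nodulation fraction:", x$nodulation, "\n")
  if (!is.null(x$scenario))
    cat("  nitrogen scenario:", x$scenario$nitrogen, "\n")
  invisible(x)
}

#' Re-express the nodulation fraction of a built holobiont
#'
#' For simulations in which the rate of nodulation varies, the nodule
#' biomass terms are removed from the objective (shoot/root weights
#' rescaled to 2/3 and 1/3) and nodule plus bacteroid biomass is instead
#' forced through a sink reaction at a rate proportional to f and the
#' current plant growth (coupled through a pseudo-metabolite). Nodule and
#' bacteroid maintenance and the zone III oxygen cap scale linearly in
#' f/0.02. `f = 0` reduces to a non-nodulated plant: no sink, no nodule
#' maintenance.
#'
#' @param holo a built `holobiont_model` (default objective).
#' @param f new nodulation fraction in `[0, 1)`.
#' @return the rescaled holobiont.
#' @export
rescale_nodulation <- function(holo, f) {
  if (f < 0 || f >= 1) stop("nodulation fraction must be in [0, 1)")
  m <- holo$model
  spec <- holo$spec
  sr <- spec$shoot_root_ratio
  m <- drop_reactions(m, "BIOMASS_holobiont")

  st <- stats::setNames(c(-sr / (1 + sr), -1 / (1 + sr)),
                        c("Shoot_biomass_c", "Root_biomass_c"))
  if (f > 0) {
    if (!"noduledemand_c" %in% m$metabolites$id)
      m <- add_metabolite(m, "noduledemand_c", name = "nodule biomass demand",
                          formula = NA_character_, charge = 0,
                          compartment = "holobiont")
    st <- c(st, c(noduledemand_c = f / (1 - f)))
  }
  m <- add_reaction(m, "BIOMASS_holobiont", st, lb = 0, ub = 1000,
                    subsystem = "objective")
  if (f > 0) {
    zw <- spec$zone_biomass_weights / sum(spec$zone_biomass_weights)
    sink <- stats::setNames(
      -as.numeric(zw),
      paste0(vapply(names(zw), biomass_term_tissue, ""), "_biomass_c"))
    sink <- c(sink, c(noduledemand_c = -1))
    if ("SINK_nodule_biomass" %in% m$reactions$id)
      m <- drop_reactions(m, "SINK_nodule_biomass")
    m <- add_reaction(m, "SINK_nodule_biomass", sink, lb = 0, ub = 1000,
                      subsystem = "objective")
  } else if ("SINK_nodule_biomass" %in% m$reactions$id) {
    m <- drop_reactions(m, "SINK_nodule_biomass")
  }
  m$objective <- c(BIOMASS_holobiont = 1)

  scale <- f / 0.02
  for (tag in c(PLANT_ZONES, BACTEROID_ZONES)) {
    rid <- paste0(tag, "_ATPM")
    if (rid %in% m$reactions$id && tag %in% names(spec$maintenance))
      m <- set_bounds(m, rid, lb = spec$maintenance[[tag]] * scale, ub = 1000)
  }
  if ("NoduleIII_EX_o2" %in% m$reactions$id) {
    cur <- get_bounds(m, "NoduleIII_EX_o2")
    if (is.finite(cur[1, "lower"]) && cur[1, "lower"] < 0)
      m <- set_bounds(m, "NoduleIII_EX_o2",
                      lb = -spec$uptake_caps$zone3_o2 * scale, ub = 0)
  }
  holo$model <- m
  holo$nodulation <- f
  holo$objective_terms <- if (f > 0)
    c(Shoot = sr / (1 + sr), Root = 1 / (1 + sr)) else
    c(Shoot = sr / (1 + sr), Root = 1 / (1 + sr))
  holo$rescaled <- TRUE
  holo
}

#' Fix or free the nitrogen-fixation efficiency
#'
#' The efficiency e is the rate of nitrogen fixation per gram nodule dry
#' weight (umol N h-1 gNoduleDW-1); the per-plant fixation flux is e * f
#' umol N h-1 gDW-1, i.e. a zone III nitrogenase flux of e * f / 2 (each
#' N2 yields two nitrogens). `NULL` frees the nitrogenase.
#'
#' @param holo a `holobiont_model`.
#' @param efficiency e, or `NULL` to relax.
#' @param f nodulation fraction (defaults to the holobiont's current one).
#' @return the modified holobiont.
#' @export
set_fixation_efficiency <- function(holo, efficiency, f = holo$nodulation) {
  rid <- "BacteroidIII_NIT"
  if (!rid %in% holo$model$reactions$id)
    stop("zone III nitrogenase not present in this model")
  if (is.null(efficiency)) {
    holo$model <- set_bounds(holo$model, rid, lb = 0, ub = 1000)
  } else {
    v <- efficiency * f / 2
    holo$model <- set_bounds(holo$model, rid, lb = v, ub = v)
  }
  holo$efficiency <- efficiency
  holo
}
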