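linear_chain <- function(caps = c(5, 3, 8)) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), formula = "C",
                     charge = 0, compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("IN", "MID", "OUT"),
                     name = c("in", "mid", "out"),
                     lower_bound = 0, upper_bound = caps,
                     gene_rule = "", subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(IN = c(A = 1), MID = c(A = -1, B = 1), OUT = c(B = -1))
  m <- metabolic_model("chain", mets, rxns, stoich)
  m$objective <- c(OUT = 1)
  m
}

test_that("a linear chain's optimum is the minimum of the bounds along it", {
  sol <- fba(linear_chain(c(5, 3, 8)))
  expect_equal(sol$objective_value, 3)
  sol <- fba(linear_chain(c(2, 3, 8)))
  expect_equal(sol$objective_value, 2)
  expect_lt(solution_mass_balance(linear_chain(), fba(linear_chain())), 1e-9)
})

test_that("flux variability matches a per-reaction two-LP brute force", {
  holo <- toy_holo_fx()
  sub <- c("BacteroidIII_NIT", "BacteroidIII_T_mal", "BacteroidIII_RESP",
           "NoduleIII_SUCHYD", "Shoot_SUCSYN", "Root_ATPM",
           "BacteroidIId_BIOMASS", "LNK_sucr_Shoot_Root",
           "NoduleI_PEPC", "BacteroidIZ_GS")
  fv <- fva(holo, fraction = 0.99, reactions = sub)
  # naive oracle: fix the objective with explicit bounds and run one LP per
  # direction per reaction, bypassing the package's fva machinery
  base <- fba(holo)
  m <- set_bounds(holo$model, "BIOMASS_holobiont",
                  lb = 0.99 * base$objective_value, ub = 1000)
  for (k in seq_along(sub)) {
    for (dir in c(1, -1)) {
      probe <- m
      probe$objective <- stats::setNames(dir, sub[k])
      o <- fba(probe)$objective_value * dir
      want <- if (dir == 1) fv$max[k] else fv$min[k]
      expect_equal(want, o, tolerance = 1e-6,
                   label = paste(sub[k], if (dir == 1) "max" else "min"))
    }
  }
  expect_true(all(fv$min <= fv$max + 1e-9))
})

test_that("fva basics: blocked reactions are (0,0), the objective is floored", {
  holo <- toy_holo_fx()
  # a gated reaction (zone III anaplerosis, off in differentiated
  # bacteroids) is blocked
  fv <- fva(holo, reactions = "BacteroidIII_PYC")
  expect_equal(c(fv$min, fv$max), c(0, 0))
  fv2 <- fva(holo, fraction = 0.99, reactions = "BIOMASS_holobiont")
  expect_gte(fv2$min, 0.99 * attr(fv2, "optimum") - 1e-9)
})

test_that("gene deletions follow GPR semantics across scopes", {
  holo <- toy_holo_fx()
  base <- fba(holo)$objective_value
  # essential transporters / nitrogenase
  expect_lt(growth_of(delete_gene(holo, "bnifH")), 1e-9)
  expect_lt(growth_of(delete_gene(holo, "bdctA")), 1e-9)
  # non-essential genes (glnA survives on plant-supplied glutamine, at a
  # small import cost)
  expect_gt(growth_of(delete_gene(holo, "bglnA")), 0.9 * base)
  expect_equal(growth_of(delete_gene(holo, "bpycA")), base, tolerance = 1e-6)
  # tissue scope: deleting nitrogenase in a zone where it is already gated
  # off changes nothing; the zone III copy is lethal
  expect_equal(growth_of(delete_gene(holo, "bnifH", scope = "BacteroidIId")),
               base, tolerance = 1e-6)
  expect_lt(growth_of(delete_gene(holo, "bnifH", scope = "BacteroidIII")), 1e-9)
  # global deletion can never beat the best per-tissue deletion
  per_tissue <- vapply(c("BacteroidIId", "BacteroidIIp", "BacteroidIZ",
                         "BacteroidIII"), function(tg)
    growth_of(delete_gene(holo, "bnifH", scope = tg)), numeric(1))
  expect_lte(growth_of(delete_gene(holo, "bnifH")), min(per_tissue) + 1e-9)
  # unknown genes warn and leave the model unchanged
  expect_warning(sol <- delete_gene(holo, "nosuchgene"), "not present")
  expect_equal(sol$objective_value, base, tolerance = 1e-9)
})

test_that("zone-local reaction removal is independent across zones", {
  holo <- toy_holo_fx()
  base <- fba(holo)$objective_value
  # photosystem II: inconsequential in the dark interior of the nodule,
  # lethal in the shoot
  expect_equal(growth_of(remove_reaction(holo, "PSII", zone = "NoduleI")),
               base, tolerance = 1e-6)
  expect_lt(growth_of(remove_reaction(holo, "PSII", zone = "Shoot")), 1e-9)
  # removing a blocked reaction changes nothing
  expect_equal(growth_of(remove_reaction(holo, "BacteroidIII_PCK")), base,
               tolerance = 1e-6)
  # zone III plant PEP carboxylation is required for fixation-driven growth
  expect_lt(growth_of(remove_reaction(holo, "PEPC", zone = "NoduleIII")), 1e-9)
  expect_error(remove_reaction(holo, "NOPE", zone = "NoduleI"), "unknown")
})

test_that("parsimonious FBA keeps the objective and shrinks total flux", {
  holo <- toy_holo_fx()
  plain <- fba(holo)
  pars <- pfba(holo)
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-3)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
  expect_lt(solution_mass_balance(holo, pars), 1e-6)
})

test_that("robustness scans bracket the productive flux range", {
  holo <- toy_holo_fx()
  rc <- robustness_scan(holo, "BacteroidIII_NIT", n_points = 8)
  expect_gte(nrow(rc), 8)
  expect_true(all(rc$objective >= 0))
  # interior maximum at least matches the endpoints (LP value is concave)
  expect_gte(max(rc$objective), rc$objective[1] - 1e-9)
  expect_gte(max(rc$objective), rc$objective[nrow(rc)] - 1e-9)
  # the unconstrained optimum is attained inside the scanned interval
  expect_equal(max(rc$objective), fba(holo)$objective_value, tolerance = 1e-4)
  # a blocked reaction yields a single-point curve at zero flux
  rc0 <- robustness_scan(holo, "BacteroidIII_PCK", n_points = 8)
  expect_equal(nrow(rc0), 1)
  expect_equal(rc0$flux, 0)
})

test_that("reaction classification agrees with a brute-force loop", {
  holo <- toy_holo_fx()
  cls <- classify_reactions(holo, "BacteroidIZ")
  base <- fba(holo)$objective_value
  for (k in seq_len(nrow(cls))) {
    rid <- cls$reaction_id[k]
    # independent check: explicit min/max LPs for activity, removal re-solve
    m <- set_bounds(holo$model, "BIOMASS_holobiont", lb = 0.99 * base, ub = 1000)
    act <- vapply(c(1, -1), function(dir) {
      p <- m; p$objective <- stats::setNames(dir, rid)
      fba(p)$objective_value * dir
    }, numeric(1))
    inactive <- all(abs(act) < 1e-9)
    g <- growth_of(fba(vnod:::close_reactions(holo$model, rid)))
    want <- if (inactive) "inactive"
            else if (g < 0.9 * base) "central" else "active"
    expect_equal(cls$class[k], want, label = rid)
  }
  # central implies active (never inactive)
  expect_false(any(cls$class == "central" &
                   abs(cls$growth_after_removal) > 0.9 * base))
})

test_that("a gated (closed) reaction classifies as inactive", {
  holo <- toy_holo_fx()
  cls3 <- classify_reactions(holo, "BacteroidIII")
  expect_equal(cls3$class[cls3$reaction_id == "BacteroidIII_PYC"], "inactive")
})

test_that("energy conservation: no growth or maintenance on an empty medium", {
  b <- toy_bact_fx()
  dark <- set_bounds(b, grep("^EX_", b$reactions$id, value = TRUE), lb = 0)
  sol <- fba(dark)
  # forced NGAM without any substrate is infeasible: no spontaneous energy
  expect_equal(sol$status, "infeasible")
  relaxed <- fba(set_bounds(dark, "ATPM", lb = 0))
  expect_lt(abs(growth_of(relaxed)), 1e-9)
})

test_that("the differentiation super-zone marks central only if central in every zone", {
  holo <- toy_holo_fx()
  super <- classify_differentiation_zone(holo)
  per <- lapply(c("BacteroidIId", "BacteroidIIp", "BacteroidIZ"),
                function(z) classify_reactions(holo, z))
  for (id in super$reaction_id) {
    k <- vapply(seq_along(per), function(i)
      per[[i]]$class[per[[i]]$reaction_id == paste0(c("BacteroidIId",
        "BacteroidIIp", "BacteroidIZ")[i], "_", id)], character(1))
    want <- if (all(k == "central")) "central"
            else if (all(k == "inactive")) "inactive" else "active"
    expect_equal(super$class[super$reaction_id == id], want, label = id)
  }
  # respiration is central to every differentiating bacteroid
  expect_equal(super$class[super$reaction_id == "RESP"], "central")
})

test_that("double deletions are at most as good as their worst single", {
  holo <- toy_holo_fx()
  g1 <- growth_of(delete_gene(holo, "bglcT"))
  g2 <- growth_of(delete_gene(holo, "bfruT"))
  g12 <- growth_of(delete_gene(holo, c("bglcT", "bfruT")))
  expect_lte(g12, min(g1, g2) + 1e-9)
  expect_error(delete_gene(holo, c("bglcT", "bfruT"), scope = "BacteroidIId"),
               "global")
})
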