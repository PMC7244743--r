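test_that("tissue replication prefixes every identifier and nothing else", {
  p <- toy_plant_fx()
  root <- replicate_tissue(p, "Root")
  expect_true(all(startsWith(root$reactions$id, "Root_")))
  expect_true(all(startsWith(root$metabolites$id, "Root_")))
  expect_true(all(startsWith(root$genes, "Root_")))
  expect_equal(nrow(root$reactions), nrow(p$reactions))
  expect_equal(nrow(root$metabolites), nrow(p$metabolites))
  # gene rules reference only prefixed genes
  for (r in root$reactions$gene_rule)
    if (nzchar(r)) expect_true(all(gene_rule_genes(r) %in% root$genes))
  # two replicas are disjoint and equally sized
  shoot <- replicate_tissue(p, "Shoot")
  expect_length(intersect(root$reactions$id, shoot$reactions$id), 0)
  expect_equal(nrow(root$reactions), nrow(shoot$reactions))
  # re-prefixing errors
  expect_error(replicate_tissue(root, "Root"), "collision")
})

test_that("objective weights reproduce the published constants and scaling", {
  w <- build_objective_weights(holobiont_spec())
  expect_equal(unname(w["Shoot"]), 0.65333)
  expect_equal(unname(w["Root"]), 0.32666)
  expect_equal(unname(w["I"]), 0.00100)
  expect_equal(unname(w["IId_plant"]), 0.00675)
  expect_equal(unname(w["IId_bact"]), 0.00225)
  expect_equal(unname(w["IZ_plant"]), 0.00075)
  expect_equal(unname(w["IZ_bact"]), 0.00025)
  expect_equal(sum(w), 0.99999, tolerance = 1e-6)
  # f = 0: shoot/root only, at the 2:1 ratio
  w0 <- build_objective_weights(holobiont_spec(nodulation_fraction = 0))
  expect_length(w0, 2)
  expect_equal(unname(w0["Shoot"]), 2 / 3, tolerance = 1e-4)
  expect_equal(unname(w0["Root"]), 1 / 3, tolerance = 1e-4)
  # f = 0.04: zone weights double, shoot scales to 0.64000
  w4 <- build_objective_weights(holobiont_spec(nodulation_fraction = 0.04))
  expect_equal(unname(w4["Shoot"]), 0.64000, tolerance = 1e-4)
  expect_equal(unname(w4["IId_plant"]), 2 * 0.00675)
  expect_equal(unname(w4["IZ_bact"]), 2 * 0.00025)
  expect_error(holobiont_spec(nodulation_fraction = 1))
})

test_that("costed transport consumes 0.25 ATP in the source tissue", {
  holo <- toy_holo_fx()
  st <- holo$model$stoichiometry[["LNK_sucr_Shoot_Root"]]
  expect_equal(unname(st["Shoot_sucr_c"]), -1)
  expect_equal(unname(st["Root_sucr_c"]), 1)
  expect_equal(unname(st["Shoot_atp_c"]), -0.25)
  expect_equal(unname(st["Shoot_adp_c"]), 0.25)
  expect_equal(unname(st["Shoot_pi_c"]), 0.25)
  # reversible costed rows become two opposed reactions, each costed at source
  st2 <- holo$model$stoichiometry[["LNK_nh3_NoduleIII_Root"]]
  expect_equal(unname(st2["NoduleIII_atp_c"]), -0.25)
  # an uncosted transfer is a pure 1:1 move
  st3 <- holo$model$stoichiometry[["PLNK_III_o2"]]
  expect_equal(sort(unname(st3)), c(-1, 1))
})

test_that("default constraints match the published simulation conditions", {
  holo <- toy_holo_fx()
  b <- vnod:::get_bounds(holo$model, "NoduleIII_EX_o2")
  expect_equal(unname(b[1, "lower"]), -8.9847)
  b <- vnod:::get_bounds(holo$model, "Shoot_EX_photon")
  expect_equal(unname(b[1, "lower"]), -1000)
  # N2-only: no soil nitrogen uptake
  expect_equal(unname(vnod:::get_bounds(holo$model, "Root_EX_nh4")[1, "lower"]), 0)
  expect_equal(unname(vnod:::get_bounds(holo$model, "Root_EX_no3")[1, "lower"]), 0)
  # maintenance bounds
  expect_equal(unname(vnod:::get_bounds(holo$model, "Shoot_ATPM")[1, "lower"]), 74)
  expect_equal(unname(vnod:::get_bounds(holo$model, "Root_ATPM")[1, "lower"]), 37)
  expect_equal(unname(vnod:::get_bounds(holo$model, "NoduleIII_ATPM")[1, "lower"]), 0.833)
  expect_equal(unname(vnod:::get_bounds(holo$model, "BacteroidIII_ATPM")[1, "lower"]), 6.3)
  expect_equal(unname(vnod:::get_bounds(holo$model, "BacteroidIZ_ATPM")[1, "lower"]), 0.6)
  # zone III carbon caps
  expect_equal(unname(vnod:::get_bounds(holo$model, "PLNK_III_mal")[1, "upper"]), 1000)
  # maintenance forces carbon flux even at zero growth
  m <- holo$model
  m <- set_bounds(m, "BIOMASS_holobiont", lb = 0, ub = 0)
  sol <- fba(set_bounds(m, "Shoot_EX_co2", lb = -1000))
  # feasibility requires photosynthate; closing light must break it
  m2 <- set_bounds(m, "Shoot_EX_photon", lb = 0)
  expect_equal(fba(m2)$status, "infeasible")
})

test_that("the gated build is feasible, smaller than ungated, and decoy-free", {
  holo <- toy_holo_fx()
  sol <- fba(holo)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_lt(solution_mass_balance(holo, sol), 1e-6)
  # pruning removed every decoy copy
  expect_length(grep("DECOY", holo$model$reactions$id), 0)
  # no reaction whose gene rule is false under its zone's calls stays open
  calls <- toy_calls_fx()
  for (z in c("BacteroidIII", "NoduleIII")) {
    inact <- paste0(z, "_", vnod:::off_genes(calls, z))
    ids <- intersect(holo$tissue_index[[z]]$reactions, holo$model$reactions$id)
    for (rid in ids) {
      i <- match(rid, holo$model$reactions$id)
      r <- holo$model$reactions$gene_rule[i]
      sub <- holo$model$reactions$subsystem[i]
      if (nzchar(r) && !sub %in% c("exchange", "transport") &&
          !evaluate_gene_rule(r, inact)) {
        expect_equal(holo$model$reactions$lower_bound[i], 0, label = rid)
        expect_equal(holo$model$reactions$upper_bound[i], 0, label = rid)
      }
    }
  }
  # an ungated build has strictly more open reaction capacity
  ungated <- build_holobiont(toy_plant_fx(), toy_bact_fx(), holobiont_spec(),
                             calls = NULL)
  open <- function(h) sum(!(h$model$reactions$lower_bound == 0 &
                            h$model$reactions$upper_bound == 0))
  expect_gt(open(ungated), open(holo))
})

test_that("fixation flux equals efficiency times nodulation fraction", {
  holo <- toy_holo_fx()
  for (e in c(50, 150)) {
    h <- set_fixation_efficiency(holo, e)
    sol <- fba(h)
    expect_equal(2 * sol$fluxes[["BacteroidIII_NIT"]], e * holo$nodulation,
                 tolerance = 1e-9)
  }
  # at the defaults e = 150 implies a fixation rate of 3 umol N h-1 gDW-1
  h <- set_fixation_efficiency(holo, 150)
  expect_equal(2 * fba(h)$fluxes[["BacteroidIII_NIT"]], 3, tolerance = 1e-9)
})

test_that("rescaled nodulation at f = 0.02 reproduces the default model", {
  holo <- toy_holo_fx()
  g0 <- growth_rate(holo, fba(holo))[["total"]]
  r <- rescale_nodulation(holo, 0.02)
  g1 <- growth_rate(r, fba(r))[["total"]]
  expect_equal(g1, g0, tolerance = 0.01)
  # f = 0 reduces to a non-nodulated plant: no sink, no nodule maintenance
  r0 <- rescale_nodulation(holo, 0)
  expect_false("SINK_nodule_biomass" %in% r0$model$reactions$id)
  expect_equal(unname(vnod:::get_bounds(r0$model, "BacteroidIII_ATPM")[1, "lower"]), 0)
  # and grows on ammonium
  g <- fba(apply_constraints(r0, "ammonium"))
  expect_gt(g$objective_value, 0)
  expect_error(rescale_nodulation(holo, 1), "nodulation fraction")
})

test_that("closing the root-to-zone-III links starves the symbiosis", {
  holo <- toy_holo_fx()
  inbound <- intersect(c("LNK_sucr_Root_NoduleIII", "LNK_nh3_Root_NoduleIII",
                         "LNK_ala_Root_NoduleIII"), holo$model$reactions$id)
  m <- set_bounds(holo$model, inbound, lb = 0, ub = 0)
  sol <- fba(m)
  expect_true(sol$status == "infeasible" || sol$objective_value < 1e-9)
})

test_that("zone III embedding without proton access cannot fix nitrogen", {
  pa <- proton_access_test(toy_holo_fx())
  expect_gt(pa$access_on, 0)
  expect_equal(pa$access_off, 0, tolerance = 1e-9)
})
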