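test_that("exogenous ammonium raises growth monotonically, more so with free nodulation", {
  holo <- toy_holo_fx()
  grid <- c(0, 2, 5, 10)
  te <- ammonium_titration(holo, "vary_efficiency", nh4_grid = grid)
  expect_true(all(diff(te$growth) >= -1e-6))
  # cap 0 equals the fixation-only optimum
  g0 <- growth_rate(holo, fba(holo))[["total"]] * 24
  expect_equal(te$growth[1], g0, tolerance = 1e-4)
  tn <- ammonium_titration(holo, "vary_nodulation", nh4_grid = grid,
                           f_max = 0.10)
  expect_true(all(diff(tn$growth) >= -1e-6))
  # freeing the nodulation fraction can only help relative to the same
  # efficiency at the default f
  fixed <- vapply(grid, function(cap) {
    h <- apply_constraints(holo, "ammonium", nh4_cap = cap)
    h <- set_fixation_efficiency(h, 150)
    growth_rate(h, fba(h))[["total"]] * 24
  }, numeric(1))
  expect_true(all(tn$growth >= fixed - 1e-6))
  # with abundant ammonium the optimal nodule investment collapses
  expect_lt(tn$f_opt[length(grid)], tn$f_opt[1])
  # both curves stay below the non-nodulated ammonium maximum
  gmax <- cost_decomposition(holo)$growth[["ammonium"]]
  expect_true(all(te$growth <= gmax + 1e-6))
})

test_that("fixation Pareto curve collapses under the oxygen cap, declines gently without", {
  holo <- toy_holo_fx()
  capped <- pareto_fixation(holo, seq(0, 300, 15))
  # zero efficiency, zero growth (no nitrogen source)
  expect_lt(capped$growth[1], 1e-9)
  feas <- capped$status == "optimal" & capped$growth > 1e-9
  # linear rise to the optimum ...
  rising <- which(feas)
  expect_gt(length(rising), 3)
  expect_true(all(diff(capped$growth[rising]) > 0))
  # ... then an abrupt end of the feasible set (collapse), within ~10%
  # above the best efficiency
  expect_true(any(capped$status == "infeasible"))
  e_best <- capped$efficiency[which.max(capped$growth)]
  e_dead <- min(capped$efficiency[capped$status == "infeasible" &
                                  capped$efficiency > e_best])
  expect_lte(e_dead, 1.1 * e_best + 15)  # within one grid step of +10%

  free <- pareto_fixation(holo, seq(0, 600, 30), zone3_o2_cap = "none")
  expect_true(all(free$status == "optimal"))
  i_best <- which.max(free$growth)
  expect_gt(i_best, 2)
  expect_lt(i_best, nrow(free))
  # decline above the optimum is shallower than the rise below it
  rise <- mean(diff(free$growth[1:i_best]))
  fall <- mean(diff(free$growth[i_best:nrow(free)]))
  expect_gt(rise, 0)
  expect_lt(fall, 0)
  expect_gt(rise, abs(fall))
})

test_that("nodulation Pareto curve is concave with a steeper below-optimum arm", {
  holo <- toy_holo_fx()
  pn <- pareto_nodulation(holo, seq(0, 0.15, 0.0125))
  expect_lt(pn$growth[1], 1e-9)  # f = 0: no fixation, no nitrogen
  i_best <- which.max(pn$growth)
  expect_gt(i_best, 1); expect_lt(i_best, nrow(pn))
  feas <- pn$status == "optimal"
  # discrete concavity over the feasible stretch
  g <- pn$growth[feas]
  expect_true(all(diff(diff(g)) < 1e-6))
  slope_below <- (pn$growth[i_best] - pn$growth[1]) /
    (pn$f[i_best] - pn$f[1])
  after <- max(which(feas))
  slope_above <- (pn$growth[after] - pn$growth[i_best]) /
    (pn$f[after] - pn$f[i_best])
  expect_gt(slope_below, 0)
  expect_lt(slope_above, 0)
  # below-optimum changes bite harder (published: about 3-fold)
  expect_gt(slope_below / abs(slope_above), 1.5)
})

test_that("optimising nodulation per efficiency shows diminishing returns and nested caps", {
  holo <- toy_holo_fx()
  grid <- c(75, 150, 300, 600)
  free <- optimize_nodulation_curve(holo, grid)
  expect_true(all(diff(free$growth) >= -1e-6))       # more efficiency never hurts
  expect_true(all(diff(free$f_opt) <= 1e-4))          # optimal f shrinks with e
  # halving the efficiency from the maximum keeps most of the growth
  expect_gte(free$growth[grid == 300], 0.85 * free$growth[grid == 600])
  cap10 <- optimize_nodulation_curve(holo, grid, f_cap = 0.10)
  cap05 <- optimize_nodulation_curve(holo, grid, f_cap = 0.05)
  # nested feasible sets, up to golden-section termination noise
  expect_true(all(cap05$growth <= cap10$growth + 1e-4))
  expect_true(all(cap10$growth <= free$growth + 1e-4))
})

test_that("the metabolic cost decomposition orders the four scenarios", {
  cd <- cost_decomposition(toy_holo_fx())
  r <- cd$ratios
  expect_lt(r[["r1"]], r[["r2"]])
  expect_lt(r[["r2"]], r[["r3"]])
  expect_lt(r[["r3"]], 1)
  expect_equal(sum(cd$shares), 1, tolerance = 1e-9)
  expect_true(all(cd$shares > 0))
})

test_that("carbon switches from sucrose to dicarboxylates as the oxidase cap falls", {
  holo <- toy_holo_sucrose_fx()
  caps <- c(0, 0.5, 1, 2, 5, 1000)
  cs <- carbon_switch_scan(holo, caps)
  expect_true(all(cs$status == "optimal"))
  expect_true(all(diff(cs$growth) >= -1e-6))                 # growth monotone in cap
  expect_true(all(diff(cs$sucrose_uptake) >= -1e-6))         # sucrose rises with cap
  expect_true(all(diff(cs$dicarboxylate_uptake) <= 1e-6))    # dicarbs fall with cap
  # a sharp extinction threshold: no sucrose below it, sucrose above it
  expect_equal(cs$sucrose_uptake[1], 0, tolerance = 1e-6)
  expect_gt(cs$sucrose_uptake[nrow(cs)], 0.1)
  expect_gt(cs$dicarboxylate_uptake[1], 1)
  expect_lt(abs(cs$dicarboxylate_uptake[nrow(cs)]), 1e-6)
  # with an unconstrained oxidase the sucrose-enabled model outgrows the
  # dicarboxylate-only model (published direction: +6.4%)
  g_dic <- fba(toy_holo_fx())$objective_value
  g_suc <- fba(holo)$objective_value
  expect_gt(g_suc, g_dic * 1.001)
})

test_that("proton access decides whether dicarboxylates can support fixation", {
  pa <- proton_access_test(toy_holo_fx())
  expect_gt(pa$access_on, 0)
  expect_equal(pa$access_off, 0, tolerance = 1e-9)
  # growth with access on matches the default build
  expect_equal(pa$access_on,
               growth_rate(toy_holo_fx(), fba(toy_holo_fx()))[["total"]] * 24,
               tolerance = 1e-6)
})

test_that("the substrate screen separates catabolisable and dead substrates", {
  b <- generate_toy_bacterium(toy_config(include_sucrose_bacteroid_path = TRUE))
  scr <- substrate_screen(b, c("glc", "fru", "sucr", "succ", "mal", "fum",
                               "gln", "xyl", "nosuchthing"))
  got <- stats::setNames(scr$call, scr$substrate)
  expect_equal(unname(got["glc"]), "growth")
  expect_equal(unname(got["sucr"]), "growth")
  expect_equal(unname(got["succ"]), "growth")
  expect_equal(unname(got["gln"]), "growth")
  expect_equal(unname(got["xyl"]), "no growth")     # exchange but no pathway
  expect_equal(unname(got["nosuchthing"]), "untestable")
})

test_that("bacteroid-normalised fluxes divide by the bacteroid mass fraction", {
  spec <- holobiont_spec()
  expect_equal(per_bacteroid(1, spec), 1 / 0.005)
  expect_equal(per_bacteroid(3.4, spec, f = 0.04), 3.4 / 0.01)
})

test_that("the command line builds deterministically and reports schema'd scans", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "h1"); out2 <- file.path(dir, "h2")
  expect_equal(run_cli(c("build", "--toy", "--seed", "1", "--out", out1)), 0L)
  expect_equal(run_cli(c("build", "--toy", "--seed", "1", "--out", out2)), 0L)
  expect_identical(readLines(file.path(out1, "reactions.tsv")),
                   readLines(file.path(out2, "reactions.tsv")))
  scanfile <- file.path(dir, "pn.tsv")
  expect_equal(run_cli(c("scan", "pareto_nodulation", "--toy",
                         "--out", scanfile)), 0L)
  df <- utils::read.delim(scanfile)
  expect_true(all(c("f", "growth", "status") %in% names(df)))
  decfile <- file.path(dir, "cd.json")
  expect_equal(run_cli(c("decompose", "--toy", "--out", decfile)), 0L)
  dec <- jsonlite::read_json(decfile)
  expect_length(dec$ratios, 4)
  expect_length(dec$shares, 3)
  # bad arguments exit 2
  expect_equal(run_cli(c("frobnicate")), 2L)
  expect_equal(run_cli(c("scan", "nosuchscan", "--toy", "--out", scanfile)), 2L)
})
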