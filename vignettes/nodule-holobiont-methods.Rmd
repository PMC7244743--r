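---
title: "Modelling a nodulated legume as one metabolic system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a nodulated legume as one metabolic system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnod)
```

# The model

`vnod` treats a nodulated legume and its rhizobial endosymbionts as a
single stoichiometric system. Two organism-level reconstructions — a plant
and a bacterium — are replicated into tissues: shoot, root, and five nodule
developmental zones (meristem I; distal and proximal differentiation zones
IId and IIp; interzone IZ; nitrogen-fixation zone III). Bacteroids are
embedded in the four infected zones behind an explicit peribacteroid-space
(PBS) compartment, so that every metabolite a bacteroid sees has first been
delivered across the plant membrane. All fluxes are expressed per gram of
total plant dry weight per hour (growth additionally per day, x24), which
lets one oxygen cap or maintenance term constrain tissues of very different
mass on a common scale.

Flux balance analysis then maximises a composite biomass reaction that
consumes the tissue biomass species in fixed proportions: 0.65333 shoot +
0.32666 root + 0.00100 zone I + 0.00675/0.00225 (IId plant/bacteroid) +
0.00675/0.00225 (IIp) + 0.00075/0.00025 (IZ) per gram of total biomass.
Encoding the weights as a *reaction* rather than as objective coefficients
forces the tissues to grow in those ratios instead of letting the optimiser
put everything into the cheapest tissue. Zone III carries no biomass term:
its plant cells and bacteroids are terminally differentiated and do not
grow, but they do pay maintenance and host all nitrogen fixation.

Assumptions inherited from this formulation: steady state (no storage
pools), a single static tissue composition (no development over time), and
purely stoichiometric limits (no enzyme kinetics or regulation beyond the
on/off expression gating described below).

# Assembly steps

1. **Replication.** Every metabolite, reaction, gene and compartment id is
   prefixed with the tissue tag (`Root_`, `BacteroidIII_`, ...); gene rules
   are rewritten accordingly, so tissue-local deletions are well defined.
2. **Inter-tissue transport.** A transport table (metabolite, from, to,
   reversible, costed) creates one transfer reaction per row. Costed rows
   additionally hydrolyse 0.25 mol ATP per mol transported in the *source*
   tissue; a reversible costed row therefore becomes two opposed
   irreversible reactions so the exporter always pays. In the default
   table sucrose flows shoot to root to every zone; ammonia moves
   reversibly between root, shoot and zones; nitrate moves root to shoot;
   alanine and pyruvate return from the zones to the root (nodules export
   amino compounds and organic acids, and these two routes are what lets a
   hypoxic zone III cell regenerate ATP glycolytically). Gases, water and
   soil nutrients are exchanged directly by each tissue rather than routed
   through the root — a simplification that leaves the carbon and nitrogen
   economy, which is what the experiments probe, fully coupled.
3. **Peribacteroid embedding.** The bacterium's external compartment
   becomes `PBS_<zone>`; its environment exchanges are deleted. Whitelisted
   nutrients get plant-to-PBS transfer reactions (carbon transfers pay the
   0.25 ATP diffusion cost), gases and water diffuse freely, NH4+ returns
   to the plant (reversibly in the differentiation zones, where bacteroids
   still grow and need nitrogen), and an ATP-driven plant proton pump
   acidifies the PBS (1 ATP per H+). In zone III only succinate, malate
   and fumarate may cross (<= 1000 umol h-1 gDW-1 each); the
   differentiation zones also receive sugars and glutamine.
4. **Expression gating.** Per-zone on/off calls close (bounds zero) every
   reaction whose gene rule evaluates false with the zone's off genes
   inactive. Exchanges, transporters and orphan (ruleless) reactions are
   never gated: gating follows gene evidence, and transport across the
   peribacteroid membrane is controlled by the embedding whitelist instead.
5. **Constraints.** Light and CO2 uptake at the shoot <= 1000; zone III
   oxygen <= 8.9847 umol h-1 gDW-1 (the micro-aerobic fixation zone);
   forced ATP-hydrolysis maintenance per tissue (shoot 74, root 37; plant
   zones 0.111/0.750/0.750/0.083/0.833; bacteroids 5.7/5.7/0.6/6.3, all
   umol h-1 per g plant dry weight); under the nitrogen-fixation scenario
   the root ammonium and nitrate uptakes are zero (export of surplus fixed
   nitrogen stays open).
6. **Pruning.** Reactions touching a metabolite that no reaction can
   produce, or none can consume, are removed to a fixpoint. The scan is
   bound-aware, so reactions closed by gating count as neither producers
   nor consumers and whole gated-off branches disappear; reactions with
   objective weight are protected (an error identifies the dead-end).

# Varying the nodulation fraction

For scans in which f (nodule share of total dry biomass, default 0.02)
varies, `rescale_nodulation()` removes the nodule terms from the objective
(shoot/root rescaled to 2/3 and 1/3) and instead forces nodule plus
bacteroid biomass through a sink reaction coupled to plant growth through a
pseudo-metabolite: per gram of plant biomass the sink drains f/(1-f) grams
of nodule tissue at the default internal zone proportions. Nodule and
bacteroid maintenance and the zone III oxygen cap scale linearly in
f/0.02. Linear scaling is a design choice — the oxygen supply of a nodule
plausibly grows with nodule mass, but any sub- or super-linear geometry
effect is outside the model. At f = 0 the model reduces to a non-nodulated
plant with no sink and no nodule maintenance.

The N2-fixation efficiency e is defined here in nitrogen units, umol N
h-1 per gram nodule dry weight, so the per-plant fixation flux is e*f and
the zone III nitrogenase flux is fixed at e*f/2 (two N per N2) when a scan
controls the efficiency. Fixing rather than bounding the flux makes the
efficiency the controlled variable, which is what a Pareto frontier over
e requires; when no scan controls it the nitrogenase is free and the
fixation rate is an output. One consequence worth knowing: in the
cost-decomposition scenarios the "non-nodulated but fixing" model keeps
the default zone III oxygen cap rather than the f-scaled one, since
fixation there is deliberately unlinked from nodule mass.

# The toy holobiont

The generator produces a deliberately small plant (light + CO2 to triose,
sucrose synthesis/cleavage through a single sucrose-synthase analogue
gene, lumped glycolysis to PEP, PEP carboxylase to oxaloacetate and on to
malate/fumarate/succinate, a terminal oxidase + ATP synthase pair coupled
through an abstract proton-motive quantum, nitrate reductase, GS/GOGAT,
alanine transaminase, biomass, maintenance) and bacterium (dicarboxylate
proton symport on one transporter gene, sugar and glutamine uptake, an
optional sucrose route, lumped TCA, oxidase/synthase, ferredoxin-style
electron supply, nitrogenase N2 + 8 H+ + 8 e- + 16 ATP -> 2 NH3 + H2,
ammonium export as NH4+, GS/GOGAT, biomass, NGAM).

Chemistry conventions: neutral (fully protonated) species except NAD+
(+1), H+ (+1), NH4+ (+1) and the electron (-1); photons, electrons and the
proton-motive quantum are massless. Every internal reaction is element-
and charge-balanced and the generator verifies this when it runs, so the
balance checker's positive results on the toy are a real invariant, not a
fixture convention. Compositions were chosen once at physiologically
sensible magnitudes — plant biomass 2000 umol N and ~28 mmol C per gram
(a nitrogen-rich legume shoot), bacterial biomass 4000 umol N/g, growth-
associated ATP 15 mmol/g, P/O = 2 — and the fixation-limited growth rate,
fixation rate and nodule carbon cost that the acceptance script reports
*emerge* from those choices plus the published constraint set.

The proton economy is the part of the design that carries the most
science. Fixed nitrogen leaves the bacteroid as NH4+, so every nitrogen
exported consumes one cytosolic proton; the bacteroid's internal redox
bookkeeping (every dehydrogenase emits the proton its oxidase consumes)
can never mint that proton, so it must come from the peribacteroid space —
delivered by the plant's ATP-driven pump and imported by the dicarboxylate
symporters or the proton channel. Switching `bacteroid_proton_access` off
turns the symporters into uniporters and removes the channel, leaving the
bacteroid with carbon and oxygen but no way to pay the export cost:
fixation-dependent growth becomes impossible while ammonium-fed growth is
untouched. That is the mechanism behind the proton-access experiment.

What the toy does **not** emulate: the size and redundancy of real
reconstructions (dozens of reactions, one gene each, versus thousands with
complex GPRs), subcellular compartments beyond cytosol/exterior/PBS,
biomass compositions at metabolite resolution, cofactor diversity (one
NAD pool stands in for NAD(P)H and quinones), and any quantitative
correspondence of its emergent numbers with measured plant physiology
beyond order of magnitude. Passing the toy suite therefore demonstrates
that the *procedures* — integration, gating, deletion semantics, scans,
decompositions — behave correctly on a system with the right structure;
it does not validate any particular full-size reconstruction.

# Expression calls

Zone calls for the toy are generated directly from the developmental
logic: nitrogenase on only in zone III bacteroids; growth machinery,
sugar uptake and anaplerosis off in zone III bacteroids; plant growth
machinery off in zone III tissue; everything on in zones I-IZ; decoy genes
off everywhere; the meristem carries no bacterial entries. For deriving
calls from abundance data, `call_from_abundance()` applies a per-zone
quantile rule (gene on iff abundance >= the given quantile of the zone's
nonzero abundances). A quantile rule is a documented stand-in: it is
deterministic and scale-free, but any real thresholding pipeline
(library-size normalisation, organism-specific cutoffs) can be substituted
by supplying the calls directly.

# Numerical choices

* Linear programs are solved by a bounded-variable two-phase primal
  simplex (dense basis inverse, sparse pricing, periodic refactorisation,
  Bland's-rule fallback on degeneracy stalls). Feasibility and optimality
  tolerances are 1e-8/1e-9; all scientific comparisons use 1e-6; fluxes
  below 1e-9 count as zero. Flux variability re-solves from the warm basis
  with only the objective changing, which is why it is cheap.
* Degenerate optima: objective values are unique, flux vectors are not.
  Reported flux routes (the sucrose/dicarboxylate split in particular) use
  parsimonious FBA — total absolute flux minimised subject to >= 99.99% of
  the optimum — so they are reproducible; plain FBA is used where only the
  objective matters.
* Robustness scans bracket the non-zero-growth flux interval by bisection
  to 1e-4 of the feasible range (the published procedure names the range
  identification but not the method), then evaluate an even grid inside it.
* Inner maximisations over f (ammonium titration with free nodulation, the
  optimal-nodulation curve) use golden-section search, tolerance 1e-4 on
  f; the LP value is piecewise-linear and unimodal in f over the scanned
  ranges, which golden-section handles, and the termination tolerance
  shows up as ~1e-5 noise in compared growth values.
* Balance checking treats an empty formula as "massless" (photons,
  electrons — determinably zero) and a missing formula as "undetermined"
  (reported, never an error). Stoichiometric tolerance 1e-6.
* The objective weights use the published five-decimal constants at
  f = 0.02 (sum 0.99999) and scale exactly from them — shoot/root by
  (1-f)/0.98, zones by f/0.02 — so at f = 0 the shoot weight is
  0.65333/0.98 ~ 0.66666, the published rounding carried through rather
  than 2/3 exactly.

# Known limitations

* Double gene deletions are global-only; there is no MOMA/ROOM-style
  knockout prediction and no flux sampling.
* The transport whitelists (inter-tissue and plant-PBS) are explicit,
  editable tables; they encode a defensible default nutrient economy, not
  a curated exchange inventory.
* SBML support covers Level 3 + fbc (bounds, gene associations, formulas,
  charges, objectives) and a pragmatic Level 2 reader (kineticLaw bounds,
  GENE_ASSOCIATION notes); exotic SBML constructs (rules, events, species
  types) are out of scope.
* The simplex is dense in its basis handling; it is sized for models up to
  roughly 10^4 reactions, not for community models an order of magnitude
  larger.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run everything on the generated
toy holobiont (about 600 reactions and 490 metabolites after pruning).
Scan grids: fixation efficiency 0-300 in steps of 10-15 (collapse scans)
or 0-600 in steps of 20-60 (decline and optimal-nodulation scans);
nodulation 0-0.15 in steps of 0.005-0.0125; ammonium caps 0-50; 13-21
oxidase cap points, log-spaced. These sizes resolve every qualitative
feature the experiments assert (kinks, thresholds, slope asymmetries)
while keeping a full run in the minutes range; the same functions accept
denser grids unchanged.
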