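## Deterministic generator of a miniature plant / bacterium model pair that
## carries the metabolic structure the nodule analyses assume: sucrose
## photosynthate, glycolysis to PEP, the PEP-carboxylase route to
## C4-dicarboxylates, proton-symport dicarboxylate uptake, nitrogenase,
## GS/GOGAT ammonium assimilation, and tissue maintenance. All internal
## reactions are element- and charge-balanced; the generator verifies this
## at build time. Chemistry conventions: neutral (fully protonated) species
## except NAD+ (+1), H+ (+1), NH4+ (+1) and the electron (-1); photons,
## electrons and the proton-motive quantum `pmf` are massless (empty
## formula). Redox is carried by a single NAD pool; respiration is split
## into a terminal oxidase that pumps `pmf` and an ATP synthase that
## consumes it, so the oxidase flux is an explicit, cappable handle.

#' Configuration for the toy holobiont generator
#'
#' @param seed integer; drives the (small) random component, the placement
#'   of decoy dead-end reactions. The same seed yields byte-identical
#'   models and calls.
#' @param include_sucrose_bacteroid_path add sucrose transport/catabolism
#'   to the bacterium (used by the carbon-source-switch analysis).
#' @param nitrogenase_atp_per_n2 ATP hydrolysed per N2 fixed (textbook 16).
#' @param o2_per_atp_respiration O2 consumed per ATP by oxidative
#'   phosphorylation (default 0.25, i.e. P/O = 2).
#' @param decoy_reaction_count dead-end decoy reactions per organism,
#'   fodder for the pruning step.
#' @return object of class `toy_config`.
#' @export
toy_config <- function(seed = 1L, include_sucrose_bacteroid_path = FALSE,
                       nitrogenase_atp_per_n2 = 16,
                       o2_per_atp_respiration = 0.25,
                       decoy_reaction_count = 5L) {
  stopifnot(nitrogenase_atp_per_n2 > 0, o2_per_atp_respiration > 0,
            decoy_reaction_count >= 0)
  structure(list(seed = as.integer(seed),
                 include_sucrose_bacteroid_path = include_sucrose_bacteroid_path,
                 nitrogenase_atp_per_n2 = nitrogenase_atp_per_n2,
                 o2_per_atp_respiration = o2_per_atp_respiration,
                 decoy_reaction_count = as.integer(decoy_reaction_count)),
            class = "toy_config")
}

## species table: id (without compartment suffix), Hill formula, charge
TOY_SPECIES <- data.frame(
  species = c("photon", "pmf", "e", "h", "h2o", "o2", "co2", "n2", "h2",
              "nh3", "nh4", "no3", "pi", "atp", "adp", "nad", "nadh",
              "triose", "glc", "fru", "sucr", "pep", "pyr", "oaa", "mal",
              "fum", "succ", "akg", "glu", "gln", "ala", "xyl"),
  formula = c("", "", "", "H", "H2O", "O2", "CO2", "N2", "H2",
              "H3N", "H4N", "HNO3", "H3O4P", "C10H16N5O13P3",
              "C10H15N5O10P2", "C21H27N7O14P2", "C21H28N7O14P2",
              "C3H6O3", "C6H12O6", "C6H12O6", "C12H22O11", "C3H4O3",
              "C3H4O3", "C4H4O5", "C4H6O5", "C4H4O4", "C4H6O4", "C5H6O5",
              "C5H9NO4", "C5H10N2O3", "C3H7NO2", "C5H10O5"),
  charge = c(0, 0, -1, 1, 0, 0, 0, 0, 0,
             0, 1, 0, 0, 0, 0, 1, 0,
             0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE)

toy_add_species <- function(model, species, compartment_suffix) {
  for (i in seq_len(nrow(TOY_SPECIES))) {
    if (!TOY_SPECIES$species[i] %in% species) next
    sid <- paste0(TOY_SPECIES$species[i], "_", compartment_suffix)
    model <- add_metabolite(model, sid, name = TOY_SPECIES$species[i],
                            formula = TOY_SPECIES$formula[i],
                            charge = TOY_SPECIES$charge[i],
                            compartment = compartment_suffix)
  }
  model
}

## add a reaction from an equation string, asserting mass/charge balance
## unless it touches a formula-free pseudo-metabolite or is flagged
toy_rxn <- function(model, id, eq, lb = 0, ub = 1000, gene = "",
                    subsystem = "", check = TRUE) {
  st <- parse_equation(eq, id)
  model <- add_reaction(model, id, st, lb = lb, ub = ub, gene_rule = gene,
                        subsystem = subsystem)
  if (check) {
    rep <- check_balance(model, id)
    if (!isTRUE(rep$balanced))
      stop("toy generator produced an unbalanced reaction ", id, ": ",
           paste(utils::capture.output(print(rep)), collapse = " "))
  }
  model
}

toy_exchange <- function(model, species, lb = 0, ub = 1000) {
  toy_rxn(model, paste0("EX_", species),
          paste0("1 ", species, "_e", " --> "), lb = lb, ub = ub,
          subsystem = "exchange", check = FALSE)
}

toy_transport <- function(model, species, lb = -1000, ub = 1000, gene = "") {
  toy_rxn(model, paste0("T_", species),
          paste0("1 ", species, "_e --> 1 ", species, "_c"),
          lb = lb, ub = ub, gene = gene, subsystem = "transport")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

toy_add_decoys <- function(model, prefix, n, seed) {
  if (n == 0L) return(model)
  feed <- c("glc", "pyr", "mal")
  picks <- with_seed(seed, sample(feed, n, replace = TRUE))
  for (k in seq_len(n)) {
    src <- picks[k]
    did <- sprintf("dec%02d", k)
    f <- TOY_SPECIES$formula[TOY_SPECIES$species == src]
    model <- add_metabolite(model, paste0(did, "_c"), name = did,
                            formula = f, charge = 0, compartment = "c")
    model <- toy_rxn(model, paste0("DECOY", sprintf("%02d", k)),
                     sprintf("1 %s_c --> 1 %s_c", src, did),
                     gene = paste0(prefix, "dec", sprintf("%02d", k)),
                     subsystem = "decoy")
  }
  model
}

#' Generate the toy plant model
#'
#' Light- and CO2-driven triose production, sucrose synthesis and cleavage
#' (a single sucrose-synthase analogue gene, `psusA`, carries both), a
#' lumped glycolysis to PEP, the PEP carboxylase / malate dehydrogenase /
#' fumarase / succinate dehydrogenase route to C4-dicarboxylates,
#' mitochondrial respiration with an explicit terminal oxidase, nitrate
#' reduction, GS/GOGAT ammonium assimilation, an alanine transaminase, a
#' biomass reaction (2000 umol N and 28200 umol C per g dry weight) and an
#' ATP-hydrolysis maintenance reaction. Exchanges exist for light, CO2, O2,
#' ammonium, nitrate, water, phosphate, sucrose and the dicarboxylates.
#'
#' @param config a [toy_config()].
#' @return a `metabolic_model`.
#' @export
generate_toy_plant <- function(config = toy_config()) {
  stopifnot(inherits(config, "toy_config"))
  p <- 1.5 / config$o2_per_atp_respiration  # pmf per NADH at the oxidase
  m <- empty_model("toy_plant")
  cyto <- setdiff(TOY_SPECIES$species, c("xyl", "e"))
  m <- toy_add_species(m, cyto, "c")
  ext <- c("photon", "co2", "o2", "nh4", "no3", "h2o", "pi", "sucr",
           "mal", "fum", "succ", "n2", "h2", "nh3", "h")
  m <- toy_add_species(m, ext, "e")

  ## exchanges (negative flux = uptake); defaults describe a free-living,
  ## ammonium-sufficient plant
  m <- toy_exchange(m, "photon", lb = -1000, ub = 0)
  m <- toy_exchange(m, "co2", lb = -1000)
  m <- toy_exchange(m, "o2", lb = -1000)
  m <- toy_exchange(m, "nh4", lb = -1000)
  m <- toy_exchange(m, "no3", lb = -1000)
  m <- toy_exchange(m, "h2o", lb = -1000)
  m <- toy_exchange(m, "pi", lb = -1000)
  m <- toy_exchange(m, "sucr")
  m <- toy_exchange(m, "mal")
  m <- toy_exchange(m, "fum")
  m <- toy_exchange(m, "succ")
  m <- toy_exchange(m, "n2", lb = -1000)
  m <- toy_exchange(m, "h2")
  m <- toy_exchange(m, "nh3")
  m <- toy_exchange(m, "h")

  for (sp in setdiff(ext, "h")) m <- toy_transport(m, sp)
  ## plasma-membrane proton extrusion (rhizosphere acidification);
  ## irreversible, so external acid is never a net proton source
  m <- toy_rxn(m, "T_hout", "1 h_c --> 1 h_e", subsystem = "transport")

  ## photosynthesis
  m <- toy_rxn(m, "PSII", "2 photon_c + 1 h2o_c + 1 nad_c --> 0.5 o2_c + 1 nadh_c + 1 h_c",
               gene = "ppsbA", subsystem = "photosynthesis")
  m <- toy_rxn(m, "CPHOS", "2 photon_c + 1 adp_c + 1 pi_c --> 1 atp_c + 1 h2o_c",
               gene = "ppetA", subsystem = "photosynthesis")
  m <- toy_rxn(m, "CALVIN",
               "3 co2_c + 6 nadh_c + 6 h_c + 6 atp_c + 3 h2o_c --> 1 triose_c + 6 nad_c + 6 adp_c + 6 pi_c",
               gene = "prbcL", subsystem = "photosynthesis")

  ## carbohydrate interconversion
  m <- toy_rxn(m, "GLUNEO", "2 triose_c --> 1 glc_c", gene = "pfbaA",
               subsystem = "carbohydrate")
  m <- toy_rxn(m, "SUCSYN", "4 triose_c + 1 atp_c --> 1 sucr_c + 1 adp_c + 1 pi_c",
               gene = "psusA", subsystem = "carbohydrate")
  m <- toy_rxn(m, "SUCHYD", "1 sucr_c + 1 h2o_c --> 1 glc_c + 1 fru_c",
               gene = "psusA", subsystem = "carbohydrate")
  m <- toy_rxn(m, "FRUISO", "1 fru_c --> 1 glc_c", gene = "ppgiA",
               subsystem = "carbohydrate")

  ## glycolysis and the dicarboxylate route
  m <- toy_rxn(m, "GLYC", "1 glc_c + 2 nad_c --> 2 pep_c + 2 nadh_c + 2 h_c",
               gene = "ppgkA", subsystem = "glycolysis")
  m <- toy_rxn(m, "PK", "1 pep_c + 1 adp_c + 1 pi_c --> 1 pyr_c + 1 atp_c + 1 h2o_c",
               gene = "ppykA", subsystem = "glycolysis")
  m <- toy_rxn(m, "PEPC", "1 pep_c + 1 co2_c --> 1 oaa_c",
               gene = "pppcA", subsystem = "anaplerosis")
  m <- toy_rxn(m, "MDH", "1 mal_c + 1 nad_c --> 1 oaa_c + 1 nadh_c + 1 h_c",
               lb = -1000, gene = "pmdhA", subsystem = "TCA")
  m <- toy_rxn(m, "FUMR", "1 fum_c + 1 h2o_c --> 1 mal_c",
               lb = -1000, gene = "pfumA", subsystem = "TCA")
  m <- toy_rxn(m, "SDH", "1 succ_c + 1 nad_c --> 1 fum_c + 1 nadh_c + 1 h_c",
               lb = -1000, gene = "psdhA", subsystem = "TCA")
  m <- toy_rxn(m, "PDHTCA",
               "1 pyr_c + 3 h2o_c + 5 nad_c --> 3 co2_c + 5 nadh_c + 5 h_c",
               gene = "pidhA", subsystem = "TCA")
  m <- toy_rxn(m, "AKGSYN",
               "1 oaa_c + 1 pyr_c + 2 nad_c + 1 h2o_c --> 1 akg_c + 2 co2_c + 2 nadh_c + 2 h_c",
               gene = "pcsyA", subsystem = "TCA")

  ## respiration
  m <- toy_rxn(m, "MITOOX",
               sprintf("1 nadh_c + 1 h_c + 0.5 o2_c --> 1 nad_c + 1 h2o_c + %.17g pmf_c", p),
               gene = "pcoxA", subsystem = "respiration")
  m <- toy_rxn(m, "MITOATPS", "1 adp_c + 1 pi_c + 3 pmf_c --> 1 atp_c + 1 h2o_c",
               gene = "patpA", subsystem = "respiration")

  ## nitrogen assimilation
  m <- toy_rxn(m, "NR", "1 no3_c + 4 nadh_c + 4 h_c --> 1 nh3_c + 3 h2o_c + 4 nad_c",
               gene = "pniaA", subsystem = "nitrogen")
  m <- toy_rxn(m, "NH4D", "1 nh4_c --> 1 nh3_c + 1 h_c", lb = -1000,
               subsystem = "nitrogen")
  m <- toy_rxn(m, "GS", "1 glu_c + 1 nh3_c + 1 atp_c --> 1 gln_c + 1 adp_c + 1 pi_c",
               gene = "pglnA", subsystem = "nitrogen")
  m <- toy_rxn(m, "GOGAT", "1 gln_c + 1 akg_c + 1 nadh_c + 1 h_c --> 2 glu_c + 1 nad_c",
               gene = "pgltA", subsystem = "nitrogen")
  m <- toy_rxn(m, "ALT", "1 pyr_c + 1 glu_c --> 1 ala_c + 1 akg_c", lb = -1000,
               gene = "palaT", subsystem = "nitrogen")

  ## maintenance and biomass
  m <- toy_rxn(m, "ATPM", "1 atp_c + 1 h2o_c --> 1 adp_c + 1 pi_c",
               subsystem = "maintenance")
  m <- add_metabolite(m, "biomass_c", name = "plant biomass",
                      formula = NA_character_, charge = 0, compartment = "c")
  m <- toy_rxn(m, "BIOMASS",
               paste("3800 glc_c + 600 gln_c + 800 ala_c + 15000 atp_c + 15000 h2o_c",
                     "--> 15000 adp_c + 15000 pi_c + 1 biomass_c"),
               gene = "pgrwA", subsystem = "biomass", check = FALSE)
  m <- toy_rxn(m, "DM_biomass", "1 biomass_c --> ", subsystem = "biomass",
               check = FALSE)

  m <- toy_add_decoys(m, "p", config$decoy_reaction_count, config$seed)
  m$objective <- c(BIOMASS = 1)
  validate_model(m)
  m
}

#' Generate the toy bacterium model
#'
#' Proton-symport uptake of succinate/malate/fumarate (a single `bdctA`
#' transporter gene), glucose and fructose uptake, optionally sucrose
#' uptake plus cleavage, a lumped TCA cycle, a terminal oxidase and ATP
#' synthase, ferredoxin-style electron supply from NADH, nitrogenase
#' (`N2 + 8 H+ + 8 e- + ATP -> 2 NH3 + H2`, ATP count set by the
#' configuration), ammonium export as NH4+ (protonation in the cytosol, so
#' each nitrogen exported costs one cytosolic proton), an alanine export
#' route, GS/GOGAT, biomass and an NGAM ATP-hydrolysis reaction.
#'
#' @param config a [toy_config()].
#' @return a `metabolic_model`.
#' @export
generate_toy_bacterium <- function(config = toy_config()) {
  stopifnot(inherits(config, "toy_config"))
  p <- 1.5 / config$o2_per_atp_respiration
  m <- empty_model("toy_bacterium")
  cyto <- setdiff(TOY_SPECIES$species, c("photon", "no3", "triose", "xyl"))
  m <- toy_add_species(m, cyto, "c")
  ext <- c("succ", "mal", "fum", "glc", "fru", "o2", "co2", "h2o", "nh4",
           "nh3", "n2", "h2", "ala", "gln", "pi", "h", "xyl",
           if (config$include_sucrose_bacteroid_path) "sucr")
  m <- toy_add_species(m, ext, "e")

  ## default medium: glucose + ammonium, aerobic
  m <- toy_exchange(m, "glc", lb = -10)
  m <- toy_exchange(m, "fru")
  m <- toy_exchange(m, "succ")
  m <- toy_exchange(m, "mal")
  m <- toy_exchange(m, "fum")
  m <- toy_exchange(m, "o2", lb = -1000)
  m <- toy_exchange(m, "co2", lb = -1000)
  m <- toy_exchange(m, "h2o", lb = -1000)
  m <- toy_exchange(m, "nh4", lb = -1000)
  m <- toy_exchange(m, "nh3", lb = -1000, ub = 0)
  m <- toy_exchange(m, "n2", lb = -1000)
  m <- toy_exchange(m, "h2")
  m <- toy_exchange(m, "ala")
  m <- toy_exchange(m, "gln", lb = -1000, ub = 0)
  m <- toy_exchange(m, "pi", lb = -1000)
  m <- toy_exchange(m, "h", lb = -1000)
  m <- toy_exchange(m, "xyl", lb = -1000)
  if (config$include_sucrose_bacteroid_path) m <- toy_exchange(m, "sucr")

  ## transporters; the dicarboxylate carrier is a proton symporter
  for (dic in c("succ", "mal", "fum"))
    m <- toy_rxn(m, paste0("T_", dic),
                 sprintf("1 %s_e + 1 h_e --> 1 %s_c + 1 h_c", dic, dic),
                 gene = "bdctA", subsystem = "transport")
  m <- toy_rxn(m, "T_glc", "1 glc_e --> 1 glc_c", lb = -1000,
               gene = "bglcT", subsystem = "transport")
  m <- toy_rxn(m, "T_fru", "1 fru_e --> 1 fru_c", lb = -1000,
               gene = "bfruT", subsystem = "transport")
  if (config$include_sucrose_bacteroid_path) {
    m <- toy_rxn(m, "T_sucr", "1 sucr_e --> 1 sucr_c", lb = -1000,
                 gene = "bsucT", subsystem = "transport")
    m <- toy_rxn(m, "SUCHYD", "1 sucr_c + 1 h2o_c --> 1 glc_c + 1 fru_c",
                 gene = "bsucH", subsystem = "carbohydrate")
  }
  m <- toy_rxn(m, "T_nh4", "1 nh4_e --> 1 nh4_c", lb = -1000,
               gene = "bamtB", subsystem = "transport")
  ## ammonia diffuses in down its gradient; export of fixed nitrogen still
  ## has to leave as NH4+ (protonation cost), as across the acidified
  ## peribacteroid membrane
  m <- toy_rxn(m, "T_nh3in", "1 nh3_e --> 1 nh3_c", subsystem = "transport")
  ## glutamine import (proton symport): the amino-acid supply that sustains
  ## differentiating bacteroids even without their own glutamine synthetase
  m <- toy_rxn(m, "T_gln", "1 gln_e + 1 h_e --> 1 gln_c + 1 h_c",
               gene = "bgluP", subsystem = "transport")
  m <- toy_rxn(m, "T_ala", "1 ala_c + 1 h_c --> 1 ala_e + 1 h_e",
               subsystem = "transport")
  ## proton efflux (respiratory chain pumping, lumped); irreversible, so it
  ## can never act as a net proton source for the cytosol
  m <- toy_rxn(m, "T_hout", "1 h_c --> 1 h_e", subsystem = "transport")
  ## inward proton flow down the electrochemical gradient of an acidified
  ## exterior (peribacteroid space); this is the channel the proton-access
  ## analysis switches off
  m <- toy_rxn(m, "T_hin", "1 h_e --> 1 h_c", subsystem = "transport")
  for (sp in c("o2", "co2", "h2o", "n2", "h2", "pi"))
    m <- toy_transport(m, sp)

  ## central carbon metabolism
  m <- toy_rxn(m, "FRUISO", "1 fru_c --> 1 glc_c", gene = "bpgiA",
               subsystem = "carbohydrate")
  m <- toy_rxn(m, "GLYC", "1 glc_c + 2 nad_c --> 2 pep_c + 2 nadh_c + 2 h_c",
               gene = "bpgkA", subsystem = "glycolysis")
  m <- toy_rxn(m, "PK", "1 pep_c + 1 adp_c + 1 pi_c --> 1 pyr_c + 1 atp_c + 1 h2o_c",
               gene = "bpykA", subsystem = "glycolysis")
  m <- toy_rxn(m, "PYC", "1 pyr_c + 1 co2_c + 1 atp_c + 1 h2o_c --> 1 oaa_c + 1 adp_c + 1 pi_c",
               gene = "bpycA", subsystem = "anaplerosis")
  m <- toy_rxn(m, "PCK", "1 oaa_c + 1 atp_c + 1 h2o_c --> 1 pep_c + 1 co2_c + 1 adp_c + 1 pi_c",
               gene = "bpckA", subsystem = "gluconeogenesis")
  m <- toy_rxn(m, "SDH", "1 succ_c + 1 nad_c --> 1 fum_c + 1 nadh_c + 1 h_c",
               lb = -1000, gene = "bsdhA", subsystem = "TCA")
  m <- toy_rxn(m, "FUMR", "1 fum_c + 1 h2o_c --> 1 mal_c", lb = -1000,
               gene = "bfumC", subsystem = "TCA")
  m <- toy_rxn(m, "MDH", "1 mal_c + 1 nad_c --> 1 oaa_c + 1 nadh_c + 1 h_c",
               lb = -1000, gene = "bmdhA", subsystem = "TCA")
  m <- toy_rxn(m, "DME", "1 mal_c + 1 nad_c --> 1 pyr_c + 1 co2_c + 1 nadh_c + 1 h_c",
               gene = "bdmeA", subsystem = "TCA")
  m <- toy_rxn(m, "PDHTCA",
               "1 pyr_c + 3 h2o_c + 5 nad_c --> 3 co2_c + 5 nadh_c + 5 h_c",
               gene = "btcaA", subsystem = "TCA")
  m <- toy_rxn(m, "AKGSYN",
               "1 oaa_c + 1 pyr_c + 2 nad_c + 1 h2o_c --> 1 akg_c + 2 co2_c + 2 nadh_c + 2 h_c",
               gene = "bcsyA", subsystem = "TCA")

  ## respiration and electron supply
  m <- toy_rxn(m, "RESP",
               sprintf("1 nadh_c + 1 h_c + 0.5 o2_c --> 1 nad_c + 1 h2o_c + %.17g pmf_c", p),
               gene = "bctaA", subsystem = "respiration")
  m <- toy_rxn(m, "ATPS", "1 adp_c + 1 pi_c + 3 pmf_c --> 1 atp_c + 1 h2o_c",
               gene = "batpA", subsystem = "respiration")
  m <- toy_rxn(m, "FDX", "1 nadh_c --> 1 nad_c + 1 h_c + 2 e_c",
               gene = "bfdxA", subsystem = "nitrogen fixation")

  ## nitrogenase and nitrogen handling
  a <- config$nitrogenase_atp_per_n2
  m <- toy_rxn(m, "NIT",
               sprintf(paste("1 n2_c + 8 h_c + 8 e_c + %.17g atp_c + %.17g h2o_c",
                             "--> 2 nh3_c + 1 h2_c + %.17g adp_c + %.17g pi_c"),
                       a, a, a, a),
               gene = "bnifH", subsystem = "nitrogen fixation")
  m <- toy_rxn(m, "NH4D", "1 nh4_c --> 1 nh3_c + 1 h_c", lb = -1000,
               subsystem = "nitrogen")
  m <- toy_rxn(m, "GS", "1 glu_c + 1 nh3_c + 1 atp_c --> 1 gln_c + 1 adp_c + 1 pi_c",
               gene = "bglnA", subsystem = "nitrogen")
  m <- toy_rxn(m, "GOGAT", "1 gln_c + 1 akg_c + 1 nadh_c + 1 h_c --> 2 glu_c + 1 nad_c",
               gene = "bgltB", subsystem = "nitrogen")
  m <- toy_rxn(m, "GDH", "1 glu_c + 1 nad_c + 1 h2o_c --> 1 akg_c + 1 nh3_c + 1 nadh_c + 1 h_c",
               gene = "bgdhA", subsystem = "nitrogen")
  m <- toy_rxn(m, "AKGDH", "1 akg_c + 1 nad_c + 1 adp_c + 1 pi_c --> 1 succ_c + 1 co2_c + 1 nadh_c + 1 h_c + 1 atp_c",
               gene = "bsucA", subsystem = "TCA")
  m <- toy_rxn(m, "ALT", "1 pyr_c + 1 glu_c --> 1 ala_c + 1 akg_c", lb = -1000,
               gene = "balaT", subsystem = "nitrogen")

  ## maintenance (NGAM) and biomass
  m <- toy_rxn(m, "ATPM", "1 atp_c + 1 h2o_c --> 1 adp_c + 1 pi_c",
               lb = 50, subsystem = "maintenance")
  m <- add_metabolite(m, "biomass_c", name = "bacterial biomass",
                      formula = NA_character_, charge = 0, compartment = "c")
  m <- toy_rxn(m, "BIOMASS",
               paste("5000 pyr_c + 2000 gln_c + 15000 atp_c + 15000 h2o_c",
                     "--> 15000 adp_c + 15000 pi_c + 1 biomass_c"),
               gene = "bgrwA", subsystem = "biomass", check = FALSE)
  m <- toy_rxn(m, "DM_biomass", "1 biomass_c --> ", subsystem = "biomass",
               check = FALSE)

  m <- toy_add_decoys(m, "b", config$decoy_reaction_count, config$seed + 1L)
  m$objective <- c(BIOMASS = 1)
  validate_model(m)
  m
}

## zone tags of the five-zone nodule structure
PLANT_ZONES <- c("NoduleI", "NoduleIId", "NoduleIIp", "NoduleIZ", "NoduleIII")
BACTEROID_ZONES <- c("BacteroidIId", "BacteroidIIp", "BacteroidIZ", "BacteroidIII")
TISSUE_TAGS <- c("Shoot", "Root", PLANT_ZONES)

#' Zone-wise expression calls for the toy holobiont
#'
#' Encodes the developmental logic of an indeterminate nodule: nitrogenase
#' is expressed only in the nitrogen-fixation zone (zone III) bacteroids;
#' growth machinery (biomass), sugar uptake and anaplerosis are switched
#' off in zone III bacteroids (terminally differentiated, non-growing
#' cells); the plant growth machinery is off in zone III plant tissue; all
#' genes are on in zones I-IZ; decoy genes are off everywhere. Zone I has
#' no bacterial entries (the meristem is uninfected). Genes not listed in a
#' zone default to "on".
#'
#' @param config a [toy_config()].
#' @param plant,bacterium models from [generate_toy_plant()] /
#'   [generate_toy_bacterium()].
#' @return an `expression_call_set`.
#' @export
generate_zone_calls <- function(config, plant, bacterium) {
  stopifnot(inherits(config, "toy_config"))
  pdec <- grep("^pdec", plant$genes, value = TRUE)
  bdec <- grep("^bdec", bacterium$genes, value = TRUE)

  off <- function(genes) stats::setNames(rep("off", length(genes)), genes)
  on <- function(genes) stats::setNames(rep("on", length(genes)), genes)

  calls <- list(
    NoduleI = off(pdec),
    NoduleIId = off(pdec),
    NoduleIIp = off(pdec),
    NoduleIZ = off(pdec),
    NoduleIII = c(off(c("pgrwA", pdec))),
    BacteroidIId = c(off(c("bnifH", bdec))),
    BacteroidIIp = c(off(c("bnifH", bdec))),
    BacteroidIZ = c(off(c("bnifH", bdec))),
    BacteroidIII = c(on("bnifH"),
                     off(c("bgrwA", "bglcT", "bfruT", "bpycA", "bpckA", bdec))))
  known <- c(plant$genes, bacterium$genes)
  unknown <- setdiff(unique(unlist(lapply(calls, names))), known)
  if (length(unknown))
    stop("expression calls reference unknown genes: ",
         paste(unknown, collapse = ", "))
  expression_call_set(calls)
}

#' Construct an expression call set
#'
#' @param calls named list: zone tag -> named character vector of
#'   `"on"`/`"off"` calls by gene id. Genes not listed are implicitly on.
#' @return object of class `expression_call_set`.
#' @export
expression_call_set <- function(calls) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  for (z in names(calls)) {
    bad <- setdiff(unique(calls[[z]]), c("on", "off"))
    if (length(bad)) stop("invalid calls in zone ", z, ": ",
                          paste(bad, collapse = ", "))
  }
  structure(list(calls = calls), class = "expression_call_set")
}

#' Look up a call
#' @param callset an `expression_call_set`.
#' @param zone zone tag.
#' @param gene gene id.
#' @return `"on"` or `"off"` (unlisted genes are on).
#' @export
get_call <- function(callset, zone, gene) {
  z <- callset$calls[[zone]]
  if (is.null(z) || !(gene %in% names(z))) "on" else unname(z[[gene]])
}

off_genes <- function(callset, zone) {
  z <- callset$calls[[zone]]
  if (is.null(z)) character() else names(z)[z == "off"]
}

#' Write / read expression calls as TSV (zone, gene, call)
#' @param callset an `expression_call_set`.
#' @param path TSV file path.
#' @return `path` (write) or an `expression_call_set` (read).
#' @export
write_calls <- function(callset, path) {
  rows <- do.call(rbind, lapply(names(callset$calls), function(z) {
    v <- callset$calls[[z]]
    if (!length(v)) return(data.frame(zone = z, gene = NA_character_,
                                      call = NA_character_)[0, ])
    data.frame(zone = z, gene = names(v), call = unname(v),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  expression_call_set(lapply(split(df, df$zone), function(d)
    stats::setNames(d$call, d$gene)))
}
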