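## SBML input/output built directly on xml2.
##
## Writing emits SBML Level 3 Version 1 with the fbc (version 2) extension:
## flux bounds as global parameters referenced via fbc:lowerFluxBound /
## fbc:upperFluxBound, GPRs as fbc:geneProductAssociation trees, the
## objective as an fbc:listOfObjectives, formulas/charges as fbc attributes.
## Ids are prefixed M_/R_/G_ on disk (COBRA convention) and stripped on
## reading. Reading also accepts Level 2 files with LOWER_BOUND /
## UPPER_BOUND kineticLaw parameters and "GENE_ASSOCIATION:" notes.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape_id <- function(x) x  # ids in this package are already SId-safe

num_attr <- function(node, attr, default = NA_real_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else as.numeric(v)
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_escape_id(model$id),
                             "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
      id = paste0("M_", mt$id), name = mt$name, compartment = mt$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(mt$charge))
      xml2::xml_set_attr(sp, "fbc:charge", format(mt$charge))
    if (!is.na(mt$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
  }

  # one shared parameter per distinct bound value
  bvals <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) {
    if (!is.finite(v)) return(if (v > 0) "bnd_plus_inf" else "bnd_minus_inf")
    paste0("bnd_", gsub("[^0-9A-Za-z]", "_", sprintf("%.17g", v)))
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bvals)
    xml2::xml_add_child(lp, "parameter", id = bid(v),
                        value = sprintf("%.17g", v), constant = "true")

  lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)

  add_gpa <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", tree))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) add_gpa(node, a)
    }
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    st <- model$stoichiometry[[rx$id]]
    rn <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", rx$id), name = rx$name, fast = "false",
      reversible = if (rx$lower_bound < 0) "true" else "false",
      "fbc:lowerFluxBound" = bid(rx$lower_bound),
      "fbc:upperFluxBound" = bid(rx$upper_bound))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lor <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(lor, "speciesReference",
                            species = paste0("M_", names(reac)[k]),
                            stoichiometry = sprintf("%.17g", -reac[[k]]),
                            constant = "true")
    }
    if (length(prod)) {
      lop <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(lop, "speciesReference",
                            species = paste0("M_", names(prod)[k]),
                            stoichiometry = sprintf("%.17g", prod[[k]]),
                            constant = "true")
    }
    if (nzchar(rx$gene_rule)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_gpa(gpa, parse_gene_rule(rx$gene_rule))
    }
    if (nzchar(rx$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rx$subsystem))
    }
  }

  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (k in seq_along(model$objective))
      xml2::xml_add_child(lf, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", names(model$objective)[k]),
                          "fbc:coefficient" = sprintf("%.17g", model$objective[[k]]))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]], fbc = FBC_NS)
  level <- xml2::xml_attr(doc, "level")
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "", xml2::xml_attr(sp, "name")),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.numeric(xml2::xml_attr(sp, "charge"))),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$charge[is.na(mets$charge)] <- 0

  # global parameters (L3 bounds)
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  parse_gpa_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(strip_prefix(xml2::xml_attr(node, "geneProduct"), "G_"))
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_gpa_node)
    if (length(args) == 1L) return(args[[1]])
    list(op = nm, args = args)
  }

  rxnodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rxnodes)
  ids <- strip_prefix(xml2::xml_attr(rxnodes, "id"), "R_")
  stoich <- vector("list", n)
  lbv <- numeric(n); ubv <- numeric(n)
  gpr <- character(n); subsys <- character(n)
  for (j in seq_len(n)) {
    node <- rxnodes[[j]]
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    sids <- c(strip_prefix(xml2::xml_attr(reac, "species"), "M_"),
              strip_prefix(xml2::xml_attr(prod, "species"), "M_"))
    coefs <- c(-vapply(reac, num_attr, 1, attr = "stoichiometry", default = 1),
               vapply(prod, num_attr, 1, attr = "stoichiometry", default = 1))
    if (!length(sids))
      stop("reaction ", ids[j], " has empty stoichiometry in ", path)
    st <- tapply(coefs, sids, sum)[unique(sids)]
    stoich[[j]] <- stats::setNames(as.numeric(st), names(st))

    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(parval)) {
      lbv[j] <- parval[[lbp]]; ubv[j] <- parval[[ubp]]
    } else {
      # SBML L2: kineticLaw parameters
      kl <- xml2::xml_find_all(node, ".//s:kineticLaw//s:parameter", ns)
      kid <- xml2::xml_attr(kl, "id")
      kva <- as.numeric(xml2::xml_attr(kl, "value"))
      lbv[j] <- if ("LOWER_BOUND" %in% kid) kva[match("LOWER_BOUND", kid)] else
        if (identical(xml2::xml_attr(node, "reversible"), "false")) 0 else -1000
      ubv[j] <- if ("UPPER_BOUND" %in% kid) kva[match("UPPER_BOUND", kid)] else 1000
    }

    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      gpr[j] <- if (length(kids)) deparse_gene_rule(parse_gpa_node(kids[[1]])) else ""
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(node, "./s:notes", ns))
      if (!is.na(notes) && grepl("GENE_ASSOCIATION:", notes)) {
        ga <- sub(".*GENE_ASSOCIATION:\\s*", "", notes)
        gpr[j] <- trimws(strsplit(ga, "\n")[[1]][1])
      } else gpr[j] <- ""
    }
    notes <- xml2::xml_text(xml2::xml_find_first(node, "./s:notes", ns))
    subsys[j] <- if (!is.na(notes) && grepl("SUBSYSTEM:", notes))
      trimws(strsplit(sub(".*SUBSYSTEM:\\s*", "", notes), "\n")[[1]][1]) else ""
  }

  lbv[lbv <= -1e30] <- -Inf; ubv[ubv >= 1e30] <- Inf
  rx <- data.frame(id = ids,
                   name = ifelse(is.na(xml2::xml_attr(rxnodes, "name")), "",
                                 xml2::xml_attr(rxnodes, "name")),
                   lower_bound = lbv, upper_bound = ubv,
                   gene_rule = gpr, subsystem = subsys,
                   stringsAsFactors = FALSE)
  names(stoich) <- ids

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- strip_prefix(xml2::xml_attr(gp, "id"), "G_")
  genes <- unique(c(genes, unlist(lapply(gpr, gene_rule_genes))))

  fo <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- stats::setNames(
    as.numeric(xml2::xml_attr(fo, "coefficient")),
    strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))

  dangling <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(dangling))
    stop("SBML reactions reference undeclared species: ",
         paste(dangling, collapse = ", "))

  metabolic_model(model_id, mets, rx, stoich, genes, objective)
}

#' Read a constraint-based model
#'
#' @param path SBML file (`dialect = "sbml"`) or directory containing
#'   `metabolites.tsv` / `reactions.tsv` (`dialect = "tabular"`).
#' @param dialect `"sbml"` or `"tabular"`; default guesses from `path`.
#' @return a `metabolic_model`. Round-trips through [write_model()] preserve
#'   all typed fields.
#' @export
read_model <- function(path, dialect = c("guess", "sbml", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "guess")
    dialect <- if (dir.exists(path)) "tabular" else "sbml"
  if (!file.exists(path) && !dir.exists(path)) stop("no such path: ", path)
  switch(dialect,
         sbml = read_model_sbml(path),
         tabular = read_model_tabular(path))
}

#' Write a constraint-based model
#'
#' @param model a `metabolic_model`.
#' @param path target file (sbml) or directory (tabular).
#' @param dialect `"sbml"` or `"tabular"`.
#' @return `path`, invisibly. Writing is deterministic: the same model
#'   produces byte-identical output.
#' @export
write_model <- function(model, path, dialect = c("sbml", "tabular")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  switch(dialect,
         sbml = write_model_sbml(model, path),
         tabular = write_model_tabular(model, path))
}
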