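## Tabular model dialect: a directory with three TSV files.
##   metabolites.tsv  id name formula charge compartment
##   reactions.tsv    id name equation lower_bound upper_bound gene_rule
##                    subsystem objective
##   model.tsv        key value   (currently only: id)
## Equation strings look like "1 glc_c + 1 atp_c --> 1 g6p_c + 1 adp_c";
## "<=>" marks a nominally reversible arrow (bounds are authoritative).

format_equation <- function(stoich) {
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  fmt <- function(s, sign) {
    if (!length(s)) return("")
    paste(sprintf("%.17g %s", sign * as.numeric(s), names(s)), collapse = " + ")
  }
  paste(fmt(lhs, -1), "-->", fmt(rhs, 1))
}

parse_equation <- function(eq, reaction_id = "?") {
  eq <- trimws(eq)
  parts <- strsplit(eq, "\\s*(-->|<=>|<->|=>)\\s*")[[1]]
  if (length(parts) > 2L)
    stop("cannot parse equation of ", reaction_id, ": ", eq)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(), character()))
    terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
    out <- numeric(); nm <- character()
    for (tm in terms) {
      tk <- strsplit(trimws(tm), "\\s+")[[1]]
      if (length(tk) == 1L) { coef <- 1; met <- tk }
      else if (length(tk) == 2L) {
        coef <- suppressWarnings(as.numeric(tk[1]))
        if (is.na(coef)) stop("bad coefficient '", tk[1], "' in ", reaction_id)
        met <- tk[2]
      } else stop("bad term '", tm, "' in equation of ", reaction_id)
      out <- c(out, sign * coef); nm <- c(nm, met)
    }
    stats::setNames(out, nm)
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- if (length(parts) == 2L) parse_side(parts[2], +1)
         else stats::setNames(numeric(), character())
  st <- c(lhs, rhs)
  # merge duplicated metabolites (appearing on both sides)
  out <- tapply(as.numeric(st), names(st), sum)[unique(names(st))]
  stats::setNames(as.numeric(out), names(out))
}

write_model_tabular <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mets <- model$metabolites
  ## an empty formula means "massless" and must survive the round trip;
  ## an unknown formula is written as the literal NA token
  utils::write.table(mets, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  rx <- model$reactions
  obj <- stats::setNames(rep(0, nrow(rx)), rx$id)
  if (length(model$objective)) obj[names(model$objective)] <- model$objective
  rx$equation <- vapply(model$stoichiometry[rx$id], format_equation, character(1))
  rx$objective <- as.numeric(obj)
  rx <- rx[, c("id", "name", "equation", "lower_bound", "upper_bound",
               "gene_rule", "subsystem", "objective")]
  utils::write.table(rx, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(data.frame(key = "id", value = model$id),
                     file.path(path, "model.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_model_tabular <- function(path) {
  need <- file.path(path, c("metabolites.tsv", "reactions.tsv"))
  if (!all(file.exists(need)))
    stop("tabular model directory must contain metabolites.tsv and reactions.tsv: ",
         path)
  mets <- utils::read.delim(need[1], stringsAsFactors = FALSE,
                            colClasses = c(id = "character", name = "character",
                                           formula = "character",
                                           compartment = "character"))
  mets$formula[is.na(mets$formula)] <- NA_character_
  rx <- utils::read.delim(need[2], stringsAsFactors = FALSE,
                          colClasses = c(id = "character", name = "character",
                                         equation = "character",
                                         gene_rule = "character",
                                         subsystem = "character"))
  rx$gene_rule[is.na(rx$gene_rule)] <- ""
  rx$subsystem[is.na(rx$subsystem)] <- ""
  id <- basename(path)
  mf <- file.path(path, "model.tsv")
  if (file.exists(mf)) {
    kv <- utils::read.delim(mf, stringsAsFactors = FALSE)
    if ("id" %in% kv$key) id <- kv$value[kv$key == "id"]
  }
  stoich <- stats::setNames(
    lapply(seq_len(nrow(rx)),
           function(j) parse_equation(rx$equation[j], rx$id[j])),
    rx$id)
  dangling <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(dangling))
    stop("reactions.tsv references metabolites absent from metabolites.tsv: ",
         paste(dangling, collapse = ", "))
  objective <- stats::setNames(rx$objective, rx$id)
  objective <- objective[objective != 0]
  genes <- unique(unlist(lapply(rx$gene_rule, gene_rule_genes)))
  metabolic_model(id,
                  mets[, c("id", "name", "formula", "charge", "compartment")],
                  rx[, c("id", "name", "lower_bound", "upper_bound",
                         "gene_rule", "subsystem")],
                  stoich, genes, objective)
}
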