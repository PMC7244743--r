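#' Parse a Hill-notation elemental formula
#'
#' @param formula character scalar such as `"C6H12O6"`. An empty string is a
#'   valid massless formula (photon, electron, proton-motive quantum) and
#'   parses to zero elements; `NA` means the composition is unknown.
#' @return named numeric vector of element counts, or `NULL` when the
#'   formula is `NA` or unparseable.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) != 1L || is.na(formula)) return(NULL)
  formula <- trimws(formula)
  if (!nzchar(formula)) return(stats::setNames(numeric(), character()))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) return(NULL)
  els <- sub("[0-9.]*$", "", parts)
  cnt <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  cnt[is.na(cnt)] <- 1
  out <- tapply(cnt, els, sum)[unique(els)]
  stats::setNames(as.numeric(out), names(out))
}

#' Mass and charge balance of a reaction
#'
#' Computes the element-wise net imbalance `sum(coefficient x element count)`
#' and the net charge imbalance of one reaction. Reactions involving a
#' metabolite without a known formula are reported as undetermined rather
#' than raising an error.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to check.
#' @param tol imbalances below this magnitude count as zero (default 1e-6).
#' @return object of class `balance_report`: list with `reaction_id`,
#'   `element_imbalance` (named numeric), `charge_imbalance`, `balanced`
#'   (logical, `NA` when undetermined) and `undetermined`.
#' @export
check_balance <- function(model, reaction_id, tol = 1e-6) {
  st <- model$stoichiometry[[reaction_id]]
  if (is.null(st)) stop("unknown reaction: ", reaction_id)
  idx <- match(names(st), model$metabolites$id)
  imb <- numeric()
  charge <- 0
  undet <- FALSE
  for (k in seq_along(st)) {
    f <- parse_formula(model$metabolites$formula[idx[k]])
    if (is.null(f)) { undet <- TRUE; break }
    for (el in names(f)) imb[el] <- (if (el %in% names(imb)) imb[el] else 0) + st[k] * f[[el]]
    ch <- model$metabolites$charge[idx[k]]
    if (is.na(ch)) { undet <- TRUE; break }
    charge <- charge + st[k] * ch
  }
  if (undet) {
    rep <- list(reaction_id = reaction_id, element_imbalance = NULL,
                charge_imbalance = NA_real_, balanced = NA, undetermined = TRUE)
  } else {
    imb <- imb[abs(imb) > tol]
    balanced <- length(imb) == 0L && abs(charge) <= tol
    rep <- list(reaction_id = reaction_id, element_imbalance = imb,
                charge_imbalance = if (abs(charge) > tol) charge else 0,
                balanced = balanced, undetermined = FALSE)
  }
  class(rep) <- "balance_report"
  rep
}

#' @export
print.balance_report <- function(x, ...) {
  if (isTRUE(x$undetermined)) {
    cat(x$reaction_id, ": undetermined (unknown formula or charge)\n")
  } else if (isTRUE(x$balanced)) {
    cat(x$reaction_id, ": balanced\n")
  } else {
    cat(x$reaction_id, ": UNBALANCED ")
    if (length(x$element_imbalance))
      cat(paste(sprintf("%s%+g", names(x$element_imbalance), x$element_imbalance),
                collapse = " "), "")
    if (x$charge_imbalance != 0) cat(sprintf("charge%+g", x$charge_imbalance))
    cat("\n")
  }
  invisible(x)
}

#' Balance report for every reaction of a model
#'
#' @param model a `metabolic_model`.
#' @param tol numeric tolerance passed to [check_balance()].
#' @return data.frame with one row per reaction: `reaction_id`, `balanced`
#'   (logical, `NA` for undetermined), `imbalance` (compact text summary).
#' @export
check_balance_all <- function(model, tol = 1e-6) {
  reps <- lapply(model$reactions$id, check_balance, model = model, tol = tol)
  data.frame(
    reaction_id = model$reactions$id,
    balanced = vapply(reps, function(r) r$balanced, NA),
    imbalance = vapply(reps, function(r) {
      if (isTRUE(r$undetermined)) return("undetermined")
      if (isTRUE(r$balanced)) return("")
      paste(c(sprintf("%s%+g", names(r$element_imbalance), r$element_imbalance),
              if (r$charge_imbalance != 0) sprintf("charge%+g", r$charge_imbalance)),
            collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE)
}
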