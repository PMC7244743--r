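chain_model <- function(with_exchange = FALSE) {
  mets <- data.frame(id = c("A", "B", "C", "S"), name = c("A", "B", "C", "S"),
                     formula = "C", charge = 0, compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_S", "R1", "R2", "R3"),
                     name = c("supply", "r1", "r2", "r3"),
                     lower_bound = c(-10, 0, 0, 0), upper_bound = 10,
                     gene_rule = "", subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(EX_S = c(S = -1), R1 = c(S = -1, A = 1),
                 R2 = c(A = -1, B = 1), R3 = c(B = -1, C = 1))
  m <- metabolic_model("chain", mets, rxns, stoich)
  if (with_exchange) m <- vnod:::add_reaction(m, "EX_C", c(C = -1), lb = -10, ub = 10)
  m
}

test_that("a dead-end chain cascades to the fixpoint; an exchange rescues it", {
  res <- remove_dead_ends(chain_model())
  # C is unconsumed -> R3 goes, then B dead -> R2, then A dead -> R1
  expect_setequal(res$removed, c("R1", "R2", "R3"))
  expect_false(any(c("A", "B", "C") %in% res$model$metabolites$id))
  # with an exchange for C nothing is removed
  res2 <- remove_dead_ends(chain_model(with_exchange = TRUE))
  expect_length(res2$removed, 0)
  expect_equal(nrow(res2$model$reactions), 5)
})

test_that("pruning is idempotent and protects the objective", {
  m <- chain_model(with_exchange = TRUE)
  # a closed drain on a live metabolite survives; a reaction (open or
  # closed) whose product nothing consumes does not
  m <- vnod:::add_reaction(m, "CLOSED_DRAIN", c(A = -1), lb = 0, ub = 0)
  m <- vnod:::add_metabolite(m, "lonely", compartment = "c")
  m <- vnod:::add_reaction(m, "MAKE_LONELY", c(A = -1, lonely = 1))
  m <- vnod:::add_metabolite(m, "lonely2", compartment = "c")
  m <- vnod:::add_reaction(m, "CLOSED_LONELY", c(A = -1, lonely2 = 1),
                           lb = 0, ub = 0)
  once <- remove_dead_ends(m)
  twice <- remove_dead_ends(once$model)
  expect_setequal(once$removed, c("MAKE_LONELY", "CLOSED_LONELY"))
  expect_true("CLOSED_DRAIN" %in% once$model$reactions$id)
  expect_length(twice$removed, 0)
  expect_identical(twice$model$reactions$id, once$model$reactions$id)

  # pruning that would remove an objective reaction raises a structured error
  bad <- chain_model()
  bad$objective <- c(R3 = 1)
  expect_error(remove_dead_ends(bad), "objective reaction")
})

test_that("random networks reach the same fixpoint as a one-at-a-time oracle", {
  # oracle: repeatedly remove a single arbitrary reaction that touches a
  # metabolite lacking a producer or a consumer, recomputing everything
  # from scratch each time (order-dependent path, order-independent fixpoint)
  oracle_prune <- function(model, order_seed) {
    set.seed(order_seed)
    repeat {
      rx <- model$reactions
      S <- stoich_matrix(model)
      can_prod <- can_cons <- matrix(FALSE, nrow(S), ncol(S),
                                     dimnames = dimnames(S))
      for (j in seq_len(ncol(S))) {
        fwd <- rx$upper_bound[j] > 0; rev <- rx$lower_bound[j] < 0
        can_prod[, j] <- (S[, j] > 0 & fwd) | (S[, j] < 0 & rev)
        can_cons[, j] <- (S[, j] < 0 & fwd) | (S[, j] > 0 & rev)
      }
      touched <- rowSums(S != 0) > 0
      dead <- touched & (rowSums(can_prod) == 0 | rowSums(can_cons) == 0)
      if (!any(dead)) return(sort(model$reactions$id))
      met <- sample(names(which(dead)), 1)
      hit <- model$reactions$id[S[met, ] != 0]
      model <- vnod:::drop_reactions(model, sample(hit, 1))
    }
  }
  set.seed(31)
  for (rep in 1:4) {
    n_m <- 14; n_r <- 50
    mets <- data.frame(id = paste0("m", 1:n_m), name = paste0("m", 1:n_m),
                       formula = "C", charge = 0, compartment = "c",
                       stringsAsFactors = FALSE)
    rxns <- data.frame(id = paste0("r", 1:n_r), name = paste0("r", 1:n_r),
                       lower_bound = ifelse(stats::runif(n_r) < 0.3, -10, 0),
                       upper_bound = 10, gene_rule = "", subsystem = "",
                       stringsAsFactors = FALSE)
    stoich <- lapply(1:n_r, function(j) {
      k <- sample(1:3, 1)
      stats::setNames(sample(c(-1, 1), k, replace = TRUE),
                      sample(mets$id, k))
    })
    names(stoich) <- rxns$id
    m <- metabolic_model("rand", mets, rxns, stoich)
    res <- remove_dead_ends(m)
    expect_identical(sort(res$model$reactions$id), oracle_prune(m, rep),
                     label = paste("network", rep))
  }
})
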