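# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no data files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

toy_plant_fx <- function() memo("plant", function() generate_toy_plant(toy_config()))
toy_bact_fx <- function() memo("bact", function() generate_toy_bacterium(toy_config()))
toy_calls_fx <- function() memo("calls", function()
  generate_zone_calls(toy_config(), toy_plant_fx(), toy_bact_fx()))

toy_holo_fx <- function() memo("holo", function()
  build_holobiont(toy_plant_fx(), toy_bact_fx(), holobiont_spec(), toy_calls_fx()))

toy_holo_sucrose_fx <- function() memo("holo_sucr", function() {
  cfg <- toy_config(include_sucrose_bacteroid_path = TRUE)
  plant <- generate_toy_plant(cfg)
  bact <- generate_toy_bacterium(cfg)
  calls <- generate_zone_calls(cfg, plant, bact)
  build_holobiont(plant, bact,
                  holobiont_spec(sucrose_bacteroid_variant = TRUE), calls)
})

growth_of <- function(sol) {
  if (sol$status == "optimal") sol$objective_value else 0
}

# independent vertex-enumeration LP oracle for small problems:
# max c'x s.t. Ax = b, lb <= x <= ub, by enumerating all bases and all
# lower/upper assignments of the nonbasic variables
oracle_lp <- function(A, b, c, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  best <- NULL
  combs <- utils::combn(n, m)
  for (k in seq_len(ncol(combs))) {
    Bset <- combs[, k]
    Nset <- setdiff(seq_len(n), Bset)
    Bm <- A[, Bset, drop = FALSE]
    if (abs(det(Bm)) < 1e-10) next
    grid <- expand.grid(rep(list(1:2), length(Nset)))
    if (!length(Nset)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xN <- numeric(length(Nset))
      ok <- TRUE
      for (ii in seq_along(Nset)) {
        v <- if (grid[g, ii] == 1) lb[Nset[ii]] else ub[Nset[ii]]
        if (!is.finite(v)) { ok <- FALSE; break }
        xN[ii] <- v
      }
      if (!ok) next
      rhs <- b - if (length(Nset)) A[, Nset, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(Bm, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[Bset] <- xB; x[Nset] <- xN
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        obj <- sum(c * x)
        if (is.null(best) || obj > best) best <- obj
      }
    }
  }
  best
}

# brute-force evaluation of a gene rule via R's own logical operators over
# a randomly generated expression tree (independent of the package parser)
random_rule_case <- function(genes, depth = 3) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      g <- sample(genes, 1)
      list(str = g, fn = function(act) act[[g]])
    } else {
      l <- build(d - 1); r <- build(d - 1)
      if (stats::runif(1) < 0.5)
        list(str = paste0("(", l$str, " and ", r$str, ")"),
             fn = function(act) l$fn(act) && r$fn(act))
      else
        list(str = paste0("(", l$str, " or ", r$str, ")"),
             fn = function(act) l$fn(act) || r$fn(act))
    }
  }
  build(depth)
}
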