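test_that("SBML round trip preserves every typed field", {
  for (model in list(toy_plant_fx(), toy_bact_fx())) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_model(model, path, "sbml")
    back <- read_model(path, "sbml")
    expect_identical(back$reactions$id, model$reactions$id)
    expect_equal(back$reactions$lower_bound, model$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, model$reactions$upper_bound)
    expect_identical(back$reactions$gene_rule, model$reactions$gene_rule)
    expect_identical(back$metabolites$formula, model$metabolites$formula)
    expect_equal(back$metabolites$charge, model$metabolites$charge)
    expect_identical(back$metabolites$compartment, model$metabolites$compartment)
    expect_equal(back$stoichiometry, model$stoichiometry)
    expect_equal(back$objective, model$objective)
    expect_setequal(back$genes, model$genes)
  }
})

test_that("tabular round trip preserves every typed field", {
  model <- toy_bact_fx()
  dir <- withr::local_tempdir()
  write_model(model, dir, "tabular")
  back <- read_model(dir, "tabular")
  expect_identical(back$reactions$id, model$reactions$id)
  expect_equal(back$reactions[, c("lower_bound", "upper_bound")],
               model$reactions[, c("lower_bound", "upper_bound")])
  expect_identical(back$reactions$gene_rule, model$reactions$gene_rule)
  expect_equal(back$metabolites, model$metabolites)
  expect_equal(back$stoichiometry, model$stoichiometry)
  expect_equal(back$objective, model$objective)
})

test_that("writes are deterministic and namespaced ids survive verbatim", {
  holo <- toy_holo_fx()
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_model(holo$model, f1, "sbml")
  write_model(holo$model, f2, "sbml")
  expect_identical(readLines(f1), readLines(f2))
  back <- read_model(f1)
  expect_setequal(back$reactions$id, holo$model$reactions$id)
  expect_setequal(back$metabolites$id, holo$model$metabolites$id)
  expect_true(all(startsWith(
    grep("^Shoot_", back$reactions$id, value = TRUE), "Shoot_")))
})

test_that("an empty model survives both dialects", {
  e <- vnod:::empty_model("nothing")
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(e, path, "sbml")
  back <- read_model(path)
  expect_equal(nrow(back$reactions), 0)
  expect_equal(nrow(back$metabolites), 0)
  dir <- withr::local_tempdir()
  write_model(e, dir, "tabular")
  expect_equal(nrow(read_model(dir)$reactions), 0)
})

test_that("a three-reaction tabular fixture with a nested GPR parses to the expected tree", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\tformula\tcharge\tcompartment",
               "a_c\ta\tC\t0\tc", "b_c\tb\tC\t0\tc", "x_e\tx\tC\t0\te"),
             file.path(dir, "metabolites.tsv"))
  writeLines(c(paste("id", "name", "equation", "lower_bound", "upper_bound",
                     "gene_rule", "subsystem", "objective", sep = "\t"),
               "R1\tr1\t1 x_e --> 1 a_c\t-10\t10\t(g1 and g2) or g3\t\t0",
               "R2\tr2\t1 a_c --> 1 b_c\t0\t10\tg3\t\t1",
               "EX\tex\t1 x_e --> \t-10\t10\t\t\t0"),
             file.path(dir, "reactions.tsv"))
  m <- read_model(dir, "tabular")
  expect_equal(nrow(m$reactions), 3)
  tree <- parse_gene_rule(m$reactions$gene_rule[1])
  expect_equal(tree$op, "or")
  expect_length(tree$args, 2)
  expect_setequal(gene_rule_genes(m$reactions$gene_rule[1]), c("g1", "g2", "g3"))
  expect_setequal(m$genes, c("g1", "g2", "g3"))
  expect_equal(m$objective, c(R2 = 1))
})

test_that("dangling metabolite references are reported by id", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\tformula\tcharge\tcompartment", "a_c\ta\tC\t0\tc"),
             file.path(dir, "metabolites.tsv"))
  writeLines(c(paste("id", "name", "equation", "lower_bound", "upper_bound",
                     "gene_rule", "subsystem", "objective", sep = "\t"),
               "R1\tr1\t1 a_c --> 1 ghost_c\t0\t10\t\t\t0"),
             file.path(dir, "reactions.tsv"))
  expect_error(read_model(dir, "tabular"), "ghost_c")
  expect_error(read_model(file.path(dir, "no_such_file.xml")), "no such path")
})
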