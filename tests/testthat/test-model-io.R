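test_that("toy JSON fixtures round-trip to identical models", {
  for (nm in c("serial", "parallel", "shared", "twocarbon")) {
    path <- system.file("extdata", paste0("fixture_", nm, ".json"),
                        package = "epifba")
    m <- read_toy_model(path)
    expect_identical(m, fx(nm)$model, label = nm)
    # reload determinism
    expect_identical(read_toy_model(path), m)
    # exchange detection is structural and stable across reloads
    expect_identical(exchange_reactions(read_toy_model(path)),
                     exchange_reactions(m))
  }
  tmp <- withr::local_tempfile(fileext = ".json")
  write_toy_model(fx("twocarbon")$model, tmp)
  expect_identical(read_toy_model(tmp), fx("twocarbon")$model)
})

test_that("SBML writer/reader round-trips and matches the JSON twin", {
  for (nm in c("serial", "twocarbon")) {
    tmp <- withr::local_tempfile(fileext = ".xml")
    write_sbml_model(fx(nm)$model, tmp)
    m <- read_sbml_model(tmp)
    expect_identical(m, fx(nm)$model, label = nm)
  }
  sbml <- system.file("extdata", "fixture_serial.sbml.xml", package = "epifba")
  json <- system.file("extdata", "fixture_serial.json", package = "epifba")
  expect_identical(read_sbml_model(sbml), read_toy_model(json))
})

test_that("Level 2 SBML with notes-based gene associations is read", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="toy"><listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c"/>',
    '<species id="Aext" compartment="e" boundaryCondition="true"/>',
    "</listOfSpecies><listOfReactions>",
    '<reaction id="EX_A" reversible="true">',
    "<listOfReactants><speciesReference species=\"Aext\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"A\"/></listOfProducts>",
    "<kineticLaw><listOfParameters>",
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="10"/>',
    "</listOfParameters></kineticLaw></reaction>",
    '<reaction id="R1" reversible="false">',
    "<notes><body><p>GENE_ASSOCIATION: (g1 and g2) or g3</p></body></notes>",
    "<listOfReactants><speciesReference species=\"A\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"B\"/></listOfProducts>",
    "<kineticLaw><listOfParameters>",
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="1000"/>',
    "</listOfParameters></kineticLaw></reaction>",
    '<reaction id="BM" reversible="false">',
    "<listOfReactants><speciesReference species=\"B\"/></listOfReactants>",
    "<kineticLaw><listOfParameters>",
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="1000"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    "</listOfParameters></kineticLaw></reaction>",
    "</listOfReactions></model></sbml>"
  )
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, tmp)
  m <- read_sbml_model(tmp)
  expect_equal(m$objective, "BM")
  expect_equal(sort(model_genes(m)), c("g1", "g2", "g3"))
  expect_equal(m$gene_to_reactions$g1, "R1")
  expect_equal(unname(m$ub["EX_A"]), 10)
  # boundary species dropped: EX_A has a single nonzero entry
  expect_true("EX_A" %in% exchange_reactions(m))
})

test_that("invalid models are rejected at load", {
  good <- fx("serial")$model
  # gene mapped to no reaction
  expect_error(
    metabolic_model(good$metabolites, good$reactions, good$S, good$lb,
                    good$ub, good$objective,
                    c(good$gene_to_reactions, list(orphan = character(0)))),
    "mapped to no reaction"
  )
  # lb > ub in a toy file
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list("A"),
    reactions = list(list(id = "R", stoich = list(A = -1), lb = 1, ub = 0,
                          genes = list())),
    objective = "R"
  ), tmp, auto_unbox = TRUE)
  expect_error(read_toy_model(tmp), "lower bound exceeds upper bound")
  # empty reaction list
  jsonlite::write_json(list(metabolites = list("A"), reactions = list(),
                            objective = "R"), tmp, auto_unbox = TRUE)
  expect_error(read_toy_model(tmp), "no objective reachable")
  # duplicate reaction id
  jsonlite::write_json(list(
    metabolites = list("A"),
    reactions = list(
      list(id = "R", stoich = list(A = -1), lb = 0, ub = 1, genes = list()),
      list(id = "R", stoich = list(A = 1), lb = 0, ub = 1, genes = list())
    ),
    objective = "R"
  ), tmp, auto_unbox = TRUE)
  expect_error(read_toy_model(tmp), "duplicate reaction id")
  # unknown metabolite
  jsonlite::write_json(list(
    metabolites = list("A"),
    reactions = list(list(id = "R", stoich = list(Z = -1), lb = 0, ub = 1,
                          genes = list())),
    objective = "R"
  ), tmp, auto_unbox = TRUE)
  expect_error(read_toy_model(tmp), "unknown metabolite")
  # SBML without an objective
  sbml_no_obj <- withr::local_tempfile(fileext = ".xml")
  txt <- readLines(system.file("extdata", "fixture_serial.sbml.xml",
                               package = "epifba"))
  txt <- txt[!grepl("Objective", txt)]
  writeLines(txt, sbml_no_obj)
  expect_error(read_sbml_model(sbml_no_obj), "no objective defined")
})

test_that("gene_pairs enumerates C(n,2) canonical pairs", {
  gp <- gene_pairs(c("b", "a", "c"))
  expect_equal(gp$gene_a, c("a", "a", "b"))
  expect_equal(gp$gene_b, c("b", "c", "c"))
  expect_equal(nrow(gene_pairs(c("x", "y"))), 1L)
  # the genome-scale pair universe: 904 genes
  big <- gene_pairs(sprintf("Y%04d", 1:904))
  expect_equal(nrow(big), 408156L)
  # brute-force double-loop count check at several n
  for (n in c(2, 5, 17)) {
    genes <- sprintf("g%02d", seq_len(n))
    cnt <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) cnt <- cnt + 1L
    expect_equal(nrow(gene_pairs(genes)), cnt)
  }
  expect_error(gene_pairs("only_one"), "at least 2 genes")
  # model input
  expect_equal(nrow(gene_pairs(fx("twocarbon")$model)), 6L)
})

test_that("gene-reaction map views are mutually consistent inverses", {
  m <- fx("twocarbon")$model
  gm <- gene_reaction_map(m)
  for (g in names(gm$gene_to_reactions)) {
    for (r in gm$gene_to_reactions[[g]]) {
      expect_true(g %in% gm$reaction_to_genes[[r]])
    }
  }
  for (r in names(gm$reaction_to_genes)) {
    for (g in gm$reaction_to_genes[[r]]) {
      expect_true(r %in% gm$gene_to_reactions[[g]])
    }
  }
})

test_that("model_summary reports bounds, genes and exchange flags", {
  sm <- model_summary(fx("serial")$model)
  expect_equal(nrow(sm), 4L)
  expect_equal(sm$genes[sm$reaction == "R1"], "g1")
  expect_true(sm$exchange[sm$reaction == "EX_A"])
  expect_false(any(sm$exchange[sm$reaction != "EX_A"]))
})
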