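test_that("equation parsing transcribes stoichiometry and reversibility", {
  m <- model_from_equations(c(R1 = "A[c] => B[c]"))
  expect_equal(nrow(m$metabolites), 2L)
  expect_length(m$reactions, 1L)
  expect_equal(as.vector(m$S), c(-1, 1))

  m2 <- model_from_equations(c(R1 = "2 A[c] <=> B[c] + C[c]"))
  st <- m2$reactions[[1]]$stoichiometry
  expect_equal(st[["A[c]"]], -2)
  expect_equal(st[["B[c]"]], 1)
  expect_equal(st[["C[c]"]], 1)
  expect_true(m2$reactions[[1]]$reversible)
})

test_that("malformed equations and duplicate ids are rejected by name", {
  expect_error(model_from_equations(c(RX = "A[c] B[c]")), "RX")
  expect_error(model_from_equations(c(RY = "A => B[c]")), "compartment")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tgpr\tsubsystem",
               "R1\tA[c] => B[c]\t\t",
               "R1\tB[c] => C[c]\t\t"), tmp)
  expect_error(read_model(tmp), "duplicate")
})

test_that("boundary metabolites are excluded from S rows", {
  m <- chain3_model()
  expect_equal(rownames(m$S), c("A[c]", "B[c]"))
  expect_equal(sum(m$metabolites$boundary), 2L)
  expect_true(all(Matrix::colSums(abs(m$S)) >= 0))
})

test_that("gpr parser handles case, parentheses and nesting", {
  tree <- parse_gpr("(g1 AND g2) OR g3")
  expect_setequal(gpr_leaves(tree), c("g1", "g2", "g3"))
  expect_true(gpr_eval(tree, "g3"))
  expect_true(gpr_eval(tree, c("g1", "g2")))
  expect_false(gpr_eval(tree, "g1"))
  expect_true(gpr_equivalent(tree, parse_gpr("g3 or (g2 and g1)")))
  expect_false(gpr_equivalent(tree, parse_gpr("g1 and g2 and g3")))
  expect_null(parse_gpr(""))
  expect_error(parse_gpr("g1 and (g2 or"), "rule")
})

test_that("tabular round-trip preserves stoichiometry, reversibility, gpr", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tgpr\tsubsystem",
               "R1\t2 A[c] <=> B[c] + C[m]\t(g1 and g2) or g3\tpath1",
               "R2\tB[c] => x[b]\tg4\t",
               "R3\tC[m] => x[b]\t\t"), tmp)
  m1 <- read_model(tmp)
  tmp2 <- tempfile(fileext = ".tsv")
  write_model(m1, tmp2)
  m2 <- read_model(tmp2)
  expect_equal(reaction_ids(m2), reaction_ids(m1))
  for (k in seq_along(m1$reactions)) {
    r1 <- m1$reactions[[k]]; r2 <- m2$reactions[[k]]
    expect_equal(sort(names(r1$stoichiometry)), sort(names(r2$stoichiometry)))
    expect_equal(r2$stoichiometry[names(r1$stoichiometry)], r1$stoichiometry)
    expect_equal(r2$reversible, r1$reversible)
    expect_true(gpr_equivalent(r1$gpr, r2$gpr))
  }
})

test_that("SBML level 3 models read with fbc gene associations", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1">',
    '<model id="toy">',
    '<listOfCompartments><compartment id="c" constant="true"/>',
    '<compartment id="b" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c" boundaryCondition="false"/>',
    '<species id="B" compartment="c" boundaryCondition="false"/>',
    '<species id="X" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R2" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="g1"/>',
    '<fbc:and><fbc:geneProductRef fbc:geneProduct="g2"/>',
    '<fbc:geneProductRef fbc:geneProduct="g3"/></fbc:and>',
    '</fbc:or></fbc:geneProductAssociation>',
    '</reaction>',
    '</listOfReactions></model></sbml>')
  tmp <- tempfile(fileext = ".xml")
  writeLines(sbml, tmp)
  m <- read_model(tmp)
  expect_equal(reaction_ids(m), c("R1", "R2"))
  expect_equal(rownames(m$S), c("A[c]", "B[c]"))
  expect_equal(m$S["A[c]", "R2"], -2)
  expect_true(m$reactions[[2]]$reversible)
  expect_true(gpr_equivalent(m$reactions[[2]]$gpr,
                             parse_gpr("g1 or (g2 and g3)")))
  expect_setequal(m$genes, c("g1", "g2", "g3"))
})

test_that("gene-to-reaction mapping matches gpr leaf membership", {
  eqs <- c(R1 = "A[c] => B[c]", R2 = "B[c] => C[c]", R3 = "C[c] => D[c]")
  m <- model_from_equations(eqs, gprs = c("(g1 and g2) or g3", "g4", ""))
  hits <- map_genes_to_reactions(m, c("g3"), quiet = TRUE)
  expect_equal(hits$R1, "g3")
  expect_equal(hits$R2, character(0))
  expect_equal(hits$R3, character(0))

  none <- map_genes_to_reactions(m, c("zz1", "zz2"), quiet = TRUE)
  expect_true(all(lengths(none) == 0L))
  expect_message(map_genes_to_reactions(m, c("g4", "zz")), "1 of 2")
})

test_that("every reaction column of S or its boundary terms is non-empty", {
  m <- make_toy_model(2, 4, n_diamonds = 1, n_parallel = 1)
  sizes <- vapply(m$reactions, function(r) length(r$stoichiometry), integer(1))
  expect_true(all(sizes > 0))
  summ <- model_summary(m)
  expect_equal(summ$n_reactions, length(m$reactions))
  expect_equal(summ$n_genes, length(m$genes))
})
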