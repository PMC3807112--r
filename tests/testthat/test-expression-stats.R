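make_phen <- function(n, seed = 1) {
  set.seed(seed)
  phenotype_vector(sprintf("s%02d", 1:n), exp(runif(n, log(0.01), log(0.04))))
}

test_that("growth rate from doubling time follows mu = ln(2)/t_d", {
  expect_equal(growth_rate_from_doubling(log(2)), 1.0)
  expect_equal(growth_rate_from_doubling(24), log(2) / 24)
  expect_equal(growth_rate_from_doubling(24), 0.02888, tolerance = 1e-3)
  expect_error(growth_rate_from_doubling(0), "positive")
  expect_error(growth_rate_from_doubling(-3), "positive")
})

test_that("spearman scores hit the rank-correlation extremes", {
  phen <- make_phen(20)
  expr <- rbind(
    up = rank(phen$value) * 2 + 5,          # strictly increasing with phenotype
    down = -rank(phen$value),               # rank negation
    flat = rep(1, 20)                       # zero variance
  )
  colnames(expr) <- phen$sample_id
  sc <- spearman_scores(expr, phen)
  expect_equal(sc$statistic[sc$gene == "up"], 1)
  expect_equal(sc$statistic[sc$gene == "down"], -1)
  expect_false(sc$defined[sc$gene == "flat"])
  expect_true(is.na(sc$p_value[sc$gene == "flat"]))
})

test_that("spearman scores agree with cor.test and are monotone-invariant", {
  set.seed(3)
  phen <- make_phen(30, seed = 3)
  expr <- matrix(rnorm(5 * 30), nrow = 5,
                 dimnames = list(paste0("g", 1:5), phen$sample_id))
  sc <- spearman_scores(expr, phen)
  for (k in 1:5) {
    ref <- suppressWarnings(
      cor.test(expr[k, ], phen$value, method = "spearman"))
    expect_equal(sc$statistic[k], unname(ref$estimate), tolerance = 1e-12)
  }
  # strictly monotone transforms of data or phenotype leave rho unchanged
  sc2 <- spearman_scores(exp(expr / 2), make_phen(30, seed = 3))
  expect_equal(sc2$statistic, sc$statistic, tolerance = 1e-12)
  phen_t <- phen
  phen_t$value <- phen$value^3
  sc3 <- spearman_scores(expr, phen_t)
  expect_equal(sc3$statistic, sc$statistic, tolerance = 1e-12)
})

test_that("welch t scores behave at the degenerate corners", {
  groups <- phenotype_vector(sprintf("s%02d", 1:10),
                             rep(c("survivor", "deceased"), each = 5))
  base <- matrix(0, nrow = 3, ncol = 10,
                 dimnames = list(c("null", "planted", "halfconst"),
                                 groups$sample_id))
  set.seed(9)
  base["null", ] <- rep(c(1, 2, 3, 4, 5), 2)        # identical group samples
  base["planted", ] <- c(rnorm(5, 0), rnorm(5, 6))
  base["halfconst", ] <- c(rep(1, 5), rnorm(5, 2))  # one group constant
  sc <- ttest_scores(base, groups)
  expect_equal(sc$statistic[sc$gene == "null"], 0)
  expect_equal(sc$p_value[sc$gene == "null"], 1)
  expect_true(is.finite(sc$statistic[sc$gene == "halfconst"]))
  # sign convention: positive t = higher in second level; factor order is
  # alphabetical so "survivor" is level 2 here
  expect_lt(sc$p_value[sc$gene == "planted"], 0.01)
  # cross-check against t.test
  ref <- t.test(base["planted", 1:5], base["planted", 6:10])
  expect_equal(abs(sc$statistic[sc$gene == "planted"]),
               abs(unname(ref$statistic)), tolerance = 1e-10)
  expect_error(ttest_scores(base, phenotype_vector(groups$sample_id,
                                                   c("a", rep("b", 9)))),
               "2 samples")
})

test_that("a planted two-group effect scores below the background p median", {
  set.seed(21)
  n <- 40
  groups <- phenotype_vector(sprintf("s%02d", 1:n),
                             rep(c("survivor", "deceased"), each = n / 2))
  expr <- matrix(rnorm(100 * n), nrow = 100,
                 dimnames = list(sprintf("g%03d", 1:100), groups$sample_id))
  expr["g001", groups$value == "deceased"] <-
    expr["g001", groups$value == "deceased"] + 3
  sc <- ttest_scores(expr, groups)
  expect_lt(sc$p_value[sc$gene == "g001"],
            median(sc$p_value[sc$gene != "g001"]))
})

test_that("BH selection reproduces the hand-computed example and monotonicity", {
  # thresholds i*q/m = 0.0125, 0.025, 0.0375, 0.05 select the two smallest
  sc <- structure(
    data.frame(gene = paste0("g", 1:4),
               statistic = c(2, 2, 2, 2),
               p_value = c(0.001, 0.02, 0.04, 0.9),
               defined = TRUE, platform = NA_character_),
    mode = "spearman", class = c("gene_scores", "data.frame"))
  expect_setequal(fdr_select(sc, 0.05, "two_sided"), c("g1", "g2"))

  sc$p_value <- rep(1, 4)
  expect_length(fdr_select(sc, 0.05, "two_sided"), 0L)

  set.seed(5)
  sc2 <- structure(
    data.frame(gene = sprintf("g%03d", 1:200),
               statistic = rnorm(200),
               p_value = runif(200)^2,
               defined = TRUE, platform = NA_character_),
    mode = "spearman", class = c("gene_scores", "data.frame"))
  s01 <- fdr_select(sc2, 0.01, "two_sided")
  s05 <- fdr_select(sc2, 0.05, "two_sided")
  expect_true(all(s01 %in% s05))
  # directional selection only admits concordant signs
  pos <- fdr_select(sc2, 0.05, "positive")
  expect_true(all(sc2$statistic[match(pos, sc2$gene)] > 0))
})

test_that("platform intersection maps probes and collapses by min p", {
  expect_length(intersect_platforms(c("a", "b"), c("c", "d")), 0L)
  expect_setequal(intersect_platforms(c("a", "b"), c("b", "a")), c("a", "b"))
  id_map <- data.frame(probe = c("p1", "p2", "p3", "q1", "q2"),
                       gene = c("G1", "G1", "G2", "G1", "G3"))
  expect_equal(intersect_platforms(c("p1", "p3"), c("q1", "q2"), id_map), "G1")

  sc <- structure(
    data.frame(gene = c("p1", "p2", "p3"),
               statistic = c(1, 2, 3), p_value = c(0.5, 0.01, 0.2),
               defined = TRUE, platform = "arrayA"),
    mode = "spearman", class = c("gene_scores", "data.frame"))
  col <- collapse_probes(sc, id_map)
  expect_equal(col$p_value[col$gene == "G1"], 0.01)  # min-p probe wins
  expect_equal(col$statistic[col$gene == "G1"], 2)
})

test_that("h-values follow the one-sided min-p rule over gpr leaves", {
  eqs <- c(R1 = "A[c] => B[c]", R2 = "B[c] => C[c]", R3 = "C[c] => D[c]")
  m <- model_from_equations(eqs, gprs = c("gA", "", "gB or gC"))
  sc <- structure(
    data.frame(gene = c("gA", "gB", "gC"),
               statistic = c(3, 3, 3),         # all positively associated
               p_value = c(0.02, 0.5, 0.001),  # two-sided
               defined = TRUE, platform = NA_character_),
    mode = "spearman", class = c("gene_scores", "data.frame"))
  h <- reaction_h_values(sc, m, direction = "positive")
  expect_equal(h$h[h$reaction_id == "R1"], 1 - 0.01)   # one-sided p = 0.02/2
  expect_equal(h$h[h$reaction_id == "R2"], 0)
  expect_false(h$scored[h$reaction_id == "R2"])
  expect_equal(h$h[h$reaction_id == "R3"], 1 - 0.0005) # min over leaves
  expect_equal(h$contributing_gene[h$reaction_id == "R3"], "gC")
  # a negatively-associated gene contributes no positive evidence
  sc$statistic <- c(-3, 3, 3)
  h2 <- reaction_h_values(sc, m, direction = "positive")
  expect_equal(h2$h[h2$reaction_id == "R1"], 1 - (1 - 0.01))
})

test_that("expression/phenotype TSV io round-trips", {
  phen <- make_phen(10)
  expr <- matrix(rnorm(30), nrow = 3,
                 dimnames = list(paste0("g", 1:3), phen$sample_id))
  d <- tempfile()
  dir.create(d)
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(tab, file.path(d, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(phen, file.path(d, "p.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_expression(file.path(d, "e.tsv")), expr, tolerance = 1e-12)
  p2 <- read_phenotype(file.path(d, "p.tsv"))
  expect_equal(p2$value, phen$value, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
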