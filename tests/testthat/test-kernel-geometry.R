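test_that("chain null space is the uniform flux vector and nothing is blocked", {
  m <- chain3_model()
  g <- compute_geometry(m)
  expect_equal(g$nullity, 1L)
  expect_length(g$blocked, 0L)
  # the kernel direction is the uniform flux (1,1,1) expressed in the
  # column-normalized coordinates, i.e. proportional to the column norms
  k <- g$K[, 1]
  expected <- g$col_norms / sqrt(sum(g$col_norms^2))
  expect_equal(abs(unname(k)), unname(expected), tolerance = 1e-12)
  # basis orthonormal and in the null space of the scaled matrix
  S_scaled <- sweep(as.matrix(m$S), 2L, g$col_norms, "/")
  expect_lt(max(abs(S_scaled %*% g$K)), 1e-9)
  expect_equal(t(g$K) %*% g$K, diag(1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a dead-end internal conversion is blocked (nullity zero)", {
  m <- model_from_equations(c(R1 = "A[c] => B[c]"))
  g <- compute_geometry(m)
  expect_equal(g$nullity, 0L)
  expect_equal(g$blocked, "R1")
  expect_error(angle(g, "R1", "R1"), "blocked")
  expect_true(oracle_blocked(as.matrix(m$S), 1))
})

test_that("fully coupled chain reactions have zero pairwise angle", {
  g <- compute_geometry(chain3_model())
  for (i in 1:3) for (j in 1:3) {
    expect_equal(angle(g, i, j), 0, tolerance = 1e-7)
  }
})

test_that("parallel alternative routes have a positive angle, self-angle zero", {
  m <- model_from_equations(c(
    EX_IN = "x[b] => A[c]",
    R2 = "A[c] => B[c]",
    R3 = "A[c] => B[c]",
    EX_OUT = "B[c] => y[b]"
  ))
  g <- compute_geometry(m)
  expect_equal(angle(g, "R2", "R2"), 0, tolerance = 1e-9)
  th <- angle(g, "R2", "R3")
  expect_gt(th, 1)
  expect_false(isTRUE(oracle_fully_coupled(as.matrix(m$S), 2, 3)))
  # but each route is still coupled to nothing besides itself
  expect_true(oracle_fully_coupled(as.matrix(m$S), 1, 4))
  expect_equal(angle(g, "EX_IN", "EX_OUT"), 0, tolerance = 1e-7)
})

test_that("angle matrix is symmetric with zero diagonal and [0,90] range", {
  m <- make_toy_model(1, 4, n_diamonds = 1)
  g <- compute_geometry(m)
  th <- angle_matrix(g)
  expect_equal(th, t(th), tolerance = 1e-9)
  expect_true(all(diag(th) == 0, na.rm = TRUE))
  expect_true(all(th >= 0 & th <= 90, na.rm = TRUE))
})

test_that("full-coupling classes match the sampling flux-coupling oracle", {
  models <- list(
    chain = chain3_model(),
    diamond = diamond_model(),
    two_chains = make_toy_model(2, 3),
    mixed = make_toy_model(1, 3, n_diamonds = 1, n_parallel = 1)
  )
  for (nm in names(models)) {
    m <- models[[nm]]
    g <- compute_geometry(m)
    classes <- full_coupling_sets(g)
    got <- lapply(classes, function(cl) sort(match(cl, reaction_ids(m))))
    want <- lapply(oracle_coupling_classes(as.matrix(m$S)), sort)
    key <- function(sets) sort(vapply(sets, paste, character(1), collapse = ","))
    expect_equal(key(got), key(want), info = nm)
  }
})

test_that("linear chain forms one class; disconnected chains form two", {
  m1 <- make_toy_model(1, 6)
  g1 <- compute_geometry(m1)
  cls1 <- full_coupling_sets(g1)
  expect_length(cls1, 1L)
  expect_length(cls1[[1]], 8L)  # 6 interior + 2 exchanges

  m2 <- make_toy_model(2, 3)
  cls2 <- full_coupling_sets(compute_geometry(m2))
  expect_length(cls2, 2L)

  # diamond branches are not mutually coupled
  cls3 <- full_coupling_sets(compute_geometry(diamond_model()))
  branch_of <- function(r) which(vapply(cls3, function(cl) r %in% cl, logical(1)))
  expect_false(branch_of("AB") == branch_of("AC"))
  expect_equal(branch_of("AB"), branch_of("BD"))
})

test_that("angles are invariant to reaction permutation and column scaling", {
  eqs <- c(
    EX_IN = "x[b] => A[c]",
    AB = "A[c] => B[c]",
    AC = "A[c] => C[c]",
    BD = "B[c] => D[c]",
    CD = "C[c] => D[c]",
    EX_OUT = "D[c] => y[b]"
  )
  m <- model_from_equations(eqs)
  th <- angle_matrix(compute_geometry(m))

  set.seed(11)
  perm <- sample(length(eqs))
  mp <- model_from_equations(eqs[perm])
  thp <- angle_matrix(compute_geometry(mp))
  expect_equal(thp[rownames(th), colnames(th)], th, tolerance = 1e-7)

  # scale one reaction's stoichiometry by an arbitrary nonzero factor
  eqs_scaled <- eqs
  eqs_scaled["AB"] <- "3 A[c] => 3 B[c]"
  ths <- angle_matrix(compute_geometry(model_from_equations(eqs_scaled)))
  expect_equal(ths, th, tolerance = 1e-7)
})

test_that("angle folding is invariant to a reaction's written direction", {
  # the same chain with the middle reaction written in either orientation:
  # the reversed sign convention must not move its angles off zero
  m_fwd <- model_from_equations(c(
    EX_IN = "x[b] => A[c]",
    AB = "A[c] <=> B[c]",
    EX_OUT = "B[c] => y[b]"
  ))
  m_rev <- model_from_equations(c(
    EX_IN = "x[b] => A[c]",
    AB = "B[c] <=> A[c]",
    EX_OUT = "B[c] => y[b]"
  ))
  g_fwd <- compute_geometry(m_fwd)
  g_rev <- compute_geometry(m_rev)
  expect_equal(angle(g_fwd, "EX_IN", "AB"), 0, tolerance = 1e-7)
  expect_equal(angle(g_rev, "EX_IN", "AB"), 0, tolerance = 1e-7)
  expect_equal(angle_matrix(g_rev), angle_matrix(g_fwd), tolerance = 1e-7)
})

test_that("a duplicated route behaves as a parallel alternative, not coupling", {
  # two copies of the same conversion can trade flux between each other in
  # steady state, so they are not fully coupled and sit at a positive angle
  m <- model_from_equations(c(
    EX_IN = "x[b] => A[c]",
    AB = "A[c] => B[c]",
    AB_COPY = "A[c] => B[c]",
    EX_OUT = "B[c] => y[b]"
  ))
  g <- compute_geometry(m)
  expect_gt(angle(g, "AB", "AB_COPY"), 1)
  expect_false(isTRUE(oracle_fully_coupled(as.matrix(m$S), 2, 3)))
  # by symmetry each copy sits at the same angle to the exchange flux
  expect_equal(angle(g, "AB", "EX_IN"), angle(g, "AB_COPY", "EX_IN"),
               tolerance = 1e-7)
})

test_that("geometry cache reuses results keyed by model content", {
  m <- chain3_model()
  cache <- file.path(tempdir(), "geomcache")
  g1 <- compute_geometry(m, cache_dir = cache)
  files <- list.files(cache)
  expect_length(files, 1L)
  g2 <- compute_geometry(m, cache_dir = cache)
  expect_equal(g2$K, g1$K)
  expect_length(list.files(cache), 1L)
  unlink(cache, recursive = TRUE)
})

test_that("angle pair export writes only pairs under the cutoff", {
  g <- compute_geometry(make_toy_model(1, 3, n_parallel = 1))
  tmp <- tempfile(fileext = ".tsv")
  export_angle_pairs(g, tmp, max_theta = 1)
  tab <- read.delim(tmp)
  expect_true(all(tab$theta_degrees <= 1))
  expect_gt(nrow(tab), 0)
})
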