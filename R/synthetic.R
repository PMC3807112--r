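# Synthetic benchmark scenarios with planted ground truth.
#
# Toy stoichiometric models are composed from small motifs (series chains
# with exchange reactions, diamonds, parallel duplicate routes), each chain
# forming one full-coupling class; expression matrices plant a monotone
# phenotype association on the genes of chosen pathway reactions against a
# noise background. Every generator is deterministic given its seed.

chain_motif <- function(prefix, length) {
  mets <- sprintf("%s_m%d[c]", prefix, seq_len(length + 1L))
  rxns <- list(list(
    id = paste0(prefix, "_ex_in"),
    stoichiometry = stats::setNames(c(-1, 1), c(sprintf("%s_x_in[b]", prefix), mets[1])),
    reversible = FALSE, gpr = NULL, subsystem = prefix
  ))
  for (k in seq_len(length)) {
    rid <- sprintf("%s_r%d", prefix, k)
    rxns[[length(rxns) + 1L]] <- list(
      id = rid,
      stoichiometry = stats::setNames(c(-1, 1), c(mets[k], mets[k + 1L])),
      reversible = FALSE, gpr = paste0("g_", rid), subsystem = prefix
    )
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = paste0(prefix, "_ex_out"),
    stoichiometry = stats::setNames(c(-1, 1),
                                    c(mets[length + 1L], sprintf("%s_x_out[b]", prefix))),
    reversible = FALSE, gpr = NULL, subsystem = prefix
  )
  rxns
}

diamond_motif <- function(prefix) {
  m <- function(x) sprintf("%s_%s[c]", prefix, x)
  mk <- function(id, from, to, gene = TRUE) {
    list(id = sprintf("%s_%s", prefix, id),
         stoichiometry = stats::setNames(c(-1, 1), c(from, to)),
         reversible = FALSE,
         gpr = if (gene) sprintf("g_%s_%s", prefix, id) else NULL,
         subsystem = prefix)
  }
  list(
    mk("ex_in", sprintf("%s_x_in[b]", prefix), m("a"), gene = FALSE),
    mk("ab", m("a"), m("b")),
    mk("bd", m("b"), m("d")),
    mk("ac", m("a"), m("c")),
    mk("cd", m("c"), m("d")),
    mk("ex_out", m("d"), sprintf("%s_x_out[b]", prefix), gene = FALSE)
  )
}

parallel_motif <- function(prefix, n_routes = 2L) {
  m <- function(x) sprintf("%s_%s[c]", prefix, x)
  rxns <- list(list(
    id = sprintf("%s_ex_in", prefix),
    stoichiometry = stats::setNames(c(-1, 1), c(sprintf("%s_x_in[b]", prefix), m("a"))),
    reversible = FALSE, gpr = NULL, subsystem = prefix
  ))
  for (k in seq_len(n_routes)) {
    rid <- sprintf("%s_p%d", prefix, k)
    rxns[[length(rxns) + 1L]] <- list(
      id = rid, stoichiometry = stats::setNames(c(-1, 1), c(m("a"), m("b"))),
      reversible = FALSE, gpr = paste0("g_", rid), subsystem = prefix
    )
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = sprintf("%s_ex_out", prefix),
    stoichiometry = stats::setNames(c(-1, 1), c(m("b"), sprintf("%s_x_out[b]", prefix))),
    reversible = FALSE, gpr = NULL, subsystem = prefix
  )
  rxns
}

#' Generate a toy metabolic model from motif counts
#'
#' Composes series chains (with exchange reactions), diamond motifs and
#' parallel duplicate routes into one model. Interior reactions carry a
#' trivial one-gene rule (`g_<reaction_id>`); exchange reactions carry no
#' rule, so they can only join sub-networks through coupling expansion.
#'
#' @param n_chains number of independent series chains.
#' @param chain_length interior reactions per chain.
#' @param n_diamonds number of diamond motifs (two parallel 2-step branches).
#' @param n_parallel number of parallel duplicate-route motifs.
#' @param seed integer seed (kept for interface symmetry; the model is
#'   deterministic in its counts).
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(n_chains = 1L, chain_length = 5L, n_diamonds = 0L,
                           n_parallel = 0L, seed = 1L) {
  stopifnot(n_chains >= 0, chain_length >= 1, n_diamonds >= 0, n_parallel >= 0)
  rxns <- list()
  for (i in seq_len(n_chains)) {
    rxns <- c(rxns, chain_motif(sprintf("chain%d", i), chain_length))
  }
  for (i in seq_len(n_diamonds)) {
    rxns <- c(rxns, diamond_motif(sprintf("diam%d", i)))
  }
  for (i in seq_len(n_parallel)) {
    rxns <- c(rxns, parallel_motif(sprintf("par%d", i)))
  }
  if (length(rxns) == 0L) stop("empty motif specification", call. = FALSE)
  rxns <- lapply(rxns, function(r) {
    r$gpr <- parse_gpr(r$gpr)
    r
  })
  new_metabolic_model(rxns)
}

#' Generate an expression matrix with a planted phenotype association
#'
#' Growth rates are drawn log-uniformly over a 4-fold range (the spread
#' observed across fast and slow cancer cell lines); genes of the planted
#' reactions follow `effect * z(rank(mu)) + noise`, all other model genes
#' and `n_decoy_genes` extra decoys are pure Gaussian noise.
#'
#' @param model a `metabolic_model`.
#' @param planted character vector of reaction ids whose genes carry signal.
#' @param n_samples number of samples (>= 8).
#' @param effect monotone effect strength (in noise-SD units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_decoy_genes extra unmapped decoy genes.
#' @param mu_range growth-rate range `c(min, max)` in 1/h.
#' @param seed integer seed.
#' @return list with `expression` (genes x samples), `phenotype`, and
#'   `truth` (`planted_reactions`, `planted_genes`).
#' @export
make_expression <- function(model, planted, n_samples = 60L, effect = 2,
                            noise_sd = 1, n_decoy_genes = 20L,
                            mu_range = c(0.01, 0.04), seed = 1L) {
  stopifnot(n_samples >= 8L)
  rids <- reaction_ids(model)
  stopifnot(all(planted %in% rids))
  set.seed(seed)
  mu <- exp(stats::runif(n_samples, log(mu_range[1]), log(mu_range[2])))
  samples <- sprintf("s%02d", seq_len(n_samples))
  phen <- phenotype_vector(samples, mu)
  planted_genes <- sort(unique(unlist(
    lapply(model$reactions[match(planted, rids)], function(r) gpr_leaves(r$gpr)),
    use.names = FALSE)))
  genes <- c(model$genes,
             if (n_decoy_genes > 0L) sprintf("decoy_%03d", seq_len(n_decoy_genes)))
  expr <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
  z <- as.numeric(scale(rank(mu)))
  for (g in planted_genes) {
    expr[g, ] <- expr[g, ] + effect * z
  }
  list(expression = expr, phenotype = phen,
       truth = list(planted_reactions = planted, planted_genes = planted_genes))
}

#' Generate a complete benchmark scenario
#'
#' Toy model plus planted expression; the planted pathway is the first
#' chain's interior, and the expected sub-network (recorded in `truth`) is
#' its full-coupling class, which the generator verifies contains the
#' planted reactions.
#'
#' @param n_chains,chain_length,n_diamonds,n_parallel motif counts passed to
#'   [make_toy_model()].
#' @param n_samples,effect,noise_sd,n_decoy_genes passed to
#'   [make_expression()].
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return list with `model`, `expression`, `phenotype`, `truth`, `seed`.
#' @export
make_scenario <- function(n_chains = 2L, chain_length = 5L, n_diamonds = 1L,
                          n_parallel = 1L, n_samples = 60L, effect = 2,
                          noise_sd = 1, n_decoy_genes = 20L, seed = 1L) {
  model <- make_toy_model(n_chains, chain_length, n_diamonds, n_parallel, seed)
  planted <- grep("^chain1_r", reaction_ids(model), value = TRUE)
  gen <- make_expression(model, planted, n_samples, effect, noise_sd,
                         n_decoy_genes, seed = seed)
  geom <- compute_geometry(model)
  classes <- full_coupling_sets(geom)
  host <- classes[vapply(classes, function(cl) any(planted %in% cl), logical(1))]
  if (length(host) != 1L || !all(planted %in% host[[1]])) {
    stop("planted pathway is not a single full-coupling class", call. = FALSE)
  }
  truth <- gen$truth
  truth$expected_subnetwork <- host[[1]]
  list(model = model, expression = gen$expression, phenotype = gen$phenotype,
       truth = truth, seed = seed)
}

#' Write a scenario to a directory
#'
#' Writes `model.tsv`, `expression.tsv`, `phenotype.tsv` and `truth.json`.
#'
#' @param scenario output of [make_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(scenario$model, file.path(dir, "model.tsv"))
  expr <- data.frame(gene = rownames(scenario$expression),
                     scenario$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(scenario$truth, list(seed = scenario$seed)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
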