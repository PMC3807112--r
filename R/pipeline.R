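# End-to-end pipeline orchestration.
#
# One configuration object drives the whole analysis: model + expression +
# phenotype in, score tables, sub-network reports, robustness reports and
# (optionally) PPI reports out, with a manifest recording config and input
# hashes so identical runs are identical on disk.

#' Build a pipeline run configuration
#'
#' @param model_path metabolic model file (tabular or SBML).
#' @param expression_path expression TSV (gene x sample).
#' @param phenotype_path phenotype TSV (sample, value-or-group).
#' @param out_dir output directory.
#' @param mode `"correlation"` (Spearman vs growth rate) or `"two_group"`
#'   (Welch t between groups).
#' @param positive_group for `two_group` mode, the label whose higher
#'   expression counts as positive evidence (e.g. the deceased group);
#'   default: second factor level of the phenotype.
#' @param ppi_path optional interaction edge-list TSV.
#' @param q FDR level for the gene selection report.
#' @param h_min seed significance threshold (the two-group mode typically
#'   uses a laxer value, e.g. 0.80, since patient cohorts yield weaker
#'   per-gene significance).
#' @param theta_max seed angle threshold, degrees.
#' @param tol_angle full-coupling tolerance, degrees.
#' @param tol_blocked blocked-reaction projection-norm tolerance.
#' @param min_seed minimum seed-cluster size.
#' @param top_n sub-networks kept for the unique-metabolite collection.
#' @param k_hub PPI hub degree threshold.
#' @param seed integer RNG seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(model_path, expression_path, phenotype_path, out_dir,
                       mode = c("correlation", "two_group"), ppi_path = NULL,
                       positive_group = NULL,
                       q = 0.05, h_min = NULL, theta_max = 15,
                       tol_angle = 1e-4, tol_blocked = 1e-8, min_seed = 2L,
                       top_n = 100L, k_hub = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(h_min)) h_min <- if (mode == "correlation") 0.95 else 0.80
  stopifnot(q > 0, q < 1, h_min > 0, h_min < 1, theta_max > 0,
            theta_max <= 90, tol_angle >= 0, tol_blocked >= 0,
            min_seed >= 1, top_n >= 1, k_hub >= 1)
  structure(
    list(model_path = model_path, expression_path = expression_path,
         phenotype_path = phenotype_path, out_dir = out_dir, mode = mode,
         ppi_path = ppi_path, positive_group = positive_group,
         q = q, h_min = h_min, theta_max = theta_max,
         tol_angle = tol_angle, tol_blocked = tol_blocked,
         min_seed = as.integer(min_seed), top_n = as.integer(top_n),
         k_hub = as.integer(k_hub), seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full sub-network pipeline
#'
#' Stages: read inputs, score genes against the phenotype, lift to
#' reaction h-values, compute null-space geometry, detect and expand
#' sub-networks, compute robustness reports, and (when an edge list is
#' configured) the PPI component report. All outputs land under
#' `config$out_dir`; a `manifest.json` records the config and md5 hashes of
#' every input.
#'
#' @param config a `run_config`.
#' @return invisible list with the in-memory results (`model`, `scores`,
#'   `h`, `geometry`, `subnetworks`, `robustness`, `unique_metabolites`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  model <- stage("read_model", read_model(config$model_path))
  expr <- stage("read_expression", {
    if (!file.exists(config$expression_path)) {
      stop("expression file not found: ", config$expression_path)
    }
    read_expression(config$expression_path)
  })
  phen <- stage("read_phenotype", read_phenotype(config$phenotype_path))

  scores <- stage("score_genes", {
    if (config$mode == "correlation") spearman_scores(expr, phen)
    else ttest_scores(expr, phen, positive_group = config$positive_group)
  })
  write_gene_scores(scores, file.path(out, "gene_scores.tsv"),
                    q_levels = config$q)

  h <- stage("h_values", reaction_h_values(scores, model))
  utils::write.table(as.data.frame(h), file.path(out, "reaction_h.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  geometry <- stage("geometry",
                    compute_geometry(model, tol_blocked = config$tol_blocked))
  subnets <- stage("subnetworks",
                   detect_subnetworks(geometry, h, model,
                                      h_min = config$h_min,
                                      theta_max = config$theta_max,
                                      min_seed = config$min_seed,
                                      tol_angle = config$tol_angle))
  robustness <- stage("robustness",
                      lapply(subnets, robustness_report, model = model))
  write_subnetwork_reports(subnets, model, out, robustness)
  write_robustness_reports(robustness, file.path(out, "robustness.tsv"),
                           file.path(out, "robustness.json"))
  um <- stage("unique_metabolites",
              if (length(subnets) > 0L)
                collection_unique_metabolites(subnets, model,
                                              min(config$top_n, length(subnets)))
              else character(0))
  writeLines(um, file.path(out, "collection_unique_metabolites.txt"))

  ppi <- NULL
  if (!is.null(config$ppi_path)) {
    ppi <- stage("ppi", {
      sel <- fdr_select(scores, config$q, "positive")
      g <- induced_subgraph(read_ppi_edges(config$ppi_path), sel)
      components_and_hubs(g, config$k_hub)
    })
    write_ppi_report(ppi, file.path(out, "ppi_components.tsv"))
  }

  manifest <- list(
    package = "metsubnet",
    version = as.character(utils::packageVersion("metsubnet")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      config$model_path, config$expression_path, config$phenotype_path,
      config$ppi_path)))),
    n_subnetworks = length(subnets)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(model = model, scores = scores, h = h, geometry = geometry,
                 subnetworks = subnets, robustness = robustness,
                 unique_metabolites = um, ppi = ppi))
}
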