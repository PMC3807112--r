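# Sub-network robustness from unique-metabolite mass balances.
#
# Each metabolite unique to a sub-network contributes, at steady state, one
# mass-balance equation over the sub-network's reaction fluxes. The degrees
# of freedom (DOF) of that system measure robustness: a series pathway has
# DOF 1 (one rate sets all), n parallel routes have DOF n. Low DOF marks
# fragile, drug-attractive regions; a unique metabolite whose blocking
# drives the remaining DOF to zero is essential to the sub-network.

subnet_reaction_set <- function(subnet) {
  if (inherits(subnet, "subnetwork")) subnet$reactions else as.character(subnet)
}

#' Metabolites unique to a sub-network
#'
#' Non-boundary metabolites with a nonzero coefficient in at least one
#' sub-network reaction and a zero coefficient in every reaction outside it.
#'
#' @param subnet a `subnetwork` or character vector of reaction ids.
#' @param model the `metabolic_model`.
#' @return character vector of metabolite ids.
#' @export
unique_metabolites <- function(subnet, model) {
  rxns <- subnet_reaction_set(subnet)
  rids <- reaction_ids(model)
  stopifnot(all(rxns %in% rids))
  S <- model$S
  inside <- abs(S[, rxns, drop = FALSE])
  outside <- abs(S[, setdiff(rids, rxns), drop = FALSE])
  rownames(S)[Matrix::rowSums(inside) > 0 & Matrix::rowSums(outside) == 0]
}

#' Degrees of freedom of a sub-network
#'
#' `DOF = |reactions| - rank(S restricted to unique-metabolite rows and
#' sub-network columns)`; rank uses the package's relative singular-value
#' tolerance. Shared (cross-boundary) metabolites contribute no constraint.
#'
#' @inheritParams unique_metabolites
#' @param rel_tol relative singular-value tolerance.
#' @return integer DOF in `[0, |reactions|]`.
#' @export
subnetwork_dof <- function(subnet, model, rel_tol = 1e-9) {
  rxns <- subnet_reaction_set(subnet)
  um <- unique_metabolites(rxns, model)
  restricted_dof(rxns, um, model, rel_tol)
}

restricted_dof <- function(rxns, mets, model, rel_tol = 1e-9) {
  if (length(rxns) == 0L) return(0L)
  if (length(mets) == 0L) return(length(rxns))
  sub <- model$S[mets, rxns, drop = FALSE]
  length(rxns) - rank_tol(sub, rel_tol)
}

#' Essential metabolites of a sub-network
#'
#' For each unique metabolite, remove every sub-network reaction that
#' produces or consumes it (mimicking competitive inhibition of the enzymes
#' processing it) and recompute the DOF of the remaining reactions against
#' the remaining unique metabolites. The metabolite is essential when the
#' remaining DOF is zero (an emptied reaction set counts as DOF 0).
#'
#' @inheritParams subnetwork_dof
#' @return character vector of essential metabolite ids (subset of the
#'   unique metabolites).
#' @export
essential_metabolites <- function(subnet, model, rel_tol = 1e-9) {
  rxns <- subnet_reaction_set(subnet)
  um <- unique_metabolites(rxns, model)
  if (length(um) == 0L) return(character(0))
  ess <- vapply(um, function(m) {
    touching <- rxns[abs(model$S[m, rxns]) > 0]
    remaining <- setdiff(rxns, touching)
    rem_um <- setdiff(um, m)
    restricted_dof(remaining, rem_um, model, rel_tol) == 0L
  }, logical(1))
  um[ess]
}

#' Full robustness report for a sub-network
#' @inheritParams subnetwork_dof
#' @return object of class `robustness_report`: `subnetwork_id`, `reactions`,
#'   `unique_metabolites`, `dof`, `essential_metabolites`.
#' @export
robustness_report <- function(subnet, model, rel_tol = 1e-9) {
  rxns <- subnet_reaction_set(subnet)
  um <- unique_metabolites(rxns, model)
  structure(
    list(
      subnetwork_id = if (inherits(subnet, "subnetwork")) subnet$id else NA_character_,
      reactions = rxns,
      unique_metabolites = um,
      dof = restricted_dof(rxns, um, model, rel_tol),
      essential_metabolites = essential_metabolites(rxns, model, rel_tol)
    ),
    class = "robustness_report"
  )
}

#' @exportS3Method base::print
print.robustness_report <- function(x, ...) {
  cat("robustness_report", if (!is.na(x$subnetwork_id)) x$subnetwork_id else "",
      ":", length(x$reactions), "reactions,",
      length(x$unique_metabolites), "unique metabolites, dof =", x$dof, ",",
      length(x$essential_metabolites), "essential\n")
  invisible(x)
}

#' Write robustness reports as a flat TSV (and optionally JSON)
#' @param reports list of `robustness_report` objects.
#' @param path output TSV path.
#' @param json_path optional JSON path.
#' @return `path`, invisibly.
#' @export
write_robustness_reports <- function(reports, path, json_path = NULL) {
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      subnetwork_id = r$subnetwork_id,
      n_reactions = length(r$reactions),
      n_unique_metabolites = length(r$unique_metabolites),
      dof = r$dof,
      essential_metabolite_ids = paste(r$essential_metabolites, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(reports, unclass), json_path,
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Histogram tables of unique-metabolite counts and DOF across sub-networks
#' @param reports list of `robustness_report` objects.
#' @return data.frame with one row per sub-network: `subnetwork_id`,
#'   `n_unique_metabolites`, `dof` (ready for tabulation/plotting).
#' @export
robustness_histogram_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(subnetwork_id = r$subnetwork_id,
               n_unique_metabolites = length(r$unique_metabolites),
               dof = r$dof, stringsAsFactors = FALSE)
  }))
}
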