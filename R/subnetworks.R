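# Phenotype-correlated sub-network detection.
#
# Two phases: (1) seed clusters = connected components of the angle graph
# restricted to significant (high h-value) non-blocked reactions; (2)
# expansion by full-coupling classes, so each reported sub-network is the
# closed, connected set of reactions whose fluxes move with the seeds.

#' Seed clusters of significant, geometrically close reactions
#'
#' Restricts to non-blocked reactions with `h >= h_min`, connects pairs with
#' `theta_ij <= theta_max`, and returns the connected components with at
#' least `min_seed` members, largest first.
#'
#' @param geometry a `reaction_geometry`.
#' @param h a `reaction_h` table.
#' @param h_min significance threshold on h in (0, 1); default 0.95.
#' @param theta_max angle threshold in degrees; default 15.
#' @param min_seed minimum component size; default 2.
#' @return list of character vectors of reaction ids.
#' @export
seed_clusters <- function(geometry, h, h_min = 0.95, theta_max = 15,
                          min_seed = 2L) {
  stopifnot(h_min > 0, h_min < 1, theta_max > 0, theta_max <= 90)
  hv <- stats::setNames(h$h, h$reaction_id)
  cand <- names(hv)[hv >= h_min]
  cand <- setdiff(intersect(cand, geometry$reaction_ids), geometry$blocked)
  if (length(cand) == 0L) return(list())
  theta <- angle_matrix(geometry, cand)
  adj <- theta <= theta_max
  adj[is.na(adj)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  seeds <- split(cand, comp)
  seeds <- seeds[vapply(seeds, length, integer(1)) >= min_seed]
  names(seeds) <- NULL
  seeds <- lapply(seeds, function(s) s[order(match(s, geometry$reaction_ids))])
  ord <- order(-vapply(seeds, length, integer(1)),
               vapply(seeds, `[`, character(1), 1))
  seeds[ord]
}

#' Expand a seed with all reactions fully coupled to it
#'
#' Union of the full-coupling classes of every seed member; the result is
#' the flux-connected closure of the seed. Metabolites touched by the final
#' reaction set are recorded (boundary metabolites excluded).
#'
#' @param seed character vector of reaction ids (non-empty).
#' @param geometry a `reaction_geometry`.
#' @param model a `metabolic_model`.
#' @param h optional `reaction_h` table used to record `mean_h` over the seed.
#' @param tol_angle full-coupling angle tolerance (degrees).
#' @return object of class `subnetwork` with fields `reactions`,
#'   `seed_reactions`, `added_by_coupling`, `metabolites`, `mean_h`.
#' @export
expand_with_coupled <- function(seed, geometry, model, h = NULL,
                                tol_angle = 1e-4) {
  if (length(seed) == 0L) stop("seed is empty", call. = FALSE)
  classes <- full_coupling_sets(geometry, tol_angle)
  members <- unique(unlist(
    classes[vapply(classes, function(cl) any(seed %in% cl), logical(1))],
    use.names = FALSE))
  members <- union(members, seed)  # blocked seeds (not in any class) kept
  members <- members[order(match(members, geometry$reaction_ids))]
  mean_h <- if (is.null(h)) NA_real_ else {
    hv <- stats::setNames(h$h, h$reaction_id)
    mean(hv[seed])
  }
  new_subnetwork(members, seed, model, mean_h)
}

new_subnetwork <- function(members, seed, model, mean_h = NA_real_,
                           id = NA_character_) {
  rids <- reaction_ids(model)
  stopifnot(all(members %in% rids))
  mets <- unique(unlist(lapply(model$reactions[match(members, rids)],
                               function(r) names(r$stoichiometry)),
                        use.names = FALSE))
  mets <- setdiff(mets, model$metabolites$id[model$metabolites$boundary])
  structure(
    list(
      id = id,
      reactions = members,
      seed_reactions = intersect(members, seed),
      added_by_coupling = setdiff(members, seed),
      metabolites = mets,
      mean_h = mean_h,
      rank = NA_integer_
    ),
    class = "subnetwork"
  )
}

#' @exportS3Method base::print
print.subnetwork <- function(x, ...) {
  cat("subnetwork", if (!is.na(x$id)) x$id else "", ":",
      length(x$reactions), "reactions (",
      length(x$seed_reactions), "seed +",
      length(x$added_by_coupling), "coupled ),",
      length(x$metabolites), "metabolites\n")
  invisible(x)
}

#' Rank sub-networks by size
#'
#' Descending reaction count; ties broken by descending `mean_h`, then by
#' the lexicographically first reaction id. Assigns `rank` and `id` fields.
#'
#' @param subnets list of `subnetwork` objects.
#' @return the list sorted, with `rank` fields `1..n`.
#' @export
rank_subnetworks <- function(subnets) {
  if (length(subnets) == 0L) return(list())
  sizes <- vapply(subnets, function(s) length(s$reactions), integer(1))
  mh <- vapply(subnets, function(s) ifelse(is.na(s$mean_h), -Inf, s$mean_h),
               numeric(1))
  first <- vapply(subnets, function(s) sort(s$reactions)[1], character(1))
  ord <- order(-sizes, -mh, first)
  out <- subnets[ord]
  for (k in seq_along(out)) {
    out[[k]]$rank <- k
    if (is.na(out[[k]]$id)) out[[k]]$id <- sprintf("subnet_%03d", k)
  }
  out
}

#' Detect phenotype-correlated sub-networks
#'
#' The full two-phase procedure: seed clusters on the thresholded angle
#' graph of significant reactions, then coupling expansion, then ranking.
#'
#' @inheritParams seed_clusters
#' @param model the `metabolic_model` the geometry was computed from.
#' @param tol_angle full-coupling tolerance for the expansion step.
#' @return ranked list of `subnetwork` objects.
#' @export
detect_subnetworks <- function(geometry, h, model, h_min = 0.95,
                               theta_max = 15, min_seed = 2L,
                               tol_angle = 1e-4) {
  seeds <- seed_clusters(geometry, h, h_min, theta_max, min_seed)
  subnets <- lapply(seeds, expand_with_coupled, geometry = geometry,
                    model = model, h = h, tol_angle = tol_angle)
  rank_subnetworks(subnets)
}

#' Write sub-network reports
#'
#' Per sub-network: a human-readable text block listing each reaction's
#' stoichiometry followed by its associated genes, plus one machine-readable
#' JSON file with seed/added/metabolite (and, when supplied, robustness)
#' fields.
#'
#' @param subnets ranked list of `subnetwork` objects.
#' @param model the `metabolic_model`.
#' @param dir output directory (created if needed).
#' @param robustness optional list of `robustness_report` objects parallel to
#'   `subnets`.
#' @return `dir`, invisibly.
#' @export
write_subnetwork_reports <- function(subnets, model, dir, robustness = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rids <- reaction_ids(model)
  txt <- character(0)
  json <- list()
  for (k in seq_along(subnets)) {
    sn <- subnets[[k]]
    txt <- c(txt, sprintf("# %s (rank %d): %d reactions, mean_h = %.4f",
                          sn$id, sn$rank, length(sn$reactions),
                          ifelse(is.na(sn$mean_h), 0, sn$mean_h)))
    for (rid in sn$reactions) {
      r <- model$reactions[[match(rid, rids)]]
      genes <- gpr_leaves(r$gpr)
      txt <- c(txt,
               sprintf("%s: %s", rid, equation_string(r)),
               sprintf("  genes: %s",
                       if (length(genes)) paste(genes, collapse = ", ") else "-"))
    }
    txt <- c(txt, "")
    entry <- list(
      id = sn$id, rank = sn$rank,
      reactions = sn$reactions,
      seed_reactions = sn$seed_reactions,
      added_by_coupling = sn$added_by_coupling,
      metabolites = sn$metabolites,
      mean_h = sn$mean_h
    )
    if (!is.null(robustness)) {
      rb <- robustness[[k]]
      entry$unique_metabolites <- rb$unique_metabolites
      entry$dof <- rb$dof
      entry$essential_metabolites <- rb$essential_metabolites
    }
    json[[sn$id]] <- entry
  }
  writeLines(txt, file.path(dir, "subnetworks.txt"))
  jsonlite::write_json(json, file.path(dir, "subnetworks.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

equation_string <- function(r) {
  st <- r$stoichiometry
  fmt <- function(v) {
    paste(ifelse(abs(v) == 1, names(v), paste(format(abs(v), trim = TRUE), names(v))),
          collapse = " + ")
  }
  paste(fmt(st[st < 0]), if (r$reversible) "<=>" else "=>", fmt(st[st > 0]))
}
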