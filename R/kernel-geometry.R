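# Null-space geometry of the stoichiometric matrix.
#
# Steady-state fluxes satisfy S v = 0; the unit vector e_i of reaction i is
# projected onto the null space, p_i = K K' e_i, and the angle between two
# projections measures how tightly the two fluxes are coupled across all
# steady states. Fully coupled reactions (proportional fluxes in every
# steady state) have collinear projections, i.e. a zero angle, even when
# they share no metabolite.

#' Numerical rank with a relative singular-value tolerance
#' @param M a matrix (dense or `Matrix`).
#' @param rel_tol singular values below `rel_tol * max(sv)` count as zero.
#' @return integer rank.
#' @export
rank_tol <- function(M, rel_tol = 1e-9) {
  M <- as.matrix(M)
  if (length(M) == 0L || all(M == 0)) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > rel_tol * d[1])
}

#' Compute the null-space geometry of a metabolic model
#'
#' Orthonormal null-space basis of `S` obtained from a singular value
#' decomposition (singular values below `rel_tol * sigma_max` are treated as
#' zero). Columns of `S` are first scaled to unit norm, so the similarity
#' measure does not depend on the arbitrary factor a reaction equation is
#' multiplied through by; this rescales flux coordinates and leaves the
#' blocked set and all full-coupling relations unchanged. Reactions whose
#' projection onto the null space has norm at most `tol_blocked` are
#' blocked: they carry zero flux in every steady state.
#'
#' @param model a `metabolic_model`.
#' @param tol_blocked projection-norm threshold for blocked reactions.
#' @param rel_tol relative singular-value tolerance for the rank decision.
#' @param cache_dir optional directory; geometry is stored there keyed by a
#'   content hash of the model and reused on identical input.
#' @return object of class `reaction_geometry` with fields `K` (n_reactions x
#'   d orthonormal basis, rows named by reaction id), `norms` (projection
#'   norms per reaction), `blocked` (reaction ids), `nullity`, `rank`.
#' @export
compute_geometry <- function(model, tol_blocked = 1e-8, rel_tol = 1e-9,
                             cache_dir = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- length(model$reactions)
  if (n < 1L) stop("model has no reactions", call. = FALSE)
  if (!is.null(cache_dir)) {
    key <- geometry_cache_key(model, tol_blocked, rel_tol)
    cache_file <- file.path(cache_dir, paste0("geometry-", key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  S <- as.matrix(model$S)
  cn <- sqrt(colSums(S^2))
  S <- sweep(S, 2L, pmax(cn, .Machine$double.eps), "/")
  rids <- reaction_ids(model)
  if (nrow(S) == 0L) {
    K <- diag(n)
    r <- 0L
  } else {
    sv <- svd(S, nu = 0, nv = n)
    d <- c(sv$d, rep(0, n - length(sv$d)))
    r <- if (max(d) == 0) 0L else sum(d > rel_tol * max(d))
    K <- if (r < n) sv$v[, (r + 1L):n, drop = FALSE] else
      matrix(0, nrow = n, ncol = 0)
  }
  rownames(K) <- rids
  norms <- sqrt(rowSums(K^2))
  geom <- structure(
    list(
      K = K,
      norms = stats::setNames(norms, rids),
      blocked = rids[norms <= tol_blocked],
      nullity = ncol(K),
      rank = as.integer(r),
      col_norms = stats::setNames(cn, rids),
      reaction_ids = rids,
      tol_blocked = tol_blocked,
      rel_tol = rel_tol
    ),
    class = "reaction_geometry"
  )
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(geom, cache_file)
  }
  geom
}

geometry_cache_key <- function(model, tol_blocked, rel_tol) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_model(model, tmp)
  cat(format(c(tol_blocked, rel_tol), digits = 17), file = tmp, append = TRUE)
  unname(tools::md5sum(tmp))
}

#' @exportS3Method base::print
print.reaction_geometry <- function(x, ...) {
  cat("reaction_geometry:", length(x$reaction_ids), "reactions, nullity",
      x$nullity, "|", length(x$blocked), "blocked\n")
  invisible(x)
}

#' Projection of reaction unit vectors onto the null space
#' @param geometry a `reaction_geometry`.
#' @return n_reactions x n_reactions matrix whose column i is
#'   `p_i = K K' e_i`.
#' @export
kernel_projections <- function(geometry) {
  P <- geometry$K %*% t(geometry$K)
  dimnames(P) <- list(geometry$reaction_ids, geometry$reaction_ids)
  P
}

resolve_rxn_index <- function(geometry, i) {
  if (is.character(i)) {
    k <- match(i, geometry$reaction_ids)
    if (anyNA(k)) stop("unknown reaction id: ", i[is.na(k)][1], call. = FALSE)
    return(k)
  }
  as.integer(i)
}

#' Angle between two reactions' null-space projections
#'
#' `theta = acos(|p_i . p_j| / (|p_i| |p_j|))` in degrees, folded to
#' `[0, 90]` by the absolute value so that a reaction and a direction-reversed
#' fully coupled partner also score zero.
#'
#' @param geometry a `reaction_geometry`.
#' @param i,j reaction indices or ids.
#' @return angle in degrees.
#' @export
angle <- function(geometry, i, j) {
  i <- resolve_rxn_index(geometry, i)
  j <- resolve_rxn_index(geometry, j)
  rids <- geometry$reaction_ids
  bad <- intersect(rids[c(i, j)], geometry$blocked)
  if (length(bad) > 0L) {
    stop("angle undefined for blocked reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (i == j) return(0)
  ki <- geometry$K[i, ]
  kj <- geometry$K[j, ]
  cosv <- abs(sum(ki * kj)) / (geometry$norms[i] * geometry$norms[j])
  acos(min(max(cosv, 0), 1)) * 180 / pi
}

#' Pairwise angle matrix for a set of reactions
#'
#' Blocked reactions get `NA` rows/columns. For genome-scale models restrict
#' `subset` rather than materializing the full matrix.
#'
#' @param geometry a `reaction_geometry`.
#' @param subset reaction ids or indices (default: all reactions).
#' @return symmetric matrix of angles in degrees, `[0, 90]`, zero diagonal
#'   for non-blocked reactions.
#' @export
angle_matrix <- function(geometry, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(geometry$reaction_ids) else
    resolve_rxn_index(geometry, subset)
  rids <- geometry$reaction_ids[idx]
  K <- geometry$K[idx, , drop = FALSE]
  nrm <- geometry$norms[idx]
  ok <- !(rids %in% geometry$blocked)
  theta <- matrix(NA_real_, length(idx), length(idx), dimnames = list(rids, rids))
  if (any(ok)) {
    Kn <- K[ok, , drop = FALSE] / nrm[ok]
    cosm <- abs(tcrossprod(Kn))
    cosm[cosm > 1] <- 1
    theta[ok, ok] <- acos(cosm) * 180 / pi
    theta[cbind(which(ok), which(ok))] <- 0
  }
  theta
}

#' Partition non-blocked reactions into full-coupling classes
#'
#' Transitive closure of the relation `theta_ij <= tol_angle`: connected
#' components of the thresholded angle graph. Reactions in one class have
#' proportional fluxes in every steady state.
#'
#' @param geometry a `reaction_geometry`.
#' @param tol_angle angle tolerance in degrees (default `1e-4`).
#' @return list of character vectors of reaction ids (classes, singletons
#'   included), ordered by first member's model position.
#' @export
full_coupling_sets <- function(geometry, tol_angle = 1e-4) {
  stopifnot(tol_angle >= 0)
  rids <- setdiff(geometry$reaction_ids, geometry$blocked)
  if (length(rids) == 0L) return(list())
  theta <- angle_matrix(geometry, rids)
  adj <- theta <= tol_angle
  adj[is.na(adj)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  classes <- split(rids, comp)
  names(classes) <- NULL
  classes[order(vapply(classes, function(cl) match(cl[1], geometry$reaction_ids),
                       integer(1)))]
}

#' Export reaction pairs below an angle cutoff as TSV
#' @param geometry a `reaction_geometry`.
#' @param path output TSV path.
#' @param max_theta only pairs with `theta <= max_theta` degrees are written.
#' @return `path`, invisibly.
#' @export
export_angle_pairs <- function(geometry, path, max_theta = 15) {
  theta <- angle_matrix(geometry)
  idx <- which(upper.tri(theta) & !is.na(theta) & theta <= max_theta,
               arr.ind = TRUE)
  tab <- data.frame(
    reaction_id_1 = rownames(theta)[idx[, 1]],
    reaction_id_2 = colnames(theta)[idx[, 2]],
    theta_degrees = theta[idx],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$reaction_id_1, tab$reaction_id_2), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
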