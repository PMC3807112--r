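# Metabolite-overlap statistics between two sub-network collections.
#
# The comparison between the growth-correlated and mortality-correlated
# analyses happens at the metabolite level: the set of metabolites unique to
# each top-n collection, and an upper-tail hypergeometric test of their
# intersection against the model's metabolite universe.

#' Metabolites unique to a collection of sub-networks
#'
#' Union over the top-n sub-networks of the metabolites that appear in the
#' collection's reactions and in no reaction outside the collection
#' (uniqueness relative to the whole model).
#'
#' @param subnets ranked list of `subnetwork` objects (or character vectors
#'   of reaction ids).
#' @param model the `metabolic_model`.
#' @param top_n number of leading sub-networks to keep (default: all).
#' @return character vector of metabolite ids.
#' @export
collection_unique_metabolites <- function(subnets, model, top_n = length(subnets)) {
  stopifnot(top_n >= 1)
  top <- subnets[seq_len(min(top_n, length(subnets)))]
  rxns <- unique(unlist(lapply(top, subnet_reaction_set), use.names = FALSE))
  unique_metabolites(rxns, model)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `n_overlap` of the `n_A` marked
#' metabolites when `n_B` are drawn without replacement from a universe of
#' `n_universe`; evaluated in log space so genome-scale overlaps do not
#' underflow.
#'
#' @param n_universe total metabolites in the model.
#' @param n_A,n_B sizes of the two unique-metabolite sets.
#' @param n_overlap observed intersection size.
#' @return object of class `overlap_result`: the four counts, `p_value`, and
#'   `log10_p`.
#' @export
hypergeom_overlap <- function(n_universe, n_A, n_B, n_overlap) {
  if (n_overlap > min(n_A, n_B) || max(n_A, n_B) > n_universe ||
      min(n_universe, n_A, n_B, n_overlap) < 0) {
    stop("inconsistent overlap counts", call. = FALSE)
  }
  logp <- stats::phyper(n_overlap - 1, n_A, n_universe - n_A, n_B,
                        lower.tail = FALSE, log.p = TRUE)
  structure(
    list(n_universe = n_universe, n_A = n_A, n_B = n_B, n_overlap = n_overlap,
         p_value = exp(logp), log10_p = logp / log(10)),
    class = "overlap_result"
  )
}

#' @exportS3Method base::print
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of (%d, %d) in universe %d; P[X >= %d] = %.4g (log10 p = %.2f)\n",
    x$n_overlap, x$n_A, x$n_B, x$n_universe, x$n_overlap, x$p_value, x$log10_p))
  invisible(x)
}

#' Overlap test between two sub-network collections
#'
#' Computes the unique-metabolite set of each collection, their
#' intersection, and the hypergeometric test against the model's non-boundary
#' metabolite universe.
#'
#' @param subnetsA,subnetsB ranked sub-network lists.
#' @param model the `metabolic_model`.
#' @param top_n number of leading sub-networks per collection.
#' @return an `overlap_result` with the two metabolite sets attached as
#'   attributes `set_A`, `set_B`.
#' @export
collection_overlap <- function(subnetsA, subnetsB, model,
                               top_n = max(length(subnetsA), length(subnetsB))) {
  setA <- collection_unique_metabolites(subnetsA, model, min(top_n, length(subnetsA)))
  setB <- collection_unique_metabolites(subnetsB, model, min(top_n, length(subnetsB)))
  universe <- sum(!model$metabolites$boundary)
  res <- hypergeom_overlap(universe, length(setA), length(setB),
                           length(intersect(setA, setB)))
  attr(res, "set_A") <- setA
  attr(res, "set_B") <- setB
  res
}
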