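# Cofactor energetics audit of closed metabolic cycles.
#
# The motivating cycle couples cytosolic fatty-acid synthesis with
# mitochondrial beta-oxidation through the carnitine shuttle and the
# citrate-malate antiporter: per unit of cycled cytosolic acetyl-CoA it
# burns 2 ATP and 2 cytosolic NADPH (plus 1 cytosolic NADH through the
# malate leg) to deliver 2 NADH and 1 FADH2 to the mitochondrion, i.e. it
# shuttles cytosolic reducing power into the respirable pool. The auditor
# is generic: it computes the unique steady-state flux through any cycle
# whose internal carbon skeleton admits a one-dimensional flux space, then
# sums cofactor turnover per compartment and converts the mitochondrial
# redox yield into ATP at a configurable P/O ratio.

#' Path to the packaged fatty-acid futile-cycle model
#'
#' One elongation / beta-oxidation round amortized per acetyl-CoA unit.
#' Cofactors (ATP, NADPH, NADH, FADH2, CO2, CoA) are boundary metabolites
#' whose id encodes their physiological compartment (`_c` cytosol, `_m`
#' mitochondrion), so the carbon skeleton alone defines the flux space.
#' Fatty-acid activation ATP (2 per molecule) is chain-length-amortized and
#' excluded from the per-unit ledger.
#'
#' @return file path of the tabular model.
#' @export
fa_cycle_model_path <- function() {
  system.file("extdata", "fa_cycle_model.tsv", package = "metsubnet",
              mustWork = TRUE)
}

#' Unique steady-state flux through a closed cycle
#'
#' Restricts `S` to the cycle's reactions and their non-boundary
#' metabolites; the null space of the restriction must be one-dimensional.
#' The flux vector is scaled so that one unit of `basis_unit` is cycled
#' (total production of the basis metabolite by the cycle equals 1).
#'
#' @param model a `metabolic_model`.
#' @param cycle_reactions reaction ids forming the cycle (default: all).
#' @param basis_unit metabolite id used as the cycling unit (e.g. cytosolic
#'   acetyl-CoA).
#' @param rel_tol relative singular-value tolerance.
#' @return named numeric flux vector over `cycle_reactions`.
#' @export
cycle_flux <- function(model, cycle_reactions = reaction_ids(model),
                       basis_unit, rel_tol = 1e-9) {
  rids <- reaction_ids(model)
  stopifnot(all(cycle_reactions %in% rids))
  sub <- model$S[, cycle_reactions, drop = FALSE]
  touched <- Matrix::rowSums(abs(sub)) > 0
  sub <- as.matrix(sub[touched, , drop = FALSE])
  n <- length(cycle_reactions)
  sv <- svd(sub, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  r <- if (max(d) == 0) 0L else sum(d > rel_tol * max(d))
  nullity <- n - r
  if (nullity != 1L) {
    stop("cycle flux space has dimension ", nullity, " (expected 1)",
         call. = FALSE)
  }
  v <- sv$v[, n]
  names(v) <- cycle_reactions
  if (!basis_unit %in% rownames(sub)) {
    stop("basis metabolite '", basis_unit, "' not internal to the cycle",
         call. = FALSE)
  }
  # orient the cycle so irreversible reactions carry forward (>= 0) flux
  irrev <- vapply(model$reactions[match(cycle_reactions, rids)],
                  function(r) !r$reversible, logical(1))
  tol <- rel_tol * max(abs(v))
  fwd <- v[irrev][abs(v[irrev]) > tol]
  if (length(fwd) > 0L) {
    if (max(fwd) > tol && min(fwd) < -tol) {
      stop("cycle is infeasible: irreversible reactions demand opposite ",
           "orientations", call. = FALSE)
    }
    if (mean(fwd) < 0) v <- -v
  }
  contrib <- sub[basis_unit, ] * v
  produced <- sum(contrib[contrib > 0])
  if (length(fwd) == 0L && produced <= tol) {
    v <- -v
    produced <- sum(-contrib[-contrib > 0])
  }
  if (produced <= tol) {
    stop("basis metabolite '", basis_unit, "' is not cycled", call. = FALSE)
  }
  v / produced
}

default_cofactor_table <- function() {
  data.frame(
    metabolite_id = c("atp_c[b]", "nadph_c[b]", "nadh_c[b]", "nadh_m[b]",
                      "fadh2_m[b]"),
    cofactor = c("atp", "nadph", "nadh", "nadh", "fadh2"),
    compartment = c("cytosol", "cytosol", "cytosol", "mitochondrion",
                    "mitochondrion"),
    stringsAsFactors = FALSE
  )
}

#' Net cofactor turnover of a cycle per unit of flux
#'
#' Sums signed cofactor stoichiometry weighted by the cycle flux, reported
#' per (cofactor, compartment) as net production (negative = consumed).
#'
#' @param model a `metabolic_model`.
#' @param flux named flux vector from [cycle_flux()].
#' @param cofactors data.frame mapping `metabolite_id` to `cofactor` and
#'   `compartment`; default covers the packaged fatty-acid cycle fixture.
#' @return object of class `cycle_ledger`: data.frame `entries`
#'   (`cofactor`, `compartment`, `net_production`) plus convenience scalars
#'   `atp_consumed`, `nadph_consumed_cytosol`, `nadh_produced_mito`,
#'   `fadh2_produced_mito`, `nadh_consumed_cytosol`.
#' @export
cofactor_ledger <- function(model, flux, cofactors = default_cofactor_table()) {
  rids <- reaction_ids(model)
  net <- stats::setNames(numeric(nrow(cofactors)), cofactors$metabolite_id)
  for (rid in names(flux)) {
    st <- model$reactions[[match(rid, rids)]]$stoichiometry
    hit <- intersect(names(st), cofactors$metabolite_id)
    if (length(hit)) net[hit] <- net[hit] + st[hit] * flux[rid]
  }
  entries <- data.frame(
    cofactor = cofactors$cofactor,
    compartment = cofactors$compartment,
    net_production = unname(net),
    stringsAsFactors = FALSE
  )
  get <- function(cf, comp) {
    sum(entries$net_production[entries$cofactor == cf &
                                 entries$compartment == comp])
  }
  structure(
    list(
      entries = entries,
      atp_consumed = -sum(entries$net_production[entries$cofactor == "atp"]),
      nadph_consumed_cytosol = -get("nadph", "cytosol"),
      nadh_produced_mito = get("nadh", "mitochondrion"),
      fadh2_produced_mito = get("fadh2", "mitochondrion"),
      nadh_consumed_cytosol = -get("nadh", "cytosol")
    ),
    class = "cycle_ledger"
  )
}

#' @exportS3Method base::print
print.cycle_ledger <- function(x, ...) {
  cat("cycle_ledger (per cycled unit):\n")
  cat(sprintf("  ATP consumed:            %.3f\n", x$atp_consumed))
  cat(sprintf("  NADPH consumed (cyt):    %.3f\n", x$nadph_consumed_cytosol))
  cat(sprintf("  NADH consumed (cyt):     %.3f\n", x$nadh_consumed_cytosol))
  cat(sprintf("  NADH produced (mito):    %.3f\n", x$nadh_produced_mito))
  cat(sprintf("  FADH2 produced (mito):   %.3f\n", x$fadh2_produced_mito))
  invisible(x)
}

#' Respiratory ATP yield of a cycle ledger
#'
#' Gross ATP from oxidizing the mitochondrial redox pool at an NADH P/O
#' ratio of `po_nadh`; FADH2 enters the chain past complex I and yields
#' `2/3` of NADH's P/O. Net subtracts the ATP the cycle consumes.
#'
#' @param ledger a `cycle_ledger`.
#' @param po_nadh P/O ratio for NADH (ATP per oxygen atom); must be >= 0.
#' @return list with `gross_atp`, `net_atp`, `po_nadh`, `po_fadh2`.
#' @export
respiratory_yield <- function(ledger, po_nadh) {
  stopifnot(po_nadh >= 0)
  po_fadh2 <- (2 / 3) * po_nadh
  gross <- ledger$nadh_produced_mito * po_nadh +
    ledger$fadh2_produced_mito * po_fadh2
  list(
    gross_atp = gross,
    net_atp = gross - ledger$atp_consumed,
    po_nadh = po_nadh,
    po_fadh2 = po_fadh2
  )
}

#' Run the full cycle audit
#'
#' Convenience wrapper: flux, ledger, and yields at the requested P/O
#' ratios, as a JSON-ready list.
#'
#' @param model a `metabolic_model` (default: the packaged fatty-acid cycle).
#' @param cycle_reactions reaction ids of the cycle.
#' @param basis_unit cycled metabolite id.
#' @param po P/O ratios to evaluate.
#' @param cofactors cofactor mapping table.
#' @return list with `flux`, `ledger`, `yields`.
#' @export
cycle_audit <- function(model = read_model(fa_cycle_model_path()),
                        cycle_reactions = reaction_ids(model),
                        basis_unit = "accoa_c[c]",
                        po = c(3, 1.5),
                        cofactors = default_cofactor_table()) {
  flux <- cycle_flux(model, cycle_reactions, basis_unit)
  ledger <- cofactor_ledger(model, flux, cofactors)
  yields <- lapply(po, function(r) respiratory_yield(ledger, r))
  names(yields) <- paste0("po_", po)
  list(flux = flux, ledger = ledger, yields = yields)
}
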