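# Gene-level phenotype association scores and their lift to reactions.
#
# Two scoring modes mirror the two study designs the package supports:
# Spearman rank correlation of each gene with a continuous growth rate, and
# a Welch t-test between two patient groups (survivor vs deceased). Scores
# are FDR-controlled with Benjamini-Hochberg, optionally intersected across
# measurement platforms, and lifted to reactions as h-values through the
# gene-reaction rules.

#' Specific growth rate from doubling time
#'
#' Exponential growth: `mu = ln(2) / t_d`.
#'
#' @param t_d doubling time in hours (vectorized); must be positive.
#' @return growth rate in 1/h.
#' @export
growth_rate_from_doubling <- function(t_d) {
  if (any(!is.finite(t_d)) || any(t_d <= 0)) {
    stop("doubling time must be positive and finite", call. = FALSE)
  }
  log(2) / t_d
}

#' Construct a phenotype vector
#' @param sample_ids character sample ids.
#' @param values numeric growth rates (strictly positive) or a factor/character
#'   of two group labels.
#' @return a `phenotype` data.frame with columns `sample_id`, `value`.
#' @export
phenotype_vector <- function(sample_ids, values) {
  stopifnot(length(sample_ids) == length(values))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (is.numeric(values) && any(values <= 0)) {
    stop("growth rates must be strictly positive", call. = FALSE)
  }
  data.frame(sample_id = as.character(sample_ids), value = values,
             stringsAsFactors = FALSE)
}

check_expr_phen <- function(expr, phen) {
  if (is.null(colnames(expr)) || !all(phen$sample_id %in% colnames(expr))) {
    stop("expression columns do not cover phenotype sample ids", call. = FALSE)
  }
  expr[, phen$sample_id, drop = FALSE]
}

#' Spearman correlation of each gene with a continuous phenotype
#'
#' Rank correlation with midranks for ties; two-sided p-value from the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom (the large-sample approximation standard for n in the dozens).
#' Genes with zero variance are flagged undefined and excluded from FDR.
#'
#' @param expr numeric matrix, genes x samples, rownames = gene ids.
#' @param phen a `phenotype` with numeric values; at least 4 samples.
#' @param platform optional platform tag stored with the table.
#' @return a `gene_scores` data.frame: `gene`, `statistic` (rho), `p_value`,
#'   `defined`, `platform`, with attribute `mode = "spearman"`.
#' @export
spearman_scores <- function(expr, phen, platform = NA_character_) {
  if (!is.numeric(phen$value)) stop("phenotype must be numeric", call. = FALSE)
  if (nrow(phen) < 4L) stop("need at least 4 samples", call. = FALSE)
  expr <- check_expr_phen(expr, phen)
  n <- ncol(expr)
  ry <- rank(phen$value)
  rx <- t(apply(expr, 1L, rank))
  sdx <- apply(rx, 1L, stats::sd)
  defined <- sdx > 0 & stats::sd(ry) > 0
  rho <- rep(NA_real_, nrow(expr))
  rho[defined] <- as.vector(stats::cor(t(rx[defined, , drop = FALSE]), ry))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmin(p, 1)
  out <- data.frame(
    gene = rownames(expr),
    statistic = rho,
    p_value = ifelse(defined, p, NA_real_),
    defined = defined,
    platform = platform,
    stringsAsFactors = FALSE
  )
  structure(out, mode = "spearman", class = c("gene_scores", "data.frame"))
}

#' Welch t-test of each gene between two phenotype groups
#'
#' Sign convention: positive statistic means higher expression in
#' `positive_group` (for survival data, set it to the deceased group so
#' that positive evidence means higher activity in the poor-outcome group).
#' Degenerate cases: both groups constant with equal means gives
#' `t = 0, p = 1`; a single constant group is handled by the Welch unequal
#' variance form without blow-up.
#'
#' @param expr numeric matrix, genes x samples.
#' @param phen a `phenotype` whose values are a two-level grouping.
#' @param positive_group label whose higher expression counts as positive;
#'   default: the second factor level.
#' @param platform optional platform tag.
#' @return a `gene_scores` data.frame with attribute `mode = "ttest"`.
#' @export
ttest_scores <- function(expr, phen, positive_group = NULL,
                         platform = NA_character_) {
  grp <- factor(phen$value)
  if (nlevels(grp) != 2L) stop("phenotype must have exactly two groups", call. = FALSE)
  if (any(table(grp) < 2L)) stop("both groups need at least 2 samples", call. = FALSE)
  if (is.null(positive_group)) positive_group <- levels(grp)[2]
  if (!positive_group %in% levels(grp)) {
    stop("positive_group '", positive_group, "' is not a phenotype label",
         call. = FALSE)
  }
  expr <- check_expr_phen(expr, phen)
  x1 <- expr[, grp != positive_group, drop = FALSE]
  x2 <- expr[, grp == positive_group, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  delta <- m2 - m1
  tstat <- ifelse(se2 > 0, delta / sqrt(se2), ifelse(delta == 0, 0, Inf * sign(delta)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  defined <- is.finite(tstat) | delta != 0
  out <- data.frame(
    gene = rownames(expr),
    statistic = tstat,
    p_value = p,
    defined = defined,
    platform = platform,
    stringsAsFactors = FALSE
  )
  structure(out, mode = "ttest", class = c("gene_scores", "data.frame"))
}

one_sided_p <- function(scores, direction) {
  p <- scores$p_value
  s <- scores$statistic
  switch(direction,
    two_sided = p,
    positive = ifelse(s > 0, p / 2, 1 - p / 2),
    negative = ifelse(s < 0, p / 2, 1 - p / 2),
    stop("unknown direction: ", direction, call. = FALSE)
  )
}

#' Select genes at a given false discovery rate
#'
#' Benjamini-Hochberg over the direction-adjusted p-values. For a directional
#' selection the one-sided p-value is `p/2` for genes whose statistic has the
#' concordant sign and `1 - p/2` otherwise, and BH runs over all defined
#' genes.
#'
#' @param scores a `gene_scores` table.
#' @param q FDR level in (0, 1).
#' @param direction `"two_sided"`, `"positive"` or `"negative"`.
#' @return character vector of selected gene ids.
#' @export
fdr_select <- function(scores, q = 0.05,
                       direction = c("two_sided", "positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(q > 0, q < 1)
  keep <- scores$defined & !is.na(scores$p_value)
  if (!any(keep)) return(character(0))
  sub <- scores[keep, , drop = FALSE]
  p1 <- one_sided_p(sub, direction)
  padj <- stats::p.adjust(p1, method = "BH")
  sub$gene[padj <= q]
}

#' Intersect platform selections in a common gene-id space
#'
#' Probe-level selections are mapped through `id_map` and collapsed
#' many-to-one by keeping each gene once (the minimum-p probe determines the
#' gene's presence, so any selected probe selects the gene).
#'
#' @param selA,selB character vectors of selected probe/gene ids.
#' @param id_map optional data.frame with columns `probe`, `gene`; if `NULL`
#'   the ids are assumed to already share a space.
#' @return character vector: the intersection in gene space.
#' @export
intersect_platforms <- function(selA, selB, id_map = NULL) {
  map_ids <- function(ids) {
    if (is.null(id_map)) return(unique(ids))
    unique(id_map$gene[id_map$probe %in% ids])
  }
  sort(intersect(map_ids(selA), map_ids(selB)))
}

#' Collapse probe-level scores to gene level by minimum p
#' @param scores a `gene_scores` table keyed by probe.
#' @param id_map data.frame with columns `probe`, `gene`.
#' @return a `gene_scores` table keyed by gene, each gene carrying its
#'   minimum-p probe's statistic and p-value.
#' @export
collapse_probes <- function(scores, id_map) {
  merged <- merge(scores, id_map, by.x = "gene", by.y = "probe")
  merged <- merged[merged$defined & !is.na(merged$p_value), , drop = FALSE]
  if (nrow(merged) == 0L) return(scores[0, , drop = FALSE])
  best <- do.call(rbind, lapply(split(merged, merged$gene.y), function(d) {
    d[which.min(d$p_value), , drop = FALSE]
  }))
  out <- data.frame(
    gene = best$gene.y,
    statistic = best$statistic,
    p_value = best$p_value,
    defined = TRUE,
    platform = best$platform,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, mode = attr(scores, "mode"),
            class = c("gene_scores", "data.frame"))
}

#' Lift gene scores to per-reaction h-values
#'
#' The h-value of a reaction is `1 - min(one-sided p)` over the scored genes
#' appearing as leaves of its gene-reaction rule (an OR-like, most-permissive
#' aggregation); reactions without any scored gene carry `h = 0` and are
#' flagged unscored. A Fisher combination of the leaf p-values is available
#' as an alternative aggregation.
#'
#' @param scores a `gene_scores` table in the model's gene-id space.
#' @param model a `metabolic_model`.
#' @param direction direction of association counted as evidence (default
#'   `"positive"`: positively growth-correlated / higher-in-deceased).
#' @param aggregate `"min_p"` (default) or `"fisher"`.
#' @return a `reaction_h` data.frame: `reaction_id`, `h`, `scored`,
#'   `contributing_gene`.
#' @export
reaction_h_values <- function(scores, model,
                              direction = c("positive", "negative", "two_sided"),
                              aggregate = c("min_p", "fisher")) {
  direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  keep <- scores$defined & !is.na(scores$p_value)
  p1 <- stats::setNames(one_sided_p(scores, direction), scores$gene)[keep]
  rows <- lapply(model$reactions, function(r) {
    genes <- intersect(gpr_leaves(r$gpr), names(p1))
    if (length(genes) == 0L) {
      return(data.frame(reaction_id = r$id, h = 0, scored = FALSE,
                        contributing_gene = NA_character_,
                        stringsAsFactors = FALSE))
    }
    pg <- p1[genes]
    if (aggregate == "min_p") {
      h <- 1 - min(pg)
      contrib <- genes[which.min(pg)]
    } else {
      stat <- -2 * sum(log(pmax(pg, .Machine$double.xmin)))
      h <- stats::pchisq(stat, df = 2 * length(pg))
      contrib <- genes[which.min(pg)]
    }
    data.frame(reaction_id = r$id, h = h, scored = TRUE,
               contributing_gene = contrib, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("reaction_h", "data.frame"))
}

#' Read an expression matrix from TSV
#'
#' First column = gene id, header = sample ids.
#' @param path TSV path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a phenotype TSV (sample_id, value-or-group)
#' @param path two-column TSV path.
#' @return a `phenotype` data.frame.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  vals <- tab[[2]]
  num <- suppressWarnings(as.numeric(vals))
  if (!anyNA(num)) vals <- num
  phenotype_vector(tab[[1]], vals)
}

#' Write a gene-scores table as TSV
#' @param scores a `gene_scores` table.
#' @param path output path.
#' @param q_levels FDR levels for which selection flags are appended
#'   (two-sided).
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path, q_levels = c(0.01, 0.05)) {
  out <- as.data.frame(scores)
  for (q in q_levels) {
    sel <- fdr_select(scores, q, "two_sided")
    out[[sprintf("q%.2g", q)]] <- out$gene %in% sel
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
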