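# ---- GPR boolean trees -------------------------------------------------------

#' Parse a gene-reaction rule into a boolean expression tree
#'
#' Rules are boolean expressions over gene identifiers with `AND`/`OR`
#' (case-insensitive) and parentheses, e.g. `"(g1 and g2) or g3"`. `AND`
#' encodes an enzyme complex, `OR` isozymes. The tree is a nested list with
#' elements `op` (`"and"`/`"or"`) and `args`; leaves are gene-id strings.
#'
#' @param text rule string; `NA`, `""` or whitespace yields `NULL` (no rule).
#' @return a gpr tree, or `NULL` for an empty rule.
#' @export
#' @examples
#' parse_gpr("(g1 AND g2) OR g3")
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed gene-reaction rule near '", st$toks[st$pos], "': ", text,
         call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed gene-reaction rule: unexpected end", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("malformed gene-reaction rule: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("malformed gene-reaction rule near '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' Gene identifiers appearing in a gpr tree
#' @param tree a gpr tree from [parse_gpr()] (or `NULL`).
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_leaves <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_leaves), use.names = FALSE))
}

#' Evaluate a gpr tree against a set of "on" genes
#' @param tree gpr tree; `NULL` evaluates to `FALSE`.
#' @param on_genes character vector of genes considered present/active.
#' @return logical scalar.
#' @export
gpr_eval <- function(tree, on_genes) {
  if (is.null(tree)) return(FALSE)
  if (is.character(tree)) return(tree %in% on_genes)
  vals <- vapply(tree$args, gpr_eval, logical(1), on_genes = on_genes)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Render a gpr tree back to rule text
#' @param tree gpr tree; `NULL` renders as `""`.
#' @return rule string.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (is.character(a) && length(a) == 1L && !is.list(a)) s else paste0("(", s, ")")
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Test whether two gpr trees are logically equivalent
#'
#' Exhaustive truth-table comparison over the union of leaf genes (feasible
#' because gene-reaction rules are small).
#' @param a,b gpr trees (possibly `NULL`).
#' @return logical scalar.
#' @export
gpr_equivalent <- function(a, b) {
  leaves <- union(gpr_leaves(a), gpr_leaves(b))
  if (length(leaves) == 0L) return(is.null(a) == is.null(b))
  if (length(leaves) > 16L) {
    stop("gpr_equivalent: rule too large for truth-table comparison", call. = FALSE)
  }
  for (mask in 0:(2^length(leaves) - 1L)) {
    on <- leaves[bitwAnd(mask, 2^(seq_along(leaves) - 1L)) > 0L]
    if (gpr_eval(a, on) != gpr_eval(b, on)) return(FALSE)
  }
  TRUE
}

# ---- Reaction equations ------------------------------------------------------

# Parses "2 A[c] + B[c] <=> C[m]" into a signed stoichiometry map plus a
# reversibility flag. Metabolite ids keep their compartment bracket (so the
# same chemical species in two compartments is two metabolites).
parse_reaction_equation <- function(eq, rid = "?") {
  eq <- trimws(eq)
  rev_split <- regmatches(eq, regexpr("<=>|<->|=>|->", eq))
  if (length(rev_split) == 0L) {
    stop("malformed equation for reaction '", rid, "': no arrow in '", eq, "'",
         call. = FALSE)
  }
  reversible <- rev_split %in% c("<=>", "<->")
  sides <- strsplit(eq, "<=>|<->|=>|->")[[1]]
  if (length(sides) > 2L) {
    stop("malformed equation for reaction '", rid, "': multiple arrows", call. = FALSE)
  }
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) == 2L) sides[2] else ""
  stoich <- c(parse_equation_side(lhs, -1, rid), parse_equation_side(rhs, +1, rid))
  if (length(stoich) == 0L) {
    stop("malformed equation for reaction '", rid, "': empty equation", call. = FALSE)
  }
  # net duplicated metabolites, drop exact zeros
  stoich <- vapply(split(unname(stoich), names(stoich)), sum, numeric(1))
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) {
    stop("reaction '", rid, "' has all-zero net stoichiometry", call. = FALSE)
  }
  list(stoichiometry = stoich, reversible = reversible)
}

parse_equation_side <- function(side, sign, rid) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- trimws(strsplit(side, "\\+")[[1]])
  terms <- terms[nzchar(terms)]
  out <- numeric(0)
  for (term in terms) {
    m <- regmatches(term, regexec("^([0-9.]+[[:space:]]+)?([^[:space:]]+)$", term))[[1]]
    if (length(m) == 0L) {
      stop("malformed equation for reaction '", rid, "': bad term '", term, "'",
           call. = FALSE)
    }
    coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    met <- m[3]
    if (!grepl("^.+\\[[^]]+\\]$", met)) {
      stop("malformed equation for reaction '", rid, "': metabolite '", met,
           "' lacks a [compartment] tag", call. = FALSE)
    }
    out <- c(out, stats::setNames(sign * coef, met))
  }
  out
}

met_compartment <- function(met_id) {
  sub("^.+\\[([^]]+)\\]$", "\\1", met_id)
}

met_name <- function(met_id) {
  sub("\\[[^]]+\\]$", "", met_id)
}

# ---- MetabolicModel ----------------------------------------------------------

#' Construct a metabolic model from parsed reactions
#'
#' Builds the validated `metabolic_model` container: a metabolite table, a
#' reaction list, the model gene set, and the sparse stoichiometric matrix `S`
#' (rows = non-boundary metabolites, columns = reactions; compartment tag
#' `"b"` marks boundary metabolites exempt from mass balance).
#'
#' @param reactions list of reaction records, each with fields `id`,
#'   `stoichiometry` (named numeric, metabolite ids with compartment
#'   brackets), `reversible`, `gpr` (tree or `NULL`) and `subsystem`.
#' @param compartments optional declared compartment set; defaults to the
#'   compartments observed in the equations.
#' @return an object of class `metabolic_model`.
#' @export
new_metabolic_model <- function(reactions, compartments = NULL) {
  rids <- vapply(reactions, `[[`, character(1), "id")
  dup <- rids[duplicated(rids)]
  if (length(dup) > 0L) {
    stop("duplicate reaction id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry)),
                           use.names = FALSE))
  comp <- met_compartment(met_ids)
  if (is.null(compartments)) compartments <- unique(comp)
  bad <- unique(comp[!comp %in% compartments])
  if (length(bad) > 0L) {
    stop("unknown compartment tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  metabolites <- data.frame(
    id = met_ids,
    name = met_name(met_ids),
    compartment = comp,
    boundary = comp == "b",
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_leaves(r$gpr)),
                              use.names = FALSE)))
  internal <- metabolites$id[!metabolites$boundary]
  S <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(internal), length(reactions)),
    dimnames = list(internal, rids)
  )
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoichiometry
    keep <- names(st) %in% internal
    if (any(keep)) S[names(st)[keep], k] <- st[keep]
  }
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      genes = genes,
      S = S,
      compartments = compartments
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

validate_model <- function(model) {
  st_sizes <- vapply(model$reactions, function(r) length(r$stoichiometry), integer(1))
  if (any(st_sizes == 0L)) {
    stop("reaction(s) with empty stoichiometry", call. = FALSE)
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids", call. = FALSE)
  }
  for (r in model$reactions) {
    missing <- setdiff(gpr_leaves(r$gpr), model$genes)
    if (length(missing) > 0L) {
      stop("gpr of reaction '", r$id, "' references unknown gene(s)", call. = FALSE)
    }
  }
  invisible(model)
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:",
      length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites",
      sprintf("(%d boundary),", sum(x$metabolites$boundary)),
      length(x$genes), "genes,",
      length(x$compartments), "compartments\n")
  invisible(x)
}

#' Reaction identifiers of a model
#' @param model a `metabolic_model`.
#' @return character vector in model column order.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

#' Read a metabolic model
#'
#' Two formats are supported: `"table"`, a TSV with header columns
#' `reaction_id`, `equation`, `gpr`, `subsystem` and equations such as
#' `"2 A[c] <=> B[c] + C[c]"` (compartment tag `b` marks boundary
#' metabolites); and `"sbml"`, SBML Level 3 with optional `fbc` gene-product
#' associations (species with `boundaryCondition="true"` or in a compartment
#' named/id'd `b`/`boundary` are treated as boundary).
#'
#' @param path file path.
#' @param format `"table"` or `"sbml"`; default guesses from the extension.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "table", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "table"
  }
  if (format == "table") read_model_table(path) else read_model_sbml(path)
}

read_model_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  required <- c("reaction_id", "equation")
  if (!all(required %in% names(tab))) {
    stop("tabular model requires header columns 'reaction_id' and 'equation'",
         call. = FALSE)
  }
  if (!"gpr" %in% names(tab)) tab$gpr <- ""
  if (!"subsystem" %in% names(tab)) tab$subsystem <- ""
  reactions <- lapply(seq_len(nrow(tab)), function(k) {
    rid <- trimws(tab$reaction_id[k])
    parsed <- parse_reaction_equation(tab$equation[k], rid)
    list(
      id = rid,
      stoichiometry = parsed$stoichiometry,
      reversible = parsed$reversible,
      gpr = parse_gpr(tab$gpr[k]),
      subsystem = trimws(tab$subsystem[k])
    )
  })
  new_metabolic_model(reactions)
}

#' Write a metabolic model in the tabular format
#' @param model a `metabolic_model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rows <- lapply(model$reactions, function(r) {
    st <- r$stoichiometry
    fmt <- function(v, ids) {
      paste(ifelse(abs(v) == 1, ids, paste(format(abs(v), trim = TRUE), ids)),
            collapse = " + ")
    }
    lhs <- st[st < 0]
    rhs <- st[st > 0]
    arrow <- if (r$reversible) "<=>" else "=>"
    eq <- paste(
      if (length(lhs)) fmt(abs(lhs), names(lhs)) else "",
      arrow,
      if (length(rhs)) fmt(rhs, names(rhs)) else ""
    )
    data.frame(reaction_id = r$id, equation = trimws(eq),
               gpr = gpr_to_string(r$gpr),
               subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bound <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  boundary <- (!is.na(sp_bound) & sp_bound == "true") |
    tolower(sp_comp) %in% c("b", "boundary")
  comp_of <- stats::setNames(ifelse(boundary, "b", sp_comp), sp_id)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    get_side <- function(which, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:listOf", which, "/s:speciesReference"), ns)
      if (length(refs) == 0L) return(numeric(0))
      sid <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, sid)
    }
    st <- c(get_side("Reactants", -1), get_side("Products", +1))
    if (length(st) == 0L) {
      stop("malformed SBML reaction '", rid, "': no species references", call. = FALSE)
    }
    st <- vapply(split(unname(st), names(st)), sum, numeric(1))
    st <- st[st != 0]
    unknown <- setdiff(names(st), names(comp_of))
    if (length(unknown) > 0L) {
      stop("reaction '", rid, "' references undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    names(st) <- paste0(names(st), "[", comp_of[names(st)], "]")
    gpr_node <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpr_node, "xml_missing")) NULL else sbml_gpr_tree(gpr_node)
    list(id = rid, stoichiometry = st, reversible = rev, gpr = gpr, subsystem = "")
  })
  new_metabolic_model(reactions)
}

sbml_gpr_tree <- function(node) {
  kids <- xml2::xml_children(node)
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    if (is.na(ref)) ref <- xml2::xml_attr(node, "id")
    return(ref)
  }
  if (name %in% c("and", "or")) {
    return(list(op = name, args = lapply(kids, sbml_gpr_tree)))
  }
  # container node (geneProductAssociation): descend into its single child
  if (length(kids) != 1L) {
    stop("malformed fbc gene association", call. = FALSE)
  }
  sbml_gpr_tree(kids[[1]])
}

#' Model summary counts
#' @param model a `metabolic_model`.
#' @param path optional path to also write the summary as JSON.
#' @return named list of counts.
#' @export
model_summary <- function(model, path = NULL) {
  out <- list(
    n_reactions = length(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_boundary_metabolites = sum(model$metabolites$boundary),
    n_genes = length(model$genes),
    n_compartments = length(model$compartments)
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Map a gene set onto reactions through their gpr rules
#'
#' For each reaction, returns the subset of `gene_set` appearing as leaves of
#' its gene-reaction rule (any leaf match counts; complexes and isozymes are
#' not distinguished). Genes in `gene_set` absent from every rule are ignored;
#' their count is reported via a message.
#'
#' @param model a `metabolic_model`.
#' @param gene_set character vector of gene ids.
#' @param quiet suppress the unmatched-gene message.
#' @return named list, reaction id -> character vector of matched genes
#'   (possibly empty).
#' @export
map_genes_to_reactions <- function(model, gene_set, quiet = FALSE) {
  gene_set <- unique(gene_set)
  hits <- lapply(model$reactions, function(r) {
    intersect(gpr_leaves(r$gpr), gene_set)
  })
  names(hits) <- reaction_ids(model)
  matched <- unique(unlist(hits, use.names = FALSE))
  n_unmatched <- length(setdiff(gene_set, matched))
  if (!quiet && n_unmatched > 0L) {
    message(n_unmatched, " of ", length(gene_set),
            " genes matched no reaction gpr")
  }
  hits
}
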