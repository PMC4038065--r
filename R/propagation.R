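#' Build a term -> gene membership index from resolved associations
#'
#' Collapses the association list to set semantics: `members[[t]]` is the set
#' of genes directly annotated to term `t`. Associations differing only in
#' evidence code contribute a single membership; evidence matters only at
#' filter time. The direct membership counts are kept as `provenance` so that
#' the fraction of memberships later created by propagation remains
#' computable.
#'
#' @param assocs An association data.frame, already resolved against the
#'   ontology with [resolve_associations()].
#' @return An object of class `term_gene_index`: a list with `members` (named
#'   list of sorted character vectors) and `provenance` (named integer vector
#'   of direct membership counts).
#' @export
build_index <- function(assocs) {
  if (nrow(assocs) == 0L) {
    return(new_term_gene_index(structure(list(), names = character(0)),
                               structure(integer(0), names = character(0))))
  }
  pairs <- unique(assocs[, c("gene_id", "term_id")])
  members <- lapply(split(pairs$gene_id, pairs$term_id), function(g) sort(g))
  provenance <- lengths(members)
  new_term_gene_index(members, provenance)
}

new_term_gene_index <- function(members, provenance) {
  structure(list(members = members, provenance = provenance),
            class = "term_gene_index")
}

#' @export
print.term_gene_index <- function(x, ...) {
  cat("term-gene index:", length(x$members), "terms,",
      sum(lengths(x$members)), "memberships (",
      sum(x$provenance), "direct )\n")
  invisible(x)
}

#' Propagate gene annotations up the ontology DAG
#'
#' Applies the true-path rule: a gene annotated to a term is implicitly
#' annotated to every ancestor of that term, so each term's member set becomes
#' the union of its direct members and the members of all its descendants
#' through propagating edges. Without this step, gene sets for general terms
#' miss most of their biologically relevant genes, because curators annotate
#' to the most specific applicable term.
#'
#' The traversal is a memoized accumulation in reverse topological order:
#' each term's set is computed exactly once from its children's final sets.
#' Terms that end up with no members are dropped from the index (they could
#' never pass a minimum size filter). Direct-membership provenance is carried
#' through unchanged.
#'
#' @param index A `term_gene_index` from [build_index()].
#' @param dag The `go_dag` the associations were resolved against.
#' @return A post-propagation `term_gene_index`.
#' @export
propagate <- function(index, dag) {
  stopifnot(inherits(index, "term_gene_index"), inherits(dag, "go_dag"))
  stray <- setdiff(names(index$members), names(dag$parents))
  if (length(stray)) {
    validation_error("index contains term(s) absent from the ontology (run ",
                     "resolve_associations() first): ",
                     paste(utils::head(stray, 5), collapse = ", "))
  }
  order <- topological_order(dag$parents)   # parents before children
  children <- invert_parent_map(dag$parents)
  acc <- index$members
  # children first: each term's final set is ready before its parents need it
  for (t in rev(order)) {
    ch <- children[[t]]
    if (is.null(ch)) next
    sets <- acc[ch]
    sets <- sets[!vapply(sets, is.null, logical(1))]
    if (!length(sets)) next
    own <- acc[[t]]
    acc[[t]] <- sort(unique(c(own, unlist(sets, use.names = FALSE))))
  }
  acc <- acc[lengths(acc) > 0L]
  acc <- acc[order(names(acc))]
  prov <- structure(integer(length(acc)), names = names(acc))
  known <- intersect(names(acc), names(index$provenance))
  prov[known] <- index$provenance[known]
  new_term_gene_index(acc, prov)
}

#' Fraction of memberships created by propagation
#'
#' Over all terms in a post-propagation index, the fraction of term-gene
#' memberships that were inferred by propagation rather than stated directly
#' in the association source: `(total - direct) / total`.
#'
#' @param index A post-propagation `term_gene_index`.
#' @return A number in `[0, 1]`, or `NA` (with a warning) for an empty index.
#' @export
propagated_fraction <- function(index) {
  stopifnot(inherits(index, "term_gene_index"))
  total <- sum(lengths(index$members))
  if (total == 0L) {
    warning("empty index: propagated fraction is undefined", call. = FALSE)
    return(NA_real_)
  }
  direct <- sum(index$provenance)
  (total - direct) / total
}
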