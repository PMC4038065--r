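#' Filter a term-gene index by set size
#'
#' Retains exactly the terms whose member count lies within the inclusive
#' bounds. The minimum cut-off removes very small sets that could never reach
#' statistical significance in a set-based test; the maximum removes terms so
#' general that a significant result would be uninformative. The defaults
#' (10 and 700) are the conventional bounds for GO-derived GSEA collections.
#'
#' @param index A `term_gene_index` (normally post-propagation).
#' @param min_size,max_size Inclusive bounds on gene-set size.
#' @return The filtered `term_gene_index`.
#' @export
size_filter <- function(index, min_size = 10L, max_size = 700L) {
  stopifnot(inherits(index, "term_gene_index"))
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (is.na(min_size) || is.na(max_size) || min_size < 1L) {
    config_error("size bounds must be positive integers")
  }
  if (min_size > max_size) {
    config_error("min_size (", min_size, ") exceeds max_size (", max_size, ")")
  }
  sz <- lengths(index$members)
  keep <- sz >= min_size & sz <= max_size
  kept <- names(index$members)[keep]
  prov <- structure(integer(length(kept)), names = kept)
  known <- intersect(kept, names(index$provenance))
  prov[known] <- index$provenance[known]
  new_term_gene_index(index$members[keep], prov)
}

#' Default URL template for representative terms
#'
#' The representative term accession is substituted for `%s` (AmiGO term page
#' by default).
#' @export
go_term_url_template <- function() {
  "http://amigo.geneontology.org/amigo/term/%s"
}

#' Collapse terms with identical gene content into single gene sets
#'
#' GO-derived collections inevitably contain multiple terms with identical
#' propagated gene membership (typically a parent whose only annotated child
#' carries all its genes). Duplicate sets distort the false discovery rate
#' estimate of set-based tests, so each distinct gene content is emitted once.
#' Unlike collections that silently discard the duplicates, every contributing
#' term is retained in the set's `all_terms` (and hence in its output
#' description), so an analyst can see that e.g. a significant parent term is
#' content-identical to one specific child. The representative term - the one
#' the set is named after and whose URL is emitted - is the term with the
#' smallest depth, i.e. the most general of the terms; ties are broken by
#' lexicographically smallest accession so the choice is deterministic.
#'
#' @param index A size-filtered, post-propagation `term_gene_index`.
#' @param depths A `term_depths` vector from [compute_depths()].
#' @param dag The `go_dag` (source of term names).
#' @param url_template Template with `%s` substituted by the representative
#'   accession.
#' @return A list of `gene_set` objects, ordered by representative accession.
#'   Each has `set_name` (upper-case, underscore-separated, collision-unique),
#'   `genes` (sorted unique), `all_terms` (data.frame term_id/name/depth
#'   ordered by depth then accession), `representative` and `url`.
#' @export
collapse_duplicates <- function(index, depths, dag,
                                url_template = go_term_url_template()) {
  stopifnot(inherits(index, "term_gene_index"), inherits(dag, "go_dag"))
  term_ids <- names(index$members)
  if (!length(term_ids)) return(list())
  miss <- setdiff(term_ids, names(depths))
  if (length(miss)) {
    validation_error("term(s) missing from the depth map: ",
                     paste(utils::head(miss, 5), collapse = ", "))
  }
  name_by_id <- dag$terms$name
  names(name_by_id) <- dag$terms$term_id

  key <- vapply(index$members, paste, character(1), collapse = "\r")
  groups <- split(term_ids, key[term_ids])
  sets <- lapply(groups, function(tids) {
    d <- as.integer(depths[tids])
    ord <- order(d, tids)
    tids <- tids[ord]
    d <- d[ord]
    all_terms <- data.frame(term_id = tids,
                            name = unname(name_by_id[tids]),
                            depth = d,
                            row.names = NULL, stringsAsFactors = FALSE)
    rep_id <- tids[1L]
    structure(
      list(set_name = NA_character_,   # assigned after collision handling
           genes = index$members[[rep_id]],
           all_terms = all_terms,
           representative = list(term_id = rep_id,
                                 name = unname(name_by_id[[rep_id]]),
                                 depth = d[1L]),
           url = sprintf(url_template, rep_id)),
      class = "gene_set")
  })
  # deterministic output order: by representative accession
  reps <- vapply(sets, function(s) s$representative$term_id, character(1))
  sets <- sets[order(reps)]
  raw <- vapply(sets, function(s) make_set_name(s$representative$name),
                character(1))
  final <- disambiguate_names(raw)
  for (i in seq_along(sets)) sets[[i]]$set_name <- final[[i]]
  unname(sets)
}

# MSigDB c5-style naming: uppercase, runs of non-alphanumerics -> one
# underscore; later collisions get suffixes _2, _3, ...
make_set_name <- function(name) {
  x <- toupper(name)
  x <- gsub("[^A-Z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x)) x <- "UNNAMED"
  x
}

disambiguate_names <- function(x) {
  out <- x
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(x)) {
    base <- x[[i]]
    k <- if (exists(base, envir = seen, inherits = FALSE)) {
      get(base, envir = seen, inherits = FALSE) + 1L
    } else 1L
    assign(base, k, envir = seen)
    if (k > 1L) out[[i]] <- paste0(base, "_", k)
  }
  out
}

#' Format the description field of a gene set
#'
#' Enumerates every GO term sharing the set's exact gene content, each with
#' its distance from the namespace root appended as a specificity level:
#' entries `"GO:NNNNNNN term name [level D]"` joined by `"|"`.
#'
#' @param set A `gene_set`.
#' @return A single description string.
#' @export
format_description <- function(set) {
  stopifnot(inherits(set, "gene_set"))
  at <- set$all_terms
  paste(sprintf("%s %s [level %d]", at$term_id, at$name, at$depth),
        collapse = "|")
}

#' Construct a gene set collection
#'
#' @param sets List of `gene_set` objects (from [collapse_duplicates()]).
#' @param params Named list recording the run configuration, kept for
#'   provenance.
#' @param warnings Named integer vector of resolution counters.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, params = list(),
                               warnings = c(synonym = 0L, obsolete = 0L,
                                            unknown = 0L)) {
  stopifnot(is.list(sets))
  keys <- vapply(sets, function(s) paste(s$genes, collapse = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    validation_error("collection contains sets with identical gene content")
  }
  nm <- vapply(sets, `[[`, character(1), "set_name")
  if (anyDuplicated(nm)) {
    validation_error("collection contains duplicate set names: ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(list(sets = sets, params = params, warnings = warnings),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  n <- length(x$sets)
  cat("gene set collection:", n, "sets")
  if (n) {
    sz <- vapply(x$sets, function(s) length(s$genes), integer(1))
    cat(", sizes", min(sz), "-", max(sz),
        sprintf("(mean %.1f)", mean(sz)))
  }
  cat("\n")
  invisible(x)
}

gmt_second_field <- function(set, style = c("url_and_terms", "url_only")) {
  style <- match.arg(style)
  if (style == "url_only") set$url
  else paste(set$url, format_description(set))
}

#' Write a collection in MSigDB .gmt format
#'
#' One set per line: set name, a description field, then the gene
#' identifiers, all tab-separated, UNIX newlines, UTF-8. The gmt format
#' allows a single free-text description field; to retain both the
#' representative term's URL and the full term list it is emitted as
#' `"URL<space>description"` by default. `description = "url_only"` emits the
#' bare URL for strict MSigDB mimicry.
#'
#' @param collection A `geneset_collection`.
#' @param path Output file path or writable connection.
#' @param description `"url_and_terms"` (default) or `"url_only"`.
#' @return The path (or connection), invisibly.
#' @export
write_gmt <- function(collection, path,
                      description = c("url_and_terms", "url_only")) {
  stopifnot(inherits(collection, "geneset_collection"))
  description <- match.arg(description)
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$set_name, gmt_second_field(s, description), s$genes),
          collapse = "\t")
  }, character(1))
  write_text_lines(lines, path)
  invisible(path)
}

#' Write a collection in MSigDB .gmx format
#'
#' The transpose of .gmt: one set per column. Row 1 holds set names, row 2
#' the description fields, subsequent rows the genes; shorter columns are
#' padded with empty fields so every row has one field per set.
#'
#' @inheritParams write_gmt
#' @export
write_gmx <- function(collection, path,
                      description = c("url_and_terms", "url_only")) {
  stopifnot(inherits(collection, "geneset_collection"))
  description <- match.arg(description)
  sets <- collection$sets
  cols <- lapply(sets, function(s) {
    c(s$set_name, gmt_second_field(s, description), s$genes)
  })
  if (!length(cols)) {
    write_text_lines(character(0), path)
    return(invisible(path))
  }
  n_rows <- max(lengths(cols))
  padded <- lapply(cols, function(x) c(x, rep("", n_rows - length(x))))
  mat <- do.call(cbind, padded)
  lines <- apply(mat, 1L, paste, collapse = "\t")
  write_text_lines(lines, path)
  invisible(path)
}

# UNIX newlines and UTF-8 regardless of platform
write_text_lines <- function(lines, path) {
  con <- if (inherits(path, "connection")) path else {
    f <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) e)
    if (inherits(f, "error")) {
      io_error("cannot open '", path, "' for writing: ", conditionMessage(f))
    }
    on.exit(close(f))
    f
  }
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
}
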