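#' Parse a Gene Ontology OBO flat file into a queryable DAG
#'
#' Reads OBO format 1.2 `[Term]` stanzas and builds a directed acyclic graph
#' in which each current term points to its parents via the propagating
#' relationships in `relations`. Obsolete terms and synonymous accessions
#' (`alt_id` lines) are recorded separately so that annotation sources built
#' against older ontology releases can be resolved with [resolve_term()].
#'
#' Only `is_a` and `part_of` edges propagate gene annotations by default;
#' `regulates`-type relationships are deliberately not followed, matching the
#' convention of the GO true-path rule. The relationship allow-list is
#' configurable via `relations`.
#'
#' @param obo Path to an OBO 1.2 file, a connection, or a character vector of
#'   lines (taken as the file content when it has length > 1 or contains a
#'   newline).
#' @param relations Character vector of relationship types treated as parent
#'   (propagating) edges. `"is_a"` refers to the dedicated `is_a:` tag; other
#'   entries match `relationship:` lines.
#' @return An object of class `go_dag`: a list with components
#'   \describe{
#'     \item{terms}{data.frame of current terms: `term_id`, `name`, `namespace`.}
#'     \item{parents}{named list mapping each current `term_id` to its parent
#'       accessions.}
#'     \item{alt_ids}{named character vector mapping synonymous accessions to
#'       the preferred accession.}
#'     \item{obsolete}{character vector of obsolete accessions.}
#'     \item{replaced_by}{named character vector giving the single designated
#'       replacement for those obsolete terms that have exactly one.}
#'     \item{roots}{named character vector, one root accession per namespace.}
#'   }
#' @examples
#' obo <- c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
#'   "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root"
#' )
#' dag <- parse_obo(obo)
#' dag$parents[["GO:0000002"]]
#' @export
parse_obo <- function(obo, relations = c("is_a", "part_of")) {
  lines <- read_input_lines(obo)
  stanzas <- split_obo_stanzas(lines)
  n <- length(stanzas)
  if (n == 0L) {
    parse_error("no [Term] stanzas found in OBO input")
  }

  ids <- character(n)
  names_ <- character(n)
  namespaces <- character(n)
  obsolete <- logical(n)
  replaced <- vector("list", n)
  parents <- vector("list", n)
  alt_pairs <- list()

  for (i in seq_len(n)) {
    st <- stanzas[[i]]
    tags <- st$tags
    vals <- st$values
    id <- vals[tags == "id"]
    if (length(id) == 0L || !nzchar(id[1])) {
      parse_error("malformed [Term] stanza starting at line ", st$line,
                  ": missing 'id' tag")
    }
    ids[i] <- id[1]
    nm <- vals[tags == "name"]
    names_[i] <- if (length(nm)) nm[1] else ""
    ns <- vals[tags == "namespace"]
    namespaces[i] <- if (length(ns)) ns[1] else ""
    obsolete[i] <- any(tags == "is_obsolete" & tolower(vals) == "true")
    replaced[[i]] <- vals[tags == "replaced_by"]

    par <- character(0)
    if ("is_a" %in% relations) {
      par <- c(par, first_token(vals[tags == "is_a"]))
    }
    rel <- vals[tags == "relationship"]
    if (length(rel)) {
      rel_parts <- strsplit(trimws(rel), "[[:space:]]+")
      for (rp in rel_parts) {
        if (length(rp) >= 2 && rp[1] %in% setdiff(relations, "is_a")) {
          par <- c(par, rp[2])
        }
      }
    }
    parents[[i]] <- unique(par)

    alts <- vals[tags == "alt_id"]
    alts <- alts[nzchar(alts)]
    if (length(alts)) {
      alt_pairs[[length(alt_pairs) + 1L]] <-
        cbind(alt = alts, preferred = id[1])
    }
  }

  if (anyDuplicated(ids)) {
    parse_error("duplicate term id(s) in OBO input: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  current <- !obsolete
  # obsolete terms carry no parent edges by definition
  parents[obsolete] <- list(character(0))

  term_ids <- ids[current]
  parent_map <- parents[current]
  names(parent_map) <- term_ids

  # replaced_by: a single target is honoured; multiple targets (or none)
  # leave the term obsolete-without-replacement
  repl <- vapply(replaced, function(x) {
    if (length(x) == 1L) x else NA_character_
  }, character(1))
  replaced_by <- repl[obsolete & !is.na(repl)]
  names(replaced_by) <- ids[obsolete & !is.na(repl)]

  alt_ids <- character(0)
  if (length(alt_pairs)) {
    am <- do.call(rbind, alt_pairs)
    if (anyDuplicated(am[, "alt"])) {
      parse_error("alt_id accession(s) claimed by multiple terms: ",
                  paste(unique(am[duplicated(am[, "alt"]), "alt"]),
                        collapse = ", "))
    }
    alt_ids <- am[, "preferred"]
    names(alt_ids) <- am[, "alt"]
  }

  # current ids, alt ids and obsolete ids must be pairwise disjoint
  obsolete_ids <- ids[obsolete]
  overlap <- c(
    intersect(names(alt_ids), term_ids),
    intersect(names(alt_ids), obsolete_ids)
  )
  if (length(overlap)) {
    validation_error("accession(s) used both as alt_id and as a stanza id: ",
                     paste(unique(overlap), collapse = ", "))
  }

  # every parent must be a current term
  all_parents <- unique(unlist(parent_map, use.names = FALSE))
  missing <- setdiff(all_parents, term_ids)
  if (length(missing)) {
    validation_error("parent accession(s) not defined as current terms: ",
                     paste(missing, collapse = ", "))
  }

  ns_by_id <- namespaces[current]
  names(ns_by_id) <- term_ids
  # part_of (any relationship) edges must stay within one namespace
  for (t in term_ids) {
    ps <- parent_map[[t]]
    bad <- ps[ns_by_id[ps] != ns_by_id[[t]]]
    if (length(bad)) {
      validation_error("parent edge crosses namespaces: ", t, " (",
                       ns_by_id[[t]], ") -> ", bad[1], " (", ns_by_id[bad[1]],
                       ")")
    }
  }

  cyc <- find_cycle(parent_map)
  if (!is.null(cyc)) {
    validation_error("parent relationships contain a cycle: ",
                     paste(cyc, collapse = " -> "))
  }

  root_ids <- term_ids[lengths(parent_map) == 0L]
  roots <- character(0)
  for (ns in unique(ns_by_id)) {
    r <- root_ids[ns_by_id[root_ids] == ns]
    if (length(r) != 1L) {
      validation_error("namespace '", ns, "' has ", length(r),
                       " parentless terms; expected exactly one root")
    }
    roots[ns] <- r
  }

  structure(
    list(
      terms = data.frame(term_id = term_ids, name = names_[current],
                         namespace = ns_by_id, row.names = NULL,
                         stringsAsFactors = FALSE),
      parents = parent_map,
      alt_ids = alt_ids,
      obsolete = obsolete_ids,
      replaced_by = replaced_by,
      roots = roots,
      relations = relations
    ),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO ontology DAG\n")
  cat("  current terms:", nrow(x$terms), "\n")
  cat("  namespaces:   ", paste(names(x$roots), collapse = ", "), "\n")
  cat("  alt_ids:      ", length(x$alt_ids), "\n")
  cat("  obsolete:     ", length(x$obsolete), "\n")
  invisible(x)
}

#' Resolve a GO accession against the ontology
#'
#' Maps an accession to the preferred current accession, following `alt_id`
#' synonym lines. Obsolete accessions (including synonyms whose preferred
#' accession is itself obsolete) are reported as such, and accessions entirely
#' absent from the ontology as unknown. All outcomes are in-band results, not
#' errors, because association sources routinely lag the ontology release.
#'
#' @param dag A `go_dag` from [parse_obo()].
#' @param accession A single GO accession string. Surrounding whitespace is
#'   trimmed; comparison is case-sensitive.
#' @return A list with `status` (one of `"current"`, `"obsolete"`,
#'   `"unknown"`) and `term_id` (the preferred accession for `"current"`,
#'   otherwise `NA`).
#' @export
resolve_term <- function(dag, accession) {
  stopifnot(inherits(dag, "go_dag"), is.character(accession),
            length(accession) == 1L)
  acc <- trimws(accession)
  if (acc %in% names(dag$parents)) {
    return(list(status = "current", term_id = acc))
  }
  if (acc %in% names(dag$alt_ids)) {
    pref <- unname(dag$alt_ids[[acc]])
    if (pref %in% dag$obsolete) {
      return(list(status = "obsolete", term_id = NA_character_))
    }
    return(list(status = "current", term_id = pref))
  }
  if (acc %in% dag$obsolete) {
    return(list(status = "obsolete", term_id = NA_character_))
  }
  list(status = "unknown", term_id = NA_character_)
}

#' Compute the depth (level) of every current term
#'
#' Depth is the edge count of the shortest path from a term to the root of its
#' namespace, following parent edges. It is reported in output descriptions as
#' a rough guide to term specificity: the root has depth 0 and terms become
#' more specific as depth grows.
#'
#' @param dag A `go_dag`.
#' @return A named integer vector (class `term_depths`) mapping every current
#'   `term_id` to its depth. Satisfies `depth[root] == 0` and, for every
#'   non-root term, `depth[t] == 1 + min(depth[parents(t)])`.
#' @export
compute_depths <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  order <- topological_order(dag$parents)
  depth <- rep(NA_integer_, length(order))
  names(depth) <- order
  for (t in order) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) {
      depth[[t]] <- 0L
    } else {
      pd <- depth[ps]
      if (anyNA(pd)) {
        validation_error("term has no path to a namespace root: ", t)
      }
      depth[[t]] <- 1L + min(pd)
    }
  }
  if (anyNA(depth)) {
    validation_error("term has no path to a namespace root: ",
                     names(depth)[which(is.na(depth))[1]])
  }
  structure(depth, class = "term_depths")
}

CACHE_FORMAT <- "gosets-dag-cache"
CACHE_VERSION <- 1L

#' Cache a parsed ontology for repeat runs
#'
#' Parsing a full GO release takes far longer than the downstream set
#' construction, so the parsed DAG can be written to a versioned cache file
#' and reloaded on subsequent runs. A cache written by a different format
#' version, or a corrupt file, raises an explicit error instructing a
#' re-parse; there is never a silent fallback to partial data.
#'
#' @param dag A `go_dag`.
#' @param path Cache file path.
#' @return `cache_dag()` returns `path` invisibly; `load_cached()` returns the
#'   `go_dag` exactly as cached.
#' @export
cache_dag <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  ok <- tryCatch({
    saveRDS(list(format = CACHE_FORMAT, version = CACHE_VERSION, dag = dag),
            path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    io_error("cannot write ontology cache to '", path, "': ",
             conditionMessage(ok))
  }
  invisible(path)
}

#' @rdname cache_dag
#' @export
load_cached <- function(path) {
  if (!file.exists(path)) {
    io_error("ontology cache '", path, "' does not exist")
  }
  obj <- tryCatch(readRDS(path), error = function(e) e)
  if (inherits(obj, "error") || !is.list(obj) ||
      !identical(obj$format, CACHE_FORMAT)) {
    validation_error("ontology cache '", path,
                     "' is corrupt or not a gosets cache; ",
                     "delete it and re-parse the OBO file")
  }
  if (!identical(obj$version, CACHE_VERSION)) {
    validation_error("ontology cache '", path, "' was written by format ",
                     "version ", obj$version, " but this build reads version ",
                     CACHE_VERSION, "; delete it and re-parse the OBO file")
  }
  if (!inherits(obj$dag, "go_dag")) {
    validation_error("ontology cache '", path,
                     "' does not contain a DAG; delete it and re-parse")
  }
  obj$dag
}

# ---- internal helpers -------------------------------------------------------

read_input_lines <- function(x) {
  if (inherits(x, "connection")) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE)) {
    if (!file.exists(x)) {
      io_error("input file '", x, "' does not exist")
    }
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x)) {
    out <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
    return(if (is.null(out)) character(0) else out)
  }
  parse_error("unsupported input: expected a path, connection or lines")
}

# Split OBO lines into [Term] stanzas; each stanza keeps its starting line
# number for error reporting, its tags and its values (with trailing
# "! comment" stripped).
split_obo_stanzas <- function(lines) {
  stanzas <- list()
  in_term <- FALSE
  cur_tags <- character(0)
  cur_vals <- character(0)
  cur_line <- 0L
  flush <- function() {
    if (in_term) {
      stanzas[[length(stanzas) + 1L]] <<-
        list(line = cur_line, tags = cur_tags, values = cur_vals)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(trimws(ln), "[Term]")
      cur_tags <- character(0)
      cur_vals <- character(0)
      cur_line <- i
      next
    }
    if (!in_term || !nzchar(trimws(ln))) next
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) {
      parse_error("malformed OBO line ", i, ": '", ln, "' (no tag separator)")
    }
    tag <- trimws(substr(ln, 1L, m - 1L))
    val <- substr(ln, m + 1L, nchar(ln))
    val <- sub("\\s*!.*$", "", val)   # strip trailing OBO comment
    cur_tags <- c(cur_tags, tag)
    cur_vals <- c(cur_vals, trimws(val))
  }
  flush()
  stanzas
}

first_token <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(trimws(x), "[[:space:]]+"), `[[`, character(1), 1L)
}

# Kahn's algorithm over the child -> parents map; returns term ids with every
# parent preceding its children, or raises on a cycle.
topological_order <- function(parent_map) {
  ids <- names(parent_map)
  indeg <- lengths(parent_map)
  children <- invert_parent_map(parent_map)
  queue <- ids[indeg == 0L]
  out <- character(length(ids))
  k <- 0L
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    k <- k + 1L
    out[k] <- t
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < length(ids)) {
    validation_error("parent relationships contain a cycle among: ",
                     paste(utils::head(setdiff(ids, out[seq_len(k)]), 10),
                           collapse = ", "))
  }
  out
}

invert_parent_map <- function(parent_map) {
  children <- vector("list", length(parent_map))
  names(children) <- names(parent_map)
  for (t in names(parent_map)) {
    for (p in parent_map[[t]]) {
      children[[p]] <- c(children[[p]], t)
    }
  }
  children
}

# Depth-first search for one cycle; returns the cycle path or NULL.
find_cycle <- function(parent_map) {
  color <- new.env(parent = emptyenv())
  stack <- character(0)
  result <- NULL
  visit <- function(t) {
    if (!is.null(result)) return()
    assign(t, 1L, envir = color)
    stack <<- c(stack, t)
    for (p in parent_map[[t]]) {
      st <- if (exists(p, envir = color, inherits = FALSE)) {
        get(p, envir = color, inherits = FALSE)
      } else 0L
      if (st == 1L) {
        i <- match(p, stack)
        result <<- c(stack[i:length(stack)], p)
        return()
      }
      if (st == 0L) visit(p)
      if (!is.null(result)) return()
    }
    stack <<- stack[-length(stack)]
    assign(t, 2L, envir = color)
  }
  for (t in names(parent_map)) {
    st <- if (exists(t, envir = color, inherits = FALSE)) {
      get(t, envir = color, inherits = FALSE)
    } else 0L
    if (st == 0L) visit(t)
    if (!is.null(result)) break
  }
  result
}
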