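# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code.

# All ancestors of term t by exhaustive upward walk (no memoization shared
# with the implementation's reverse-topological accumulation).
oracle_ancestors <- function(dag, t, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[t]])) return(cache[[t]])
  out <- character(0)
  frontier <- dag$parents[[t]]
  while (length(frontier)) {
    p <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (!(p %in% out)) {
      out <- c(out, p)
      frontier <- c(frontier, dag$parents[[p]])
    }
  }
  if (!is.null(cache)) cache[[t]] <- out
  out
}

# Brute-force propagation: for every (gene, term) pair, add the gene to the
# term and every ancestor of the term.
oracle_propagate <- function(assocs, dag) {
  cache <- new.env(parent = emptyenv())
  acc <- new.env(parent = emptyenv())
  pairs <- unique(assocs[, c("gene_id", "term_id")])
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]
    t <- pairs$term_id[i]
    for (tt in c(t, oracle_ancestors(dag, t, cache))) {
      acc[[tt]] <- c(acc[[tt]], g)
    }
  }
  out <- lapply(as.list(acc), function(x) sort(unique(x)))
  out[order(names(out))]
}

# Breadth-first-search depth oracle: expand children level by level from each
# namespace root.
oracle_depths <- function(dag) {
  children <- list()
  for (t in names(dag$parents)) {
    for (p in dag$parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  depth <- integer(0)
  for (root in dag$roots) {
    level <- 0L
    frontier <- root
    while (length(frontier)) {
      new <- setdiff(frontier, names(depth))
      depth[new] <- level
      frontier <- unique(unlist(children[frontier], use.names = FALSE))
      frontier <- setdiff(frontier, names(depth))
      level <- level + 1L
    }
  }
  depth
}

# Test-only readers recovering a collection's content from its serialized
# forms.
read_gmt_lines <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    list(set_name = f[1], field2 = f[2], genes = f[-(1:2)])
  })
}

read_gmx_lines <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(list())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- max(lengths(rows))
  rows <- lapply(rows, function(r) c(r, rep("", n_col - length(r))))
  mat <- do.call(rbind, rows)
  lapply(seq_len(n_col), function(j) {
    col <- mat[, j]
    genes <- col[-(1:2)]
    list(set_name = col[1], field2 = col[2], genes = genes[nzchar(genes)])
  })
}

# Inverse of format_description(): recovers (term_id, name, depth).
parse_description <- function(desc) {
  entries <- strsplit(desc, "|", fixed = TRUE)[[1]]
  m <- regmatches(entries,
                  regexec("^(GO:[0-9]{7}) (.*) \\[level ([0-9]+)\\]$", entries))
  stopifnot(all(lengths(m) == 4L))
  data.frame(term_id = vapply(m, `[[`, character(1), 2L),
             name = vapply(m, `[[`, character(1), 3L),
             depth = as.integer(vapply(m, `[[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

assoc_key <- function(df) {
  sort(paste(df$gene_id, df$term_id,
             ifelse(is.na(df$evidence), "", df$evidence), sep = "\r"))
}

# Small hand-rolled OBO used across tests.
tiny_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: middle",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "alt_id: GO:0000010", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000009", "name: obsolete leaf",
    "namespace: biological_process", "is_obsolete: true",
    "replaced_by: GO:0000003", "")
}
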