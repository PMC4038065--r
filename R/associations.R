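#' @title Gene-GO association records
#' @description Associations are plain data.frames with columns `gene_id`
#'   (character, non-empty), `term_id` (GO accession) and `evidence` (GO
#'   evidence code, or `NA` for sources that carry none, such as array
#'   annotation files). Readers attach an `accounting` attribute recording how
#'   many input rows were emitted, skipped as malformed, or excluded by
#'   taxon/qualifier filters.
#' @name associations
NULL

# strsplit() drops a trailing empty field ("a\t" -> "a"); pad back so rows
# ending in empty columns keep their true arity
split_tsv <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_true <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  Map(function(f, n) c(f, rep("", n - length(f))), fields, n_true)
}

new_associations <- function(gene_id, term_id, evidence) {
  df <- data.frame(gene_id = as.character(gene_id),
                   term_id = as.character(term_id),
                   evidence = as.character(evidence),
                   row.names = NULL, stringsAsFactors = FALSE)
  # duplicate-free per (gene, term, evidence)
  key <- paste(df$gene_id, df$term_id, ifelse(is.na(df$evidence), "",
                                              df$evidence), sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read gene-GO associations from an NCBI gene2go table
#'
#' The gene2go table links Entrez Gene IDs to GO accessions with evidence
#' codes, for every taxon NCBI curates. Rows are filtered to the requested
#' taxon; rows whose Qualifier asserts `NOT` (non-membership) are excluded,
#' since propagating a negated annotation would poison ancestor sets.
#'
#' gene2go carries no gene symbol column: the gene identifier is always the
#' Entrez Gene ID. To obtain symbol-keyed sets, supply an Entrez-to-symbol
#' translation via [apply_id_map()].
#'
#' @param src Path, connection or character lines of a tab-separated table
#'   with columns tax_id, GeneID, GO_ID, Evidence, Qualifier, GO_term,
#'   PubMed, Category; lines beginning `#` are comments/header.
#' @param taxon Numeric or string NCBI taxon ID to keep.
#' @param id_choice `"entrez_id"` (the only identifier gene2go provides).
#'   Requesting `"symbol"` warns and falls back to the Entrez ID.
#' @return An association data.frame (see [associations]).
#' @export
read_gene2go <- function(src, taxon, id_choice = c("entrez_id", "symbol")) {
  id_choice <- match.arg(id_choice)
  if (id_choice == "symbol") {
    warning("gene2go carries no gene symbol; using Entrez Gene IDs. ",
            "Supply an Entrez-to-symbol file via apply_id_map() for symbols.",
            call. = FALSE)
  }
  if (missing(taxon) || is.null(taxon)) {
    config_error("read_gene2go() requires a taxon ID")
  }
  taxon <- as.character(taxon)

  lines <- read_input_lines(src)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- split_tsv(lines)
  bad <- lengths(fields) != 8L
  if (any(bad)) {
    warning(sum(bad), " gene2go row(s) skipped: expected 8 tab-separated ",
            "columns", call. = FALSE)
  }
  fields <- fields[!bad]

  skipped <- sum(bad)
  excluded <- 0L
  keep <- list()
  for (f in fields) {
    if (f[1] != taxon || grepl("\\bNOT\\b", f[5])) {
      excluded <- excluded + 1L
      next
    }
    keep[[length(keep) + 1L]] <- f
  }
  emitted <- length(keep)
  if (emitted == 0L) {
    warning("no gene2go associations found for taxon ", taxon, call. = FALSE)
    out <- new_associations(character(0), character(0), character(0))
  } else {
    m <- do.call(rbind, keep)
    out <- new_associations(m[, 2], m[, 3], m[, 4])
  }
  attr(out, "accounting") <- c(rows = length(fields) + skipped,
                               emitted = emitted, skipped = skipped,
                               excluded = excluded)
  out
}

#' Read gene-GO associations from a GAF 2.x annotation file
#'
#' GAF is the flat-file dialect of the GO association database: 17
#' tab-separated columns with `!`-prefixed comments. The gene identifier is
#' either the DB object symbol (column 3) or the DB object ID (column 2), as
#' chosen by the user. Rows whose qualifier contains `NOT` are excluded.
#'
#' @param src Path, connection or character lines.
#' @param taxon Optional NCBI taxon ID; when given, rows are kept only if the
#'   first taxon in column 13 (`taxon:NNNN`) matches.
#' @param id_choice `"symbol"` (column 3) or `"object_id"` (column 2).
#' @return An association data.frame (see [associations]).
#' @export
read_gaf <- function(src, taxon = NULL, id_choice = c("symbol", "object_id")) {
  id_choice <- match.arg(id_choice)
  gene_col <- if (id_choice == "symbol") 3L else 2L
  taxon <- if (is.null(taxon)) NULL else as.character(taxon)

  lines <- read_input_lines(src)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- split_tsv(lines)
  bad <- lengths(fields) != 17L
  if (any(bad)) {
    warning(sum(bad), " GAF row(s) skipped: expected 17 tab-separated ",
            "columns", call. = FALSE)
  }
  fields <- fields[!bad]
  skipped <- sum(bad)
  excluded <- 0L
  unparseable_taxon <- 0L
  keep <- list()
  for (f in fields) {
    if (grepl("\\bNOT\\b", f[4])) {
      excluded <- excluded + 1L
      next
    }
    row_taxon <- sub("^taxon:", "",
                     strsplit(f[13], "|", fixed = TRUE)[[1]][1])
    taxon_ok <- grepl("^[0-9]+$", row_taxon)
    if (!taxon_ok) unparseable_taxon <- unparseable_taxon + 1L
    if (!is.null(taxon)) {
      if (!taxon_ok || row_taxon != taxon) {
        excluded <- excluded + 1L
        next
      }
    }
    keep[[length(keep) + 1L]] <- f
  }
  if (unparseable_taxon > 0L) {
    warning(unparseable_taxon, " GAF row(s) had an unparseable taxon field",
            if (!is.null(taxon)) " and were excluded by the taxon filter",
            call. = FALSE)
  }
  emitted <- length(keep)
  if (emitted == 0L) {
    out <- new_associations(character(0), character(0), character(0))
  } else {
    m <- do.call(rbind, keep)
    out <- new_associations(m[, gene_col], m[, 5], m[, 7])
  }
  attr(out, "accounting") <- c(rows = length(fields) + skipped,
                               emitted = emitted, skipped = skipped,
                               excluded = excluded)
  out
}

AFFY_GO_COLUMNS <- c("Gene Ontology Biological Process",
                     "Gene Ontology Molecular Function",
                     "Gene Ontology Cellular Component")

#' Read gene-GO associations from an array annotation file
#'
#' Supports two manufacturer dialects. The Affymetrix (NetAffx) dialect is a
#' quoted CSV with `#`-prefixed header comments, a `Probe Set ID` column and
#' three Gene Ontology columns whose cells hold `///`-separated entries of the
#' form `"<numeric id> // <term name> // <evidence>"`; the NetAffx null marker
#' is `---`. The Agilent dialect is tab-separated with a GO column of
#' `|`-separated `GO:NNNNNNN(term name)` entries and carries no evidence
#' codes. Numeric GO ids are zero-padded to 7 digits and prefixed `GO:`.
#'
#' @param src Path, connection or character lines.
#' @param dialect `"affymetrix"` or `"agilent"`.
#' @param probe_col Probe identifier column name; defaults to
#'   `"Probe Set ID"` (affymetrix) or `"ProbeID"` (agilent).
#' @param go_cols GO column name(s); defaults to the three NetAffx Gene
#'   Ontology columns (affymetrix) or `"GO"` (agilent).
#' @return An association data.frame keyed by probe ID; `evidence` is `NA`
#'   for the Agilent dialect.
#' @export
read_array_annotation <- function(src, dialect = c("affymetrix", "agilent"),
                                  probe_col = NULL, go_cols = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_input_lines(src)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) {
    parse_error("array annotation input is empty")
  }

  if (dialect == "affymetrix") {
    if (is.null(probe_col)) probe_col <- "Probe Set ID"
    if (is.null(go_cols)) go_cols <- AFFY_GO_COLUMNS
    tab <- utils::read.csv(text = lines, check.names = FALSE,
                           colClasses = "character")
  } else {
    if (is.null(probe_col)) probe_col <- "ProbeID"
    if (is.null(go_cols)) go_cols <- "GO"
    tab <- utils::read.delim(text = lines, check.names = FALSE,
                             colClasses = "character")
  }
  missing_cols <- setdiff(c(probe_col, go_cols), colnames(tab))
  if (length(missing_cols)) {
    parse_error("array annotation file lacks required ", dialect,
                " column(s): ", paste(missing_cols, collapse = ", "))
  }

  genes <- character(0)
  terms <- character(0)
  evid <- character(0)
  skipped_entries <- 0L
  emitted_entries <- 0L

  for (col in go_cols) {
    cells <- tab[[col]]
    for (i in seq_along(cells)) {
      cell <- trimws(cells[[i]])
      if (!nzchar(cell) || cell == "---") next
      if (dialect == "affymetrix") {
        entries <- strsplit(cell, "\\s*///\\s*")[[1]]
        for (e in entries) {
          parts <- trimws(strsplit(e, "\\s*//\\s*")[[1]])
          if (length(parts) < 2L || !grepl("^[0-9]+$", parts[1])) {
            skipped_entries <- skipped_entries + 1L
            next
          }
          genes <- c(genes, tab[[probe_col]][i])
          terms <- c(terms, sprintf("GO:%07d", as.integer(parts[1])))
          evid <- c(evid, if (length(parts) >= 3L && nzchar(parts[3]))
            parts[3] else NA_character_)
          emitted_entries <- emitted_entries + 1L
        }
      } else {
        entries <- strsplit(cell, "|", fixed = TRUE)[[1]]
        for (e in entries) {
          m <- regmatches(e, regexpr("GO:[0-9]{7}", e))
          if (!length(m)) {
            skipped_entries <- skipped_entries + 1L
            next
          }
          genes <- c(genes, tab[[probe_col]][i])
          terms <- c(terms, m)
          evid <- c(evid, NA_character_)
          emitted_entries <- emitted_entries + 1L
        }
      }
    }
  }
  if (skipped_entries > 0L) {
    warning(skipped_entries, " malformed GO cell entr",
            if (skipped_entries == 1L) "y" else "ies", " skipped",
            call. = FALSE)
  }
  out <- new_associations(genes, terms, evid)
  attr(out, "accounting") <- c(rows = nrow(tab), emitted = emitted_entries,
                               skipped = skipped_entries, excluded = 0L)
  out
}

#' GO evidence codes and named evidence profiles
#'
#' `go_evidence_codes()` returns the full vocabulary of GO evidence codes.
#' `evidence_profile()` returns a named allow-list: `"all"` disables evidence
#' filtering entirely (returns `NULL`); `"high_quality"` excludes the
#' electronically inferred (IEA), no-data (ND) and non-traceable author
#' statement (NAS) codes, approximating the well-supported subset used by
#' curated human GO collections. The exact historical subset is not published,
#' so the profile is a documented convention and any custom code set can be
#' passed to [filter_by_evidence()] instead.
#'
#' @param name `"all"` or `"high_quality"`.
#' @return `evidence_profile()`: a character vector of allowed codes, or
#'   `NULL` meaning no filtering.
#' @export
evidence_profile <- function(name = c("high_quality", "all")) {
  name <- match.arg(name)
  if (name == "all") return(NULL)
  setdiff(go_evidence_codes(), c("IEA", "ND", "NAS"))
}

#' @rdname evidence_profile
#' @export
go_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
    "HTP", "HDA", "HMP", "HGI", "HEP",
    "IBA", "IBD", "IKR", "IRD",
    "ISS", "ISO", "ISA", "ISM", "IGC", "RCA",
    "TAS", "NAS", "IC", "ND", "IEA")
}

#' Filter associations by evidence code
#'
#' Keeps associations whose evidence code is in the allow-list. Associations
#' without an evidence code (array annotation sources) can only pass when
#' filtering is disabled, because their support level is unknowable; a warning
#' reports how many were excluded on that ground.
#'
#' @param assocs An association data.frame.
#' @param allowed Character vector of allowed codes, or `NULL` to disable
#'   filtering (identity). Unknown codes in `allowed` draw a warning, not an
#'   error, since the code vocabulary evolves.
#' @return The filtered association data.frame.
#' @export
filter_by_evidence <- function(assocs, allowed = evidence_profile()) {
  if (is.null(allowed)) return(assocs)
  if (!length(allowed)) {
    config_error("evidence allow-list is empty; use NULL to disable filtering")
  }
  unknown <- setdiff(allowed, go_evidence_codes())
  if (length(unknown)) {
    warning("evidence code(s) not in the known GO vocabulary: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  no_code <- is.na(assocs$evidence)
  if (any(no_code)) {
    warning(sum(no_code), " association(s) excluded: the source carries no ",
            "evidence codes, so they cannot pass an evidence filter. Use the ",
            "'all' profile for such sources.", call. = FALSE)
  }
  out <- assocs[!no_code & assocs$evidence %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene identifier translation maps
#'
#' `read_id_map()` loads a two-column tab-separated file (`source TAB target`,
#' `#` comments allowed) mapping gene identifiers from the association source
#' to user-supplied identifiers, e.g. probe IDs to gene symbols. Duplicate
#' source keys are a load error. `id_map()` builds the same object from a
#' named character vector.
#'
#' The `mode` decides the fate of identifiers missing from the map:
#' `"keep_unmapped"` leaves them verbatim (useful to remap only a subset);
#' `"drop_unmapped"` removes them (useful to restrict an annotation file
#' covering several species to one of them).
#'
#' @param src Path, connection or character lines of the map file.
#' @param mapping Named character vector, `names = source`, `values = target`.
#' @param mode `"keep_unmapped"` or `"drop_unmapped"`.
#' @return An object of class `id_map`.
#' @export
read_id_map <- function(src, mode = c("keep_unmapped", "drop_unmapped")) {
  mode <- match.arg(mode)
  lines <- read_input_lines(src)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    parse_error("id map line(s) without two tab-separated columns: line ",
                which(bad)[1])
  }
  src_ids <- vapply(fields, `[[`, character(1), 1L)
  tgt_ids <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(src_ids)) {
    parse_error("duplicate source identifier(s) in id map: ",
                paste(unique(src_ids[duplicated(src_ids)]), collapse = ", "))
  }
  mapping <- tgt_ids
  names(mapping) <- src_ids
  id_map(mapping, mode)
}

#' @rdname read_id_map
#' @export
id_map <- function(mapping = character(0),
                   mode = c("keep_unmapped", "drop_unmapped")) {
  mode <- match.arg(mode)
  stopifnot(is.character(mapping))
  if (length(mapping) && anyDuplicated(names(mapping))) {
    parse_error("duplicate source identifier(s) in id map")
  }
  structure(list(mapping = mapping, mode = mode), class = "id_map")
}

#' Remap gene identifiers in an association table
#'
#' @param assocs An association data.frame.
#' @param map An [id_map()].
#' @return The association data.frame with gene identifiers substituted;
#'   under `drop_unmapped`, unmapped genes are removed and their count
#'   reported via a message.
#' @export
apply_id_map <- function(assocs, map) {
  stopifnot(inherits(map, "id_map"))
  if (!length(map$mapping)) {
    if (map$mode == "drop_unmapped" && nrow(assocs)) {
      message("id map: dropped ", nrow(assocs), " association(s) with ",
              "unmapped gene identifiers")
      out <- assocs[0, , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
    return(assocs)
  }
  hit <- assocs$gene_id %in% names(map$mapping)
  out <- assocs
  out$gene_id[hit] <- unname(map$mapping[assocs$gene_id[hit]])
  if (map$mode == "drop_unmapped") {
    n_drop <- sum(!hit)
    if (n_drop > 0L) {
      message("id map: dropped ", n_drop, " association(s) with unmapped ",
              "gene identifiers")
    }
    out <- out[hit, , drop = FALSE]
  }
  out <- new_associations(out$gene_id, out$term_id, out$evidence)
  out
}

#' Resolve association accessions against the ontology
#'
#' Rewrites synonymous GO accessions to the preferred accession of the
#' supplied ontology release, removes associations to obsolete terms, and
#' removes associations to accessions the ontology does not know at all
#' (possible when the term source is older than the association source). All
#' three anomalies are counted, not raised: the counters are reported as
#' informational warnings by the pipeline driver.
#'
#' @param assocs An association data.frame.
#' @param dag A `go_dag`.
#' @return A list with `associations` (the resolved, duplicate-free table)
#'   and `counters`, a named integer vector
#'   `c(synonym = , obsolete = , unknown = )` counting affected association
#'   rows.
#' @export
resolve_associations <- function(assocs, dag) {
  stopifnot(inherits(dag, "go_dag"))
  terms <- assocs$term_id
  current <- terms %in% names(dag$parents)
  is_alt <- !current & terms %in% names(dag$alt_ids)
  pref <- rep(NA_character_, length(terms))
  pref[current] <- terms[current]
  pref[is_alt] <- unname(dag$alt_ids[terms[is_alt]])
  # a synonym whose preferred accession is itself obsolete counts as obsolete
  alt_to_obsolete <- is_alt & pref %in% dag$obsolete
  pref[alt_to_obsolete] <- NA_character_
  obsolete <- (terms %in% dag$obsolete) | alt_to_obsolete
  unknown <- !current & !is_alt & !obsolete

  counters <- c(
    synonym = sum(is_alt & !alt_to_obsolete),
    obsolete = sum(obsolete),
    unknown = sum(unknown)
  )
  keep <- !is.na(pref)
  out <- new_associations(assocs$gene_id[keep], pref[keep],
                          assocs$evidence[keep])
  list(associations = out, counters = counters)
}
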