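#' Assemble and validate a pipeline run configuration
#'
#' Collects every knob of the gene-set build into one validated object. The
#' same object (and its serialized form, see [write_run_config()]) is stored
#' in the output collection's `params` for provenance.
#'
#' @param ontology_path Path to the GO OBO file.
#' @param source_kind `"gene2go"`, `"gaf"` or `"array"`.
#' @param source_path Path to the association source file.
#' @param output_path Path of the .gmt/.gmx file to write.
#' @param cache_path Optional ontology cache file; when it exists it is loaded
#'   instead of re-parsing the OBO file, otherwise it is written after parsing.
#' @param dialect Array dialect, `"affymetrix"` or `"agilent"`; required when
#'   `source_kind = "array"`.
#' @param taxon NCBI taxon ID; required for gene2go, optional for GAF.
#' @param evidence `"high_quality"` (default), `"all"`, or a character vector
#'   of evidence codes to allow.
#' @param id_choice Gene identifier choice; defaults to `"entrez_id"` for
#'   gene2go and `"symbol"` for GAF; ignored for array sources (probe ids).
#' @param map_path Optional two-column identifier map file.
#' @param map_mode `"keep_unmapped"` or `"drop_unmapped"`.
#' @param min_size,max_size Inclusive gene-set size bounds.
#' @param output_format `"gmt"` or `"gmx"`.
#' @param url_template URL pattern for representative terms (`%s` =
#'   accession).
#' @param description_style `"url_and_terms"` or `"url_only"` (second gmt
#'   field).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ontology_path, source_kind, source_path, output_path,
                       cache_path = NULL, dialect = NULL, taxon = NULL,
                       evidence = "high_quality", id_choice = NULL,
                       map_path = NULL,
                       map_mode = c("keep_unmapped", "drop_unmapped"),
                       min_size = 10L, max_size = 700L,
                       output_format = c("gmt", "gmx"),
                       url_template = go_term_url_template(),
                       description_style = c("url_and_terms", "url_only")) {
  source_kind <- match.arg(source_kind, c("gene2go", "gaf", "array"))
  map_mode <- match.arg(map_mode)
  output_format <- match.arg(output_format)
  description_style <- match.arg(description_style)
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (is.na(min_size) || is.na(max_size) || min_size < 1L) {
    config_error("size bounds must be positive integers")
  }
  if (min_size > max_size) {
    config_error("min_size (", min_size, ") exceeds max_size (", max_size, ")")
  }
  if (source_kind == "array") {
    if (is.null(dialect)) {
      config_error("source_kind 'array' requires a dialect ",
                   "('affymetrix' or 'agilent')")
    }
    dialect <- match.arg(dialect, c("affymetrix", "agilent"))
  }
  if (source_kind == "gene2go" && is.null(taxon)) {
    config_error("source_kind 'gene2go' requires a taxon ID")
  }
  if (is.null(id_choice)) {
    id_choice <- switch(source_kind, gene2go = "entrez_id", gaf = "symbol",
                        array = NULL)
  }
  if (is.character(evidence) && length(evidence) == 1L &&
      !evidence %in% c("all", "high_quality") &&
      !evidence %in% go_evidence_codes()) {
    config_error("evidence must be 'all', 'high_quality' or a vector of ",
                 "evidence codes; got '", evidence, "'")
  }
  structure(list(
    ontology_path = ontology_path, cache_path = cache_path,
    source_kind = source_kind, source_path = source_path, dialect = dialect,
    taxon = if (is.null(taxon)) NULL else as.character(taxon),
    evidence = evidence, id_choice = id_choice, map_path = map_path,
    map_mode = map_mode, min_size = min_size, max_size = max_size,
    output_format = output_format, output_path = output_path,
    url_template = url_template, description_style = description_style
  ), class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Configurations round-trip through JSON: `read_run_config()` re-validates
#' through [run_config()], so a restored configuration is identical to the
#' original.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

with_stage <- function(stage, hint, expr) {
  withCallingHandlers(
    tryCatch(expr, gosets_error = function(e) {
      cls <- setdiff(class(e), c("error", "condition"))
      stop_gosets(cls[1], "[stage: ", stage, "] ", conditionMessage(e),
                  " (hint: ", hint, ")")
    }, error = function(e) {
      if (inherits(e, "gosets_error")) stop(e)
      stop_gosets("gosets_error", "[stage: ", stage, "] ",
                  conditionMessage(e), " (hint: ", hint, ")")
    }),
    warning = function(w) {
      message("warning [", stage, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
}

#' Run the full gene-set construction pipeline
#'
#' Executes, in fixed order: ontology parse (or cache load), association
#' reading, evidence filtering, identifier selection and remapping, GO
#' accession resolution, propagation up the DAG, size filtering, duplicate
#' collapsing, and .gmt/.gmx output. Informational warnings (synonym,
#' obsolete and unknown-term counts; dropped rows) go to standard error,
#' ending with a single machine-readable summary line. The output file is
#' written atomically: on failure no partial file is left behind.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (the summary line is always
#'   emitted).
#' @return The written `geneset_collection`, invisibly.
#' @export
build_genesets <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  dag <- with_stage("ontology", "check the OBO file and cache path", {
    if (!is.null(config$cache_path) && file.exists(config$cache_path)) {
      d <- load_cached(config$cache_path)
      say("ontology: cache hit, parse skipped (", config$cache_path, ")")
      d
    } else {
      d <- parse_obo(config$ontology_path)
      if (!is.null(config$cache_path)) {
        cache_dag(d, config$cache_path)
        say("ontology: parsed ", nrow(d$terms), " terms; cache written")
      } else {
        say("ontology: parsed ", nrow(d$terms), " terms")
      }
      d
    }
  })

  assocs <- with_stage("read", "check the association file and its dialect", {
    switch(config$source_kind,
      gene2go = read_gene2go(config$source_path, taxon = config$taxon,
                             id_choice = config$id_choice),
      gaf = read_gaf(config$source_path, taxon = config$taxon,
                     id_choice = config$id_choice),
      array = read_array_annotation(config$source_path,
                                    dialect = config$dialect))
  })
  say("read: ", nrow(assocs), " associations from ", config$source_kind,
      " source")

  assocs <- with_stage("evidence_filter",
                       "use evidence = 'all' for sources without codes", {
    allowed <- if (is.character(config$evidence) &&
                   length(config$evidence) == 1L &&
                   config$evidence %in% c("all", "high_quality")) {
      evidence_profile(config$evidence)
    } else {
      config$evidence
    }
    filter_by_evidence(assocs, allowed)
  })

  if (!is.null(config$map_path)) {
    assocs <- with_stage("id_map", "check the two-column map file", {
      apply_id_map(assocs, read_id_map(config$map_path, config$map_mode))
    })
  }

  res <- with_stage("resolve", "association and ontology releases may differ",
                    resolve_associations(assocs, dag))
  say("resolve: ", res$counters[["synonym"]], " synonym(s) remapped, ",
      res$counters[["obsolete"]], " obsolete and ",
      res$counters[["unknown"]], " unknown term reference(s) dropped")

  prop <- with_stage("propagate", "ontology and associations must match", {
    propagate(build_index(res$associations), dag)
  })
  depths <- with_stage("depths", "ontology must be a rooted DAG",
                       compute_depths(dag))
  pfrac <- propagated_fraction(prop)

  sets <- with_stage("collapse", "check size bounds", {
    filtered <- size_filter(prop, config$min_size, config$max_size)
    collapse_duplicates(filtered, depths, dag,
                        url_template = config$url_template)
  })
  collection <- geneset_collection(sets, params = unclass(config),
                                   warnings = res$counters)

  with_stage("write", "check the output path is writable", {
    tmp <- paste0(config$output_path, ".tmp", Sys.getpid())
    on.exit(unlink(tmp), add = TRUE)
    writer <- if (config$output_format == "gmt") write_gmt else write_gmx
    writer(collection, tmp, description = config$description_style)
    if (!file.rename(tmp, config$output_path)) {
      io_error("cannot move temporary output to '", config$output_path, "'")
    }
  })

  message(sprintf(
    "gosets-summary synonyms=%d obsolete=%d unknown=%d propagated_fraction=%.4f sets=%d output=%s",
    res$counters[["synonym"]], res$counters[["obsolete"]],
    res$counters[["unknown"]],
    if (is.na(pfrac)) NaN else pfrac,
    length(collection$sets), config$output_path))
  invisible(collection)
}
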