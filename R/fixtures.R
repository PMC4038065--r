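#' Specification for synthetic ontology and association fixtures
#'
#' The generator emits a random—but seeded and therefore byte-reproducible—
#' ontology in OBO 1.2 format plus association files in each supported source
#' dialect, together with the ground truth (edge lists, injected anomaly
#' counts, expected post-resolution associations) needed to check every
#' pipeline stage without network access. Fixtures target code-path coverage,
#' not biological realism: term-size distributions are uniform, not GO-like.
#'
#' Defaults give a mid-sized single-namespace ontology with the anomaly rates
#' (a few percent of synonymous and obsolete references, a small admixture of
#' NOT-qualified and unknown-term rows) that real association sources built
#' against a newer ontology release typically show.
#'
#' @param n_terms Number of current terms (>= 3: a root plus two levels).
#' @param max_parents Maximum parents drawn per non-root term.
#' @param n_genes Gene universe size.
#' @param n_assocs Number of base association rows.
#' @param obsolete_fraction Fraction of `n_terms` emitted as obsolete stanzas,
#'   and of `n_assocs` injected as rows citing obsolete accessions.
#' @param synonym_fraction Fraction of `n_terms` given alt_id synonyms, and of
#'   `n_assocs` injected as rows citing those synonyms.
#' @param not_fraction Fraction of `n_assocs` injected as NOT-qualified rows
#'   (dialects with a qualifier column only).
#' @param unknown_fraction Fraction of `n_assocs` injected as rows citing
#'   accessions absent from the ontology.
#' @param evidence_mix Named numeric vector of evidence-code weights.
#' @param seed Integer random seed; identical spec + seed gives identical
#'   bytes in every emitted file.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 50L, max_parents = 3L, n_genes = 100L,
                         n_assocs = 200L, obsolete_fraction = 0.05,
                         synonym_fraction = 0.05, not_fraction = 0.05,
                         unknown_fraction = 0.02,
                         evidence_mix = c(IEA = 0.5, IDA = 0.3, TAS = 0.2),
                         seed = 1L) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 3L) {
    config_error("fixture_spec: n_terms must be >= 3")
  }
  fr <- c(obsolete_fraction, synonym_fraction, not_fraction, unknown_fraction)
  if (any(fr < 0 | fr > 1)) {
    config_error("fixture_spec: fractions must lie in [0, 1]")
  }
  if (is.null(names(evidence_mix)) || any(evidence_mix < 0) ||
      sum(evidence_mix) <= 0) {
    config_error("fixture_spec: evidence_mix must be a named non-negative ",
                 "weight vector")
  }
  structure(list(n_terms = n_terms, max_parents = as.integer(max_parents),
                 n_genes = as.integer(n_genes), n_assocs = as.integer(n_assocs),
                 obsolete_fraction = obsolete_fraction,
                 synonym_fraction = synonym_fraction,
                 not_fraction = not_fraction,
                 unknown_fraction = unknown_fraction,
                 evidence_mix = evidence_mix, seed = as.integer(seed)),
            class = "fixture_spec")
}

go_acc <- function(i) sprintf("GO:%07d", i)

#' Generate a synthetic ontology with ground truth
#'
#' Builds a random single-namespace DAG that is acyclic by construction
#' (each term draws its parents only from earlier-generated terms), serialises
#' it as an OBO 1.2 file, and returns the ground-truth edge list, synonym map
#' and obsolete list alongside for oracle-style testing. About one edge in
#' five is a `part_of` relationship; the rest are `is_a`.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `obo` (character lines), `edges` (data.frame
#'   child/parent/relation), `alt_ids` (named character, alt -> preferred),
#'   `obsolete` (character), `replaced_by` (named character), `term_ids`
#'   (current accessions) and `spec`.
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_terms
  ns <- "biological_process"
  term_ids <- go_acc(seq_len(n))
  term_names <- c("synthetic root process",
                  sprintf("synthetic process %02d", seq_len(n)[-1]))

  child <- integer(0); parent <- integer(0); relation <- character(0)
  for (i in 2:n) {
    k <- sample.int(min(spec$max_parents, i - 1L), 1L)
    ps <- if (i == 2L) 1L else sample.int(i - 1L, k)
    rel <- sample(c("is_a", "part_of"), length(ps), replace = TRUE,
                  prob = c(0.8, 0.2))
    child <- c(child, rep.int(i, length(ps)))
    parent <- c(parent, ps)
    relation <- c(relation, rel)
  }

  n_obs <- round(spec$obsolete_fraction * n)
  n_syn <- round(spec$synonym_fraction * n)
  obsolete_ids <- if (n_obs > 0) go_acc(n + seq_len(n_obs)) else character(0)
  # every other obsolete term names a replacement
  replaced_by <- character(0)
  if (n_obs > 0) {
    with_repl <- seq_len(n_obs) %% 2L == 1L
    replaced_by <- go_acc(sample.int(n, sum(with_repl), replace = TRUE))
    names(replaced_by) <- obsolete_ids[with_repl]
  }
  alt_ids <- character(0)
  if (n_syn > 0) {
    alt_acc <- go_acc(n + n_obs + seq_len(n_syn))
    alt_ids <- go_acc(sample.int(n, n_syn, replace = TRUE))
    names(alt_ids) <- alt_acc
  }

  lines <- c("format-version: 1.2", "ontology: gosets-fixture", "")
  for (i in seq_len(n)) {
    st <- c("[Term]",
            paste0("id: ", term_ids[i]),
            paste0("name: ", term_names[i]),
            paste0("namespace: ", ns))
    alts <- names(alt_ids)[alt_ids == term_ids[i]]
    if (length(alts)) st <- c(st, paste0("alt_id: ", sort(alts)))
    sel <- child == i
    for (j in which(sel)) {
      st <- c(st, if (relation[j] == "is_a") {
        paste0("is_a: ", term_ids[parent[j]], " ! ", term_names[parent[j]])
      } else {
        paste0("relationship: part_of ", term_ids[parent[j]])
      })
    }
    lines <- c(lines, st, "")
  }
  for (o in obsolete_ids) {
    st <- c("[Term]",
            paste0("id: ", o),
            paste0("name: obsolete synthetic process ", sub("GO:", "", o)),
            paste0("namespace: ", ns),
            "is_obsolete: true")
    if (o %in% names(replaced_by)) {
      st <- c(st, paste0("replaced_by: ", replaced_by[[o]]))
    }
    lines <- c(lines, st, "")
  }

  list(obo = lines,
       edges = data.frame(child = term_ids[child], parent = term_ids[parent],
                          relation = relation, row.names = NULL,
                          stringsAsFactors = FALSE),
       alt_ids = alt_ids,
       obsolete = obsolete_ids,
       replaced_by = replaced_by,
       term_ids = term_ids,
       spec = spec)
}

# Draw n unique (gene index, accession, evidence) triples.
sample_unique_rows <- function(n, gene_pool, acc_pool, ev_pool, ev_prob) {
  if (n <= 0L || !length(acc_pool)) {
    return(data.frame(gene = character(0), acc = character(0),
                      ev = character(0), stringsAsFactors = FALSE))
  }
  out <- NULL
  for (. in 1:50) {
    need <- n - if (is.null(out)) 0L else nrow(out)
    if (need <= 0L) break
    cand <- data.frame(
      gene = gene_pool[sample.int(length(gene_pool), need, replace = TRUE)],
      acc = acc_pool[sample.int(length(acc_pool), need, replace = TRUE)],
      ev = sample(names(ev_pool), need, replace = TRUE, prob = ev_prob),
      stringsAsFactors = FALSE)
    out <- unique(rbind(out, cand))
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

#' Generate a synthetic association file in a source dialect
#'
#' Emits a syntactically valid association file for the requested dialect,
#' exercising the hostile paths the readers and [resolve_associations()] must
#' handle: NOT-qualified rows, rows citing synonymous, obsolete and unknown
#' accessions, a decoy second taxon (gene2go), and the spec's evidence-code
#' mix. The returned ground truth holds the associations the pipeline must
#' emit after resolution (synonyms remapped, everything else dropped) plus
#' the exact injected anomaly counts.
#'
#' Gene identifiers are Entrez-style numbers (gene2go), symbols `GENExxxx`
#' (GAF, matching `id_choice = "symbol"`), or probe ids `P_xxxx_at`
#' (affymetrix). The affymetrix dialect carries no qualifier column, so no
#' NOT rows are injected there.
#'
#' @param spec A [fixture_spec()].
#' @param ontology The list returned by [make_ontology()].
#' @param dialect `"gene2go"`, `"gaf"` or `"affymetrix"`.
#' @param taxon Taxon ID used for the real rows (gene2go/GAF); a decoy taxon
#'   `9606` is also emitted for gene2go.
#' @return A list: `text` (character lines of the file), `truth` (list with
#'   `associations`, `counters`, `n_not`, `taxon`).
#' @export
make_associations <- function(spec, ontology,
                              dialect = c("gene2go", "gaf", "affymetrix"),
                              taxon = 10090) {
  stopifnot(inherits(spec, "fixture_spec"))
  dialect <- match.arg(dialect)
  set.seed(spec$seed + match(dialect, c("gene2go", "gaf", "affymetrix")))

  genes <- switch(dialect,
    gene2go = as.character(100000L + seq_len(spec$n_genes)),
    gaf = sprintf("GENE%04d", seq_len(spec$n_genes)),
    affymetrix = sprintf("P_%04d_at", seq_len(spec$n_genes)))
  current <- ontology$term_ids
  ev_mix <- spec$evidence_mix
  ev_prob <- ev_mix / sum(ev_mix)

  base <- sample_unique_rows(spec$n_assocs, genes, current, ev_mix, ev_prob)
  n_not <- if (dialect == "affymetrix") 0L else
    round(spec$not_fraction * spec$n_assocs)
  not_rows <- sample_unique_rows(n_not, genes, current, ev_mix, ev_prob)
  syn_rows <- sample_unique_rows(round(spec$synonym_fraction * spec$n_assocs),
                                 genes, names(ontology$alt_ids), ev_mix,
                                 ev_prob)
  obs_rows <- sample_unique_rows(round(spec$obsolete_fraction * spec$n_assocs),
                                 genes, ontology$obsolete, ev_mix, ev_prob)
  n_unk <- round(spec$unknown_fraction * spec$n_assocs)
  unk_rows <- sample_unique_rows(n_unk, genes, go_acc(9000000L + seq_len(max(n_unk, 1L))),
                                 ev_mix, ev_prob)

  # expected post-resolution associations: base plus remapped synonyms,
  # deduplicated per (gene, term, evidence)
  truth_rows <- rbind(
    base,
    if (nrow(syn_rows)) {
      transform(syn_rows, acc = unname(ontology$alt_ids[acc]))
    })
  truth_rows <- unique(truth_rows)
  truth <- list(
    associations = data.frame(gene_id = truth_rows$gene,
                              term_id = truth_rows$acc,
                              evidence = truth_rows$ev,
                              row.names = NULL, stringsAsFactors = FALSE),
    counters = c(synonym = nrow(syn_rows), obsolete = nrow(obs_rows),
                 unknown = nrow(unk_rows)),
    n_not = nrow(not_rows),
    taxon = taxon)

  name_of <- function(acc) {
    i <- match(acc, ontology$term_ids)
    ifelse(is.na(i), "retired synthetic process",
           c("synthetic root process",
             sprintf("synthetic process %02d", seq_along(ontology$term_ids)[-1]))[i])
  }

  text <- switch(dialect,
    gene2go = {
      header <- paste("#tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier",
                      "GO_term", "PubMed", "Category", sep = "\t")
      row_of <- function(df, qual, tax) {
        if (!nrow(df)) return(character(0))
        paste(tax, df$gene, df$acc, df$ev, qual, name_of(df$acc), "-",
              "Process", sep = "\t")
      }
      decoy <- sample_unique_rows(ceiling(spec$n_assocs / 4), genes, current,
                                  ev_mix, ev_prob)
      c(header,
        row_of(base, "-", taxon),
        row_of(not_rows, "NOT", taxon),
        row_of(syn_rows, "-", taxon),
        row_of(obs_rows, "-", taxon),
        row_of(unk_rows, "-", taxon),
        row_of(decoy, "-", 9606))
    },
    gaf = {
      row_of <- function(df, qual) {
        if (!nrow(df)) return(character(0))
        vapply(seq_len(nrow(df)), function(i) {
          paste(c("FIXDB", paste0("OBJ_", df$gene[i]), df$gene[i], qual,
                  df$acc[i], "FIX:0001", df$ev[i], "", "P", name_of(df$acc[i]),
                  "", "protein", paste0("taxon:", taxon), "20130901", "FIX",
                  "", ""), collapse = "\t")
        }, character(1))
      }
      c("!gaf-version: 2.2",
        row_of(base, "involved_in"),
        row_of(not_rows, "NOT|involved_in"),
        row_of(syn_rows, "involved_in"),
        row_of(obs_rows, "involved_in"),
        row_of(unk_rows, "involved_in"))
    },
    affymetrix = {
      all_rows <- rbind(base, syn_rows, obs_rows, unk_rows)
      cells <- vapply(genes, function(g) {
        sel <- all_rows$gene == g
        if (!any(sel)) return("---")
        paste(sprintf("%s // %s // %s", sub("GO:", "", all_rows$acc[sel]),
                      name_of(all_rows$acc[sel]), all_rows$ev[sel]),
              collapse = " /// ")
      }, character(1))
      quote_csv <- function(x) paste0('"', gsub('"', '""', x), '"')
      c("#For research use only.",
        paste(quote_csv(c("Probe Set ID", "Gene Symbol",
                          "Gene Ontology Biological Process",
                          "Gene Ontology Molecular Function",
                          "Gene Ontology Cellular Component")),
              collapse = ","),
        vapply(seq_along(genes), function(i) {
          paste(quote_csv(c(genes[i], paste0("SYM", i), cells[i], "---",
                            "---")), collapse = ",")
        }, character(1)))
    })

  list(text = text, truth = truth)
}

#' Write a complete fixture directory
#'
#' Emits `ontology.obo`, `gene2go.tsv`, `assoc.gaf`, `array.csv`,
#' `idmap.tsv` (mapping half of the gene2go Entrez ids to symbols) and
#' `truth.json` (ground truth for every file) under `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, spec = fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ont <- make_ontology(spec)
  g2g <- make_associations(spec, ont, "gene2go")
  gaf <- make_associations(spec, ont, "gaf")
  affy <- make_associations(spec, ont, "affymetrix")

  write_text_lines(ont$obo, file.path(dir, "ontology.obo"))
  write_text_lines(g2g$text, file.path(dir, "gene2go.tsv"))
  write_text_lines(gaf$text, file.path(dir, "assoc.gaf"))
  write_text_lines(affy$text, file.path(dir, "array.csv"))

  entrez <- as.character(100000L + seq_len(spec$n_genes))
  half <- entrez[seq_len(spec$n_genes %/% 2)]
  write_text_lines(c("# source\ttarget",
                     paste0(half, "\tSYM_", half)),
                   file.path(dir, "idmap.tsv"))

  truth <- list(
    ontology = list(edges = ont$edges,
                    alt_ids = as.list(ont$alt_ids),
                    obsolete = ont$obsolete),
    gene2go = g2g$truth, gaf = gaf$truth, affymetrix = affy$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Canned fixture illustrating why propagation matters
#'
#' A small cellular-component-style DAG mirroring the structure of the
#' classic motivating case for annotation propagation: one parent term with
#' 16 directly annotated genes whose three children (sub-structure terms)
#' carry 81 additional distinct genes. Before propagation the parent's gene
#' set has 16 members and misses the large majority of relevant genes; after
#' propagation it has exactly 97. The gene identifiers are synthetic; only
#' the arithmetic of the real-world example is reconstructed.
#'
#' @return A list: `dag` (a parsed `go_dag`), `associations` (resolved-ready
#'   association data.frame), `parent` (the accession of the 16-gene parent
#'   term).
#' @export
sarcomere_fixture <- function() {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: cellular component root",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0000002", "name: contractile fiber unit",
    "namespace: cellular_component", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: anisotropic band analog",
    "namespace: cellular_component",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: isotropic band analog",
    "namespace: cellular_component",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000005", "name: z line analog",
    "namespace: cellular_component", "is_a: GO:0000002", "")
  dag <- parse_obo(obo)
  direct <- sprintf("PG%03d", seq_len(16))
  extra <- sprintf("CG%03d", seq_len(81))
  assoc <- data.frame(
    gene_id = c(direct, extra),
    term_id = c(rep("GO:0000002", 16),
                rep(c("GO:0000003", "GO:0000004", "GO:0000005"), c(27, 27, 27))),
    evidence = "IDA", row.names = NULL, stringsAsFactors = FALSE)
  list(dag = dag, associations = assoc, parent = "GO:0000002")
}
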