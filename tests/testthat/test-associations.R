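g2g_lines <- c(
  "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
  "10090\t11421\tGO:0000001\tIDA\t-\troot\t-\tProcess",
  "10090\t11422\tGO:0000002\tIEA\t-\tmid\t-\tProcess",
  "10090\t11423\tGO:0000003\tTAS\t-\tleaf\t-\tProcess",
  "9606\t21\tGO:0000001\tIDA\t-\troot\t-\tProcess",
  "9606\t22\tGO:0000002\tIEA\t-\tmid\t-\tProcess")

test_that("read_gene2go filters by taxon and excludes NOT-qualified rows", {
  a <- read_gene2go(g2g_lines, taxon = 10090)
  expect_equal(nrow(a), 3L)
  expect_setequal(a$gene_id, c("11421", "11422", "11423"))

  withnot <- c(g2g_lines[1:2],
               "10090\t11429\tGO:0000002\tIDA\tNOT\tmid\t-\tProcess")
  a <- read_gene2go(withnot, taxon = 10090)
  expect_equal(a$gene_id, "11421")
  acc <- attr(a, "accounting")
  expect_equal(unname(acc["rows"]),
               unname(acc["emitted"] + acc["skipped"] + acc["excluded"]))
})

test_that("read_gene2go warns on malformed rows, empty results and symbol requests", {
  short <- c(g2g_lines[1:2], "10090\tonly_two_columns")
  expect_warning(a <- read_gene2go(short, taxon = 10090), "skipped")
  expect_equal(nrow(a), 1L)
  expect_equal(attr(a, "accounting")[["skipped"]], 1L)

  expect_warning(a <- read_gene2go(g2g_lines, taxon = 7227), "no gene2go")
  expect_equal(nrow(a), 0L)
  expect_warning(a <- read_gene2go(character(0), taxon = 10090), "no gene2go")
  expect_equal(nrow(a), 0L)

  expect_warning(read_gene2go(g2g_lines, taxon = 10090, id_choice = "symbol"),
                 "no gene symbol")
})

gaf_row <- function(object_id = "P12345", symbol = "Abc1",
                    qualifier = "involved_in", go = "GO:0000002",
                    evidence = "IDA", taxon = "taxon:10090") {
  paste(c("UniProtKB", object_id, symbol, qualifier, go, "PMID:1", evidence,
          "", "P", "a name", "", "protein", taxon, "20130901", "UniProt",
          "", ""), collapse = "\t")
}

test_that("read_gaf honours the identifier choice and NOT qualifiers", {
  lines <- c("!gaf-version: 2.2", gaf_row())
  expect_equal(read_gaf(lines, id_choice = "symbol")$gene_id, "Abc1")
  expect_equal(read_gaf(lines, id_choice = "object_id")$gene_id, "P12345")

  lines <- c("!gaf-version: 2.2", gaf_row(),
             gaf_row(symbol = "Neg1", qualifier = "NOT|contributes_to"))
  a <- read_gaf(lines, id_choice = "symbol")
  expect_equal(a$gene_id, "Abc1")
  acc <- attr(a, "accounting")
  expect_equal(unname(acc["rows"]),
               unname(acc["emitted"] + acc["skipped"] + acc["excluded"]))
})

test_that("read_gaf applies the taxon filter and reports taxon anomalies", {
  lines <- c("!gaf-version: 2.2",
             gaf_row(symbol = "Mouse1", taxon = "taxon:10090"),
             gaf_row(symbol = "Human1", taxon = "taxon:9606"),
             gaf_row(symbol = "Dual1", taxon = "taxon:10090|taxon:32630"))
  a <- read_gaf(lines, taxon = 10090)
  expect_setequal(a$gene_id, c("Mouse1", "Dual1"))

  odd <- c("!gaf-version: 2.2", gaf_row(symbol = "Odd1", taxon = "unparseable"))
  # no filter: retained with a warning
  expect_warning(a <- read_gaf(odd), "taxon")
  expect_equal(a$gene_id, "Odd1")
  # active filter: excluded
  expect_warning(a <- read_gaf(odd, taxon = 10090), "taxon")
  expect_equal(nrow(a), 0L)

  bad <- c("!gaf-version: 2.2", gaf_row(), "too\tfew\tcolumns")
  expect_warning(a <- read_gaf(bad), "17")
  expect_equal(nrow(a), 1L)
})

affy_lines <- c(
  "#Comment header",
  paste('"Probe Set ID","Gene Symbol","Gene Ontology Biological Process",',
        '"Gene Ontology Molecular Function","Gene Ontology Cellular Component"',
        sep = ""),
  paste('"1000_at","ABC",',
        '"0007155 // cell adhesion // IEA /// 0000002 // other process // TAS",',
        '"---",""', sep = ""))

test_that("read_array_annotation parses the affymetrix cell grammar", {
  a <- read_array_annotation(affy_lines, dialect = "affymetrix")
  expect_equal(nrow(a), 2L)
  expect_equal(a$gene_id, c("1000_at", "1000_at"))
  expect_setequal(a$term_id, c("GO:0007155", "GO:0000002"))
  expect_equal(a$evidence[a$term_id == "GO:0007155"], "IEA")

  # "---" and empty cells yield nothing; malformed entries are skipped
  quiet <- c(affy_lines[1:2], '"2000_at","XYZ","---","",""')
  expect_equal(nrow(read_array_annotation(quiet, dialect = "affymetrix")), 0L)
  bad <- c(affy_lines[1:2], '"2000_at","XYZ","garbage with no slashes","",""')
  expect_warning(a <- read_array_annotation(bad, dialect = "affymetrix"),
                 "malformed")
  expect_equal(nrow(a), 0L)

  # missing GO columns are a fatal dialect error
  nocol <- c('"Probe Set ID","Gene Symbol"', '"1000_at","ABC"')
  expect_error(read_array_annotation(nocol, dialect = "affymetrix"),
               class = "gosets_parse_error")
})

test_that("read_array_annotation parses the agilent dialect without evidence", {
  lines <- c("ProbeID\tGO",
             "A_1\tGO:0006355(regulation of transcription)|GO:0000002(x)",
             "A_2\t")
  a <- read_array_annotation(lines, dialect = "agilent")
  expect_equal(nrow(a), 2L)
  expect_true(all(is.na(a$evidence)))
  expect_setequal(a$term_id, c("GO:0006355", "GO:0000002"))

  # user-supplied column names
  lines2 <- c("Probe\tAnnotation",
              "A_9\tGO:0000003(y)")
  a2 <- read_array_annotation(lines2, dialect = "agilent",
                              probe_col = "Probe", go_cols = "Annotation")
  expect_equal(a2$gene_id, "A_9")
})

test_that("filter_by_evidence keeps the allow-list and handles code-free sources", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  term_id = rep("GO:0000001", 3),
                  evidence = c("IEA", "TAS", NA), stringsAsFactors = FALSE)
  expect_warning(f <- filter_by_evidence(a, allowed = "TAS"), "no evidence")
  expect_equal(f$gene_id, "g2")
  # disabled filtering is the identity
  expect_identical(filter_by_evidence(a, allowed = NULL), a)
  # unknown codes warn but do not error
  expect_warning(filter_by_evidence(a[1:2, ], allowed = c("TAS", "ZZZ")),
                 "ZZZ")
  # empty allow-list is a configuration error, not silent all-drop
  expect_error(filter_by_evidence(a, allowed = character(0)),
               class = "gosets_config_error")
  # high_quality profile excludes electronic and unsupported codes
  prof <- evidence_profile("high_quality")
  expect_false(any(c("IEA", "ND", "NAS") %in% prof))
  expect_true(all(c("IDA", "TAS") %in% prof))
  expect_null(evidence_profile("all"))
})

test_that("apply_id_map remaps, keeps or drops unmapped identifiers", {
  a <- data.frame(gene_id = c("A", "B"), term_id = rep("GO:0000001", 2),
                  evidence = "IDA", stringsAsFactors = FALSE)
  keep <- id_map(c(A = "X"), mode = "keep_unmapped")
  expect_setequal(apply_id_map(a, keep)$gene_id, c("X", "B"))
  drop <- id_map(c(A = "X"), mode = "drop_unmapped")
  expect_message(res <- apply_id_map(a, drop), "dropped 1")
  expect_equal(res$gene_id, "X")
  # empty map with keep mode is the identity
  expect_equal(apply_id_map(a, id_map())$gene_id, a$gene_id)
})

test_that("read_id_map loads two-column files and rejects duplicate keys", {
  m <- read_id_map(c("# comment", "A\tX", "B\tY"))
  expect_equal(m$mapping, c(A = "X", B = "Y"))
  expect_error(read_id_map(c("A\tX", "A\tY")), class = "gosets_parse_error")
  expect_error(read_id_map(c("A_only", "B\tY")),
               class = "gosets_parse_error")
})

test_that("resolve_associations remaps synonyms, drops obsoletes and unknowns", {
  dag <- parse_obo(tiny_obo())
  a <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    term_id = c("GO:0000002",  # current
                "GO:0000010",  # synonym of GO:0000002
                "GO:0000009",  # obsolete
                "GO:9999999"), # unknown
    evidence = "IDA", stringsAsFactors = FALSE)
  r <- resolve_associations(a, dag)
  expect_equal(r$counters, c(synonym = 1L, obsolete = 1L, unknown = 1L))
  expect_setequal(r$associations$gene_id, c("g1", "g2"))
  expect_true(all(r$associations$term_id == "GO:0000002"))

  # idempotence: a second pass changes nothing and counts nothing
  r2 <- resolve_associations(r$associations, dag)
  expect_equal(r2$counters, c(synonym = 0L, obsolete = 0L, unknown = 0L))
  expect_equal(assoc_key(r2$associations), assoc_key(r$associations))
})

test_that("filtering and mapping are order-independent up to set equality", {
  set.seed(42)
  a <- data.frame(gene_id = sample(sprintf("g%02d", 1:20), 50, replace = TRUE),
                  term_id = sprintf("GO:%07d", sample(5, 50, replace = TRUE)),
                  evidence = sample(c("IEA", "IDA", "TAS"), 50, replace = TRUE),
                  stringsAsFactors = FALSE)
  perm <- a[sample(nrow(a)), ]
  expect_equal(assoc_key(filter_by_evidence(a, "IDA")),
               assoc_key(filter_by_evidence(perm, "IDA")))
  m <- id_map(c(g01 = "X1", g02 = "X2"), mode = "keep_unmapped")
  expect_equal(assoc_key(apply_id_map(a, m)), assoc_key(apply_id_map(perm, m)))
})
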