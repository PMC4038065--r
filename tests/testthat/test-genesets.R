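make_index <- function(members) {
  build_index(data.frame(
    gene_id = as.character(unlist(members, use.names = FALSE)),
    term_id = rep(names(members) %||% character(0), lengths(members)),
    evidence = rep("IDA", sum(lengths(members))),
    stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("size_filter applies inclusive bounds and validates them", {
  members <- list(
    `GO:0000001` = sprintf("a%03d", 1:3),
    `GO:0000002` = sprintf("b%03d", 1:10),
    `GO:0000003` = sprintf("c%03d", 1:700),
    `GO:0000004` = sprintf("d%03d", 1:701))
  idx <- make_index(members)
  kept <- size_filter(idx, 10, 700)
  expect_setequal(names(kept$members), c("GO:0000002", "GO:0000003"))
  # all-pass bounds are the identity on membership
  expect_equal(size_filter(idx, 1, 10000)$members, idx$members)
  # degenerate input
  empty <- make_index(list())
  expect_equal(length(size_filter(empty, 10, 700)$members), 0L)
  expect_error(size_filter(idx, 10, 9), class = "gosets_config_error")
})

two_term_dag <- function() {
  parse_obo(c(
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: muscle system process",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: muscle contraction",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: muscle hypertrophy",
    "namespace: biological_process", "is_a: GO:0000002", ""))
}

test_that("collapse_duplicates groups identical content under the most general term", {
  dag <- two_term_dag()
  depths <- compute_depths(dag)
  idx <- new_index <- make_index(list(
    `GO:0000002` = c("g1", "g2"),   # parent, depth 1
    `GO:0000003` = c("g1", "g2"),   # child, depth 2, identical content
    `GO:0000004` = c("g3", "g4")))
  sets <- collapse_duplicates(idx, depths, dag)
  expect_length(sets, 2L)
  merged <- sets[[which(vapply(sets, function(s)
    setequal(s$genes, c("g1", "g2")), logical(1)))]]
  expect_equal(merged$representative$term_id, "GO:0000002")
  expect_equal(merged$all_terms$term_id, c("GO:0000002", "GO:0000003"))
  expect_equal(merged$set_name, "MUSCLE_SYSTEM_PROCESS")
  expect_match(merged$url, "GO:0000002", fixed = TRUE)
  # representative depth is the minimum over all contributing terms
  expect_equal(merged$representative$depth, min(merged$all_terms$depth))

  # three pairwise-distinct contents yield three sets
  idx3 <- make_index(list(`GO:0000002` = c("x1", "x2"),
                          `GO:0000003` = c("y1", "y2"),
                          `GO:0000004` = c("z1", "z2")))
  expect_length(collapse_duplicates(idx3, depths, dag), 3L)

  # equal-depth tie breaks to the lexicographically smaller accession
  tie <- make_index(list(`GO:0000004` = c("g1", "g2"),
                         `GO:0000003` = c("g1", "g2")))
  sets <- collapse_duplicates(tie, depths, dag)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$representative$term_id, "GO:0000003")
  expect_setequal(sets[[1]]$genes, c("g1", "g2"))

  # never changes gene content, only groups labels
  all_genes_in <- sort(unique(unlist(idx$members)))
  all_genes_out <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  expect_true(all(all_genes_out %in% all_genes_in))

  # depths missing a term is a contract violation
  expect_error(collapse_duplicates(idx, depths[-2], dag),
               class = "gosets_validation_error")
})

test_that("set naming is MSigDB-style with collision suffixes", {
  expect_equal(gosets:::make_set_name("muscle system process"),
               "MUSCLE_SYSTEM_PROCESS")
  expect_equal(gosets:::make_set_name("NAD(P)+ activity, 5'->3'"),
               "NAD_P_ACTIVITY_5_3")
  expect_equal(gosets:::disambiguate_names(c("A", "A", "B", "A")),
               c("A", "A_2", "B", "A_3"))
})

test_that("format_description lists every term with its level and inverts cleanly", {
  dag <- two_term_dag()
  depths <- compute_depths(dag)
  idx <- make_index(list(`GO:0000002` = c("g1", "g2"),
                         `GO:0000003` = c("g1", "g2")))
  set <- collapse_duplicates(idx, depths, dag)[[1]]
  desc <- format_description(set)
  expect_match(desc, "muscle system process [level 1]", fixed = TRUE)
  expect_match(desc, "muscle contraction [level 2]", fixed = TRUE)
  parsed <- parse_description(desc)
  expect_equal(parsed, set$all_terms)

  single <- set
  single$all_terms <- data.frame(term_id = "GO:0000001", name = "x",
                                 depth = 4L, stringsAsFactors = FALSE)
  expect_equal(format_description(single), "GO:0000001 x [level 4]")
})

fixture_collection <- function(seed = 5) {
  spec <- fixture_spec(n_terms = 80L, n_genes = 50L, n_assocs = 250L,
                       seed = seed)
  ont <- make_ontology(spec)
  dag <- parse_obo(ont$obo)
  res <- resolve_associations(
    read_gene2go(make_associations(spec, ont, "gene2go")$text, taxon = 10090),
    dag)
  idx <- size_filter(propagate(build_index(res$associations), dag), 2, 700)
  geneset_collection(collapse_duplicates(idx, compute_depths(dag), dag),
                     warnings = res$counters)
}

test_that("write_gmt emits one well-formed line per set and round-trips", {
  col <- fixture_collection()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, path)
  back <- read_gmt_lines(path)
  expect_length(back, length(col$sets))
  for (i in seq_along(col$sets)) {
    expect_equal(back[[i]]$set_name, col$sets[[i]]$set_name)
    expect_equal(back[[i]]$genes, col$sets[[i]]$genes)
    # field 2 carries the URL followed by the full description
    expect_equal(back[[i]]$field2,
                 paste(col$sets[[i]]$url, format_description(col$sets[[i]])))
  }
  # no trailing tabs, newline-terminated
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  expect_false(grepl("\t\n", raw, fixed = TRUE))
  expect_equal(substr(raw, nchar(raw), nchar(raw)), "\n")

  # single 2-gene set: exactly 4 tab-separated fields
  one <- geneset_collection(col$sets[which(
    vapply(col$sets, function(s) length(s$genes), integer(1)) == 2)[1]])
  write_gmt(one, path)
  expect_length(strsplit(readLines(path), "\t")[[1]], 4L)

  # url_only style
  write_gmt(col, path, description = "url_only")
  expect_equal(read_gmt_lines(path)[[1]]$field2, col$sets[[1]]$url)
})

test_that("write_gmx is the exact transpose of write_gmt", {
  col <- fixture_collection()
  gmt <- withr::local_tempfile(fileext = ".gmt")
  gmx <- withr::local_tempfile(fileext = ".gmx")
  write_gmt(col, gmt)
  write_gmx(col, gmx)
  a <- read_gmt_lines(gmt)
  b <- read_gmx_lines(gmx)
  expect_equal(a, b)
  # row count = 2 header rows + size of the largest set
  expect_length(readLines(gmx),
                2L + max(vapply(col$sets, function(s) length(s$genes),
                                integer(1))))
  # gene conservation across gmt lines
  expect_setequal(unique(unlist(lapply(a, `[[`, "genes"))),
                  unique(unlist(lapply(col$sets, `[[`, "genes"))))

  # empty collection: zero columns, error-free
  empty <- geneset_collection(list())
  write_gmx(empty, gmx)
  expect_length(readLines(gmx), 0L)
  write_gmt(empty, gmt)
  expect_length(readLines(gmt), 0L)
})

test_that("collapsing matches a brute-force grouping oracle on fixtures", {
  for (seed in c(2, 4)) {
    spec <- fixture_spec(n_terms = 120L, n_genes = 40L, n_assocs = 300L,
                         seed = seed)
    ont <- make_ontology(spec)
    dag <- parse_obo(ont$obo)
    res <- resolve_associations(
      read_gene2go(make_associations(spec, ont, "gene2go")$text,
                   taxon = 10090), dag)
    idx <- size_filter(propagate(build_index(res$associations), dag), 2, 700)
    sets <- collapse_duplicates(idx, compute_depths(dag), dag)
    distinct <- unique(lapply(idx$members, function(g) paste(sort(g),
                                                             collapse = ";")))
    expect_length(sets, length(distinct))
    # every term of the filtered index appears in exactly one set
    listed <- unlist(lapply(sets, function(s) s$all_terms$term_id))
    expect_setequal(listed, names(idx$members))
    expect_false(anyDuplicated(listed) > 0)
  }
})

test_that("collections reject duplicate content or names", {
  col <- fixture_collection()
  expect_error(geneset_collection(c(col$sets, col$sets[1])),
               class = "gosets_validation_error")
  s2 <- col$sets[[2]]
  s2$set_name <- col$sets[[1]]$set_name
  expect_error(geneset_collection(c(col$sets[1], list(s2))),
               class = "gosets_validation_error")
})
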