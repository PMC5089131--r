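test_that("TSV tables parse with missing cells, transposition and id checks", {
  path <- write_tsv_fixture(
    rows = c("r1\t1\t2\t3\t4", "r2\t5\t\t7\t8", "r3\t9\t10\t11\t12"),
    header = c("s1", "s2", "s3", "s4"))
  tab <- read_tsv_table(path)
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(sum(is.na(tab$values)), 1L)
  expect_true(is.na(tab$values["r2", "s2"]))
  expect_equal(tab$values["r1", "s3"], 3)

  flipped <- read_tsv_table(path, transpose = TRUE)
  expect_equal(dim(flipped), c(4L, 3L))
  expect_equal(flipped$values["s3", "r1"], 3)

  dup <- write_tsv_fixture(rows = c("r1\t1\t2", "r1\t3\t4"),
                           header = c("s1", "s2"))
  expect_error(read_tsv_table(dup), "r1")

  txt <- write_tsv_fixture(rows = c("r1\t1\tabc", "r2\t3\t4"),
                           header = c("s1", "s2"))
  expect_error(read_tsv_table(txt), "r1.*s2|s2.*r1")

  na_tokens <- write_tsv_fixture(rows = c("r1\tNA\tnan", "r2\t3\t4"),
                                 header = c("s1", "s2"))
  expect_equal(sum(is.na(read_tsv_table(na_tokens)$values)), 2L)
})

test_that("biom JSON files yield dense values and parsed lineages", {
  skip_if_not_installed("biomformat")
  tab <- read_biom(write_biom_fixture())
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(unname(tab$values["OTU1", ]), c(5, 2))
  expect_equal(unname(tab$values["OTU2", ]), c(0, 7))
  lin <- tab$lineage[["OTU1"]]
  expect_length(lin, 7L)
  expect_equal(names(lin),
               c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species"))
  expect_equal(unname(lin[["species"]]), "Lactobacillus acidophilus")

  bare <- read_biom(write_biom_fixture(taxonomy = FALSE))
  expect_true(all(vapply(bare$lineage, is.null, logical(1))))
})

test_that("lineage parsing handles prefixes, positions, gaps and round trips", {
  lin <- parse_lineage(paste0(
    "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; ",
    "f__Lactobacillaceae; g__Lactobacillus; s_Lactobacillus acidophilus"))
  expect_length(lin, 7L)
  expect_equal(unname(lin[["kingdom"]]), "Bacteria")
  expect_equal(unname(lin[["order"]]), "Lactobacillales")
  expect_equal(unname(lin[["species"]]), "Lactobacillus acidophilus")

  pos <- parse_lineage("Bacteria;Firmicutes")
  expect_equal(pos, c(kingdom = "Bacteria", phylum = "Firmicutes"))

  gap <- parse_lineage("k__Bacteria; p__; c__")
  expect_equal(gap, c(kingdom = "Bacteria"))

  # idempotence on the canonical rendering
  expect_equal(parse_lineage(format_lineage(lin)), lin)
  expect_equal(format_lineage(empty <- parse_lineage("")), "")
  expect_length(empty, 0L)
})

test_that("sample metadata merges into extra rows, matched by sample id", {
  cids <- sprintf("S%02d", 1:10)
  tab <- abundance_table(toy_matrix(seq_len(30), c("a", "b", "c"), cids))
  ph <- abundance_table(toy_matrix(seq(4, 8.5, by = 0.5), "ph", cids))
  merged <- merge_feature_rows(tab, ph)
  expect_equal(nrow(merged$values), 4L)
  expect_equal(unname(merged$group["ph"]), "metadata")
  expect_equal(unname(merged$values["ph", "S03"]), 5)

  ph8 <- abundance_table(toy_matrix(1:8, "ph", cids[1:8]))
  expect_message(m8 <- merge_feature_rows(tab, ph8, match_samples = TRUE),
                 "dropped 2")
  expect_equal(ncol(m8$values), 8L)

  alien <- abundance_table(toy_matrix(1:3, "ph", c("X1", "X2", "X3")))
  expect_error(merge_feature_rows(tab, alien, match_samples = TRUE),
               "overlap")
})

test_that("matrix properties report sparsity and give rule-based advice", {
  uneven <- abundance_table(toy_matrix(c(40, 80, 60, 120), c("a", "b"),
                                       c("s1", "s2")))
  rep1 <- matrix_properties(uneven)
  expect_equal(rep1$min_col_sum, 100)
  expect_equal(rep1$max_col_sum, 200)
  expect_true(any(grepl("normalization", rep1$recommendations)))

  even <- abundance_table(toy_matrix(c(1, 2, 3, 3, 2, 1), c("a", "b"),
                                     c("s1", "s2", "s3")))
  expect_length(matrix_properties(even)$recommendations, 0L)

  v <- toy_matrix(c(1, NA, 3, 4), c("a", "b"), c("s1", "s2"))
  expect_equal(matrix_properties(abundance_table(v))$missing_count, 1L)
})

test_that("settings bundles round-trip exactly and render as command lines", {
  s <- default_settings()
  s[c("input", "measures", "edge_number", "col_norm", "row_minocc",
      "resample", "iterations", "renormalize", "pmerge", "multitest",
      "minsupport", "seed")] <-
    c("table.tsv", "pearson,spearman", "500", "true", "20",
      "shuffle_rows", "100", "true", "brown", "benjaminihochberg",
      "2", "42")
  f <- tempfile(fileext = ".settings")
  write_settings(s, f)
  expect_identical(read_settings(f), s)

  cmd <- generate_command_line(s)
  expect_match(cmd, "--input 'table.tsv'", fixed = TRUE)
  expect_match(cmd, "--edge-number '500'", fixed = TRUE)
  expect_match(cmd, "--col-norm( |$)")
  expect_false(grepl("--output", cmd))  # defaults stay out

  writeLines(c("# comment", "edge_numberr=5"), bad <- tempfile())
  expect_error(read_settings(bad), "edge_numberr")
  expect_error(write_settings(c(nonsense = "1"), tempfile()), "nonsense")
})

test_that("adjacency matrices import as undirected weighted networks", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("\tA\tB\tC", "A\t0\t0.7\t0", "B\t0.7\t0\t0", "C\t0\t0\t0"),
             path)
  net <- read_adjacency_matrix(path)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$source, "A")
  expect_equal(net$edges$target, "B")
  expect_equal(net$edges$weight, 0.7)

  writeLines(c("\tA\tB", "A\t0\t0", "B\t0\t0"), z <- tempfile())
  expect_equal(nrow(read_adjacency_matrix(z)$edges), 0L)

  writeLines(c("\tA\tB", "A\t0\t0.5", "B\t-0.5\t0"), a <- tempfile())
  expect_warning(asym <- read_adjacency_matrix(a), "upper triangle")
  expect_equal(asym$edges$weight, 0.5)

  writeLines(c("\tA\tB\tC", "A\t0\t1\t0", "B\t1\t0\t0"), ns <- tempfile())
  expect_error(read_adjacency_matrix(ns), "square")
})

test_that("GML export round-trips nodes, edges, signs and numbers", {
  nodes <- data.frame(id = c("A", "B", "C"), stringsAsFactors = FALSE)
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      sign = c("positive", "negative"),
                      weight = c(0.123456789012345, 2e-7),
                      p = c(0.001, 0.04),
                      stringsAsFactors = FALSE)
  net <- assoc_network(nodes, edges)
  f <- tempfile(fileext = ".gml")
  write_network(net, f, format = "gml")
  back <- read_network_gml(f)
  expect_setequal(back$nodes$id, nodes$id)
  expect_equal(back$edges[order(back$edges$source), c("source", "target")],
               edges[c("source", "target")], ignore_attr = TRUE)
  ord <- order(back$edges$source)
  expect_equal(back$edges$weight[ord], edges$weight, tolerance = 1e-12)
  expect_equal(back$edges$sign[ord], edges$sign)

  d <- tempfile(fileext = ".dot")
  write_network(net, d, format = "dot")
  dot <- readLines(d)
  expect_true(any(grepl('"B" -- "C" \\[color=red\\]', dot)))
  expect_true(any(grepl("color=green", dot)))

  empty <- assoc_network(data.frame(id = character(0)))
  g0 <- tempfile(fileext = ".gml")
  write_network(empty, g0, format = "gml")
  expect_equal(nrow(read_network_gml(g0)$edges), 0L)

  e <- tempfile(fileext = ".tsv")
  write_network(net, e, format = "edge_tsv")
  lines <- readLines(e)
  expect_length(lines, 3L)
  expect_match(lines[1], "^source\ttarget\tsign")
})
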