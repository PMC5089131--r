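cand <- function(a, b, measure, score, sign) {
  data.frame(a = a, b = b, measure = measure, score = score, sign = sign,
             stringsAsFactors = FALSE)
}

test_that("the multigraph keeps one edge per supporting measure", {
  sets <- list(
    pearson = cand("A", "B", "pearson", 0.9, "positive"),
    spearman = cand("A", "B", "spearman", 0.8, "positive"),
    kendall = cand("A", "B", "kendall", 0.7, "positive"),
    bray_curtis = cand("A", "B", "bray_curtis", 0.1, "positive"),
    mutual_information = cand("A", "B", "mutual_information", 1.2, "unsigned"))
  mg <- build_multigraph(sets)
  expect_true(mg$multigraph)
  expect_equal(nrow(mg$edges), 5L)
  expect_setequal(mg$edges$measure, names(sets))

  disjoint <- list(pearson = cand("A", "B", "pearson", 0.9, "positive"),
                   spearman = cand("C", "D", "spearman", 0.8, "positive"))
  expect_equal(nrow(build_multigraph(disjoint)$edges), 2L)

  single <- list(pearson = cand(c("A", "B"), c("B", "C"), "pearson",
                                c(0.9, -0.8), c("positive", "negative")))
  mg1 <- build_multigraph(single)
  m1 <- merge_edges(single)
  expect_equal(nrow(mg1$edges), nrow(m1$edges))
  expect_equal(mg1$edges[c("source", "target", "sign")],
               m1$edges[c("source", "target", "sign")])
})

test_that("minsupport voting retains edges by support and discards sign conflicts", {
  sets <- list(
    pearson = cand(c("A", "C"), c("B", "D"), "pearson", c(0.9, 0.8),
                   c("positive", "positive")),
    spearman = cand(c("A", "C"), c("B", "D"), "spearman", c(0.85, 0.7),
                    c("positive", "positive")),
    kendall = cand("A", "B", "kendall", 0.6, "positive"),
    bray_curtis = cand("C", "D", "bray_curtis", 0.95, "negative"))
  # A-B: support 3, all positive; C-D: support 3 but signs disagree
  m3 <- merge_edges(sets, minsupport = 3)
  expect_equal(nrow(m3$edges), 1L)
  expect_equal(m3$edges$source, "A")
  expect_equal(m3$edges$sign, "positive")
  expect_equal(m3$edges$support, 3L)

  # sign conflict discards regardless of support
  m1 <- merge_edges(sets, minsupport = 1)
  expect_false("C" %in% m1$edges$source)

  expect_error(merge_edges(sets, minsupport = 5), "minsupport")
})

test_that("unsigned measures are neutral and inherit the signed consensus", {
  sets <- list(
    mutual_information = cand("A", "B", "mutual_information", 1.5,
                              "unsigned"),
    pearson = cand("A", "B", "pearson", 0.9, "positive"),
    spearman = cand("A", "B", "spearman", 0.8, "positive"))
  m <- merge_edges(sets, minsupport = 3)
  expect_equal(nrow(m$edges), 1L)
  expect_equal(m$edges$sign, "positive")
  expect_equal(m$edges$support, 3L)

  only_mi <- merge_edges(sets["mutual_information"])
  expect_equal(only_mi$edges$sign, "unsigned")
})

test_that("voting thresholds nest and intersection equals full support", {
  set.seed(17)
  measures <- c("pearson", "spearman", "kendall")
  ids <- sprintf("n%02d", 1:8)
  all_pairs <- t(utils::combn(ids, 2))
  sets <- lapply(measures, function(m) {
    take <- sample(nrow(all_pairs), 15)
    cand(all_pairs[take, 1], all_pairs[take, 2], m, runif(15, 0.5, 1),
         "positive")
  })
  names(sets) <- measures
  prev <- NULL
  for (k in 1:3) {
    ek <- merge_edges(sets, minsupport = k)$edges
    keys <- paste(ek$source, ek$target)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
    # no output pair that no measure proposed
    proposed <- unlist(lapply(sets, function(s) paste(s$a, s$b)))
    expect_true(all(keys %in% proposed))
  }
  inter <- merge_edges(sets, intersection = TRUE)$edges
  expect_setequal(paste(inter$source, inter$target), prev)
})

test_that("combined edge weights prefer q, then mean oriented score", {
  row_q <- data.frame(q = 0.01, score_pearson = 0.8)
  expect_equal(combined_edge_weight(row_q, "pearson"), 0.01)
  row2 <- data.frame(score_pearson = 0.8, score_spearman = 0.6)
  expect_equal(combined_edge_weight(row2, c("pearson", "spearman")), 0.7)
  row_mi <- data.frame(score_mutual_information = 1.3)
  expect_equal(combined_edge_weight(row_mi, "mutual_information"), 1.3)
})

test_that("node annotation computes degrees, abundance stats and rank attributes", {
  tab <- lacto_table()
  tab$values["Lactobacillales", ] <- c(0, 2, 5)
  tab$values["Lactobacillaceae", 3] <- NA
  nodes <- data.frame(id = rownames(tab$values), stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("Lactobacillaceae", "Lactobacillaceae", "Lactobacillales"),
    target = c("Lactobacillales", "Ureaplasma", "Ureaplasma"),
    sign = c("positive", "positive", "negative"),
    weight = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  net <- annotate_nodes(assoc_network(nodes, edges), tab)
  nd <- net$nodes
  lb <- nd[nd$id == "Lactobacillaceae", ]
  expect_equal(lb$degree, 2L)
  expect_equal(lb$posdegree, 2L)
  expect_equal(lb$negdegree, 0L)
  expect_equal(nd$degree, nd$posdegree + nd$negdegree + nd$unsigneddegree)
  expect_equal(lb$rowsum, 4 + 5)
  expect_equal(lb$prevalence, 2L)
  expect_equal(nd$rowsum[nd$id == "Lactobacillales"], 7)
  expect_equal(nd$prevalence[nd$id == "Lactobacillales"], 2L)
  expect_equal(lb$family, "Lactobacillaceae")
  expect_equal(nd$genus[nd$id == "Ureaplasma"], "Ureaplasma")
  expect_equal(nd$order[nd$id == "Lactobacillales"], "Lactobacillales")

  # idempotent
  again <- annotate_nodes(net, tab)
  expect_identical(again$nodes, net$nodes)
})

test_that("positive-edge filtering drops the rest and isolated nodes, idempotently", {
  nodes <- data.frame(id = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  edges <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "D"),
                      sign = c("positive", "negative", "positive"),
                      weight = 1:3, stringsAsFactors = FALSE)
  net <- assoc_network(nodes, edges)
  pos <- filter_positive_edges(net)
  expect_equal(nrow(pos$edges), 2L)
  expect_setequal(pos$nodes$id, c("A", "B", "D"))
  expect_identical(filter_positive_edges(pos)$edges, pos$edges)

  allneg <- assoc_network(nodes[1:2, , drop = FALSE],
                          data.frame(source = "A", target = "B",
                                     sign = "negative", weight = 1,
                                     stringsAsFactors = FALSE))
  emptied <- filter_positive_edges(allneg)
  expect_equal(nrow(emptied$edges), 0L)
  expect_equal(nrow(emptied$nodes), 0L)
})

test_that("network invariants are enforced at construction", {
  nodes <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  expect_error(assoc_network(nodes, data.frame(source = "A", target = "A",
                                               stringsAsFactors = FALSE)),
               "self-loop")
  expect_error(assoc_network(nodes, data.frame(source = "A", target = "Z",
                                               stringsAsFactors = FALSE)),
               "missing")
  dup <- data.frame(source = c("A", "A"), target = c("B", "B"),
                    stringsAsFactors = FALSE)
  expect_error(assoc_network(nodes, dup), "parallel")
  expect_silent(assoc_network(nodes, dup, multigraph = TRUE))
})
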