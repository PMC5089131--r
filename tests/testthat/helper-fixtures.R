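# Small in-code fixtures shared across test files.

# object-by-sample matrix with named dims
toy_matrix <- function(vals, rids, cids) {
  matrix(vals, nrow = length(rids), byrow = TRUE,
         dimnames = list(rids, cids))
}

# write a TSV table file (first column = object ids, header = sample ids)
write_tsv_fixture <- function(rows, header, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(c("id", header), collapse = "\t"), rows), path)
  path
}

# minimal sparse biom (JSON 1.0) file
write_biom_fixture <- function(path = tempfile(fileext = ".biom"),
                               taxonomy = TRUE) {
  rows <- if (taxonomy) paste0(
    '{"id":"OTU1","metadata":{"taxonomy":["k__Bacteria","p__Firmicutes",',
    '"c__Bacilli","o__Lactobacillales","f__Lactobacillaceae",',
    '"g__Lactobacillus","s__Lactobacillus acidophilus"]}},',
    '{"id":"OTU2","metadata":{"taxonomy":["k__Bacteria","p__Proteobacteria"]}}')
  else '{"id":"OTU1","metadata":null},{"id":"OTU2","metadata":null}'
  writeLines(paste0(
    '{"id":null,"format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org",',
    '"type":"OTU table","generated_by":"fixture","date":"2026-01-01T00:00:00",',
    '"rows":[', rows, '],',
    '"columns":[{"id":"S1","metadata":null},{"id":"S2","metadata":null}],',
    '"matrix_type":"sparse","matrix_element_type":"int","shape":[2,2],',
    '"data":[[0,0,5],[0,1,2],[1,1,7]]}'), path)
  path
}

# lineage helpers for parent-child tests
lacto_table <- function() {
  v <- toy_matrix(c(1, 2, 3,
                    4, 5, 6,
                    7, 8, 9), c("Lactobacillales", "Lactobacillaceae",
                                "Ureaplasma"),
                  c("S1", "S2", "S3"))
  abundance_table(
    v,
    lineage = list(
      Lactobacillales = parse_lineage("k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales"),
      Lactobacillaceae = parse_lineage("k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae"),
      Ureaplasma = parse_lineage("k__Bacteria; p__Tenericutes; c__Mollicutes; o__Mycoplasmatales; f__Mycoplasmataceae; g__Ureaplasma")),
    level = c(Lactobacillales = "order", Lactobacillaceae = "family",
              Ureaplasma = "genus"))
}

# random nonnegative abundance vectors
random_abundance <- function(n, zero_frac = 0.3) {
  x <- stats::rexp(n, rate = 0.2)
  x[stats::runif(n) < zero_frac] <- 0
  x
}

# brute-force tau-b (tie-corrected Kendall), quadratic enumeration
taub_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive hypergeometric co-presence tail: probability that a uniformly
# random placement of y's presences attains at least the observed overlap
hyper_bruteforce <- function(x, y) {
  xb <- x > 0; yb <- y > 0
  n <- length(x); m2 <- sum(yb); k_obs <- sum(xb & yb)
  if (m2 == 0) return(1)
  sets <- utils::combn(n, m2)
  hits <- apply(sets, 2, function(s) sum(xb[s]) >= k_obs)
  mean(hits)
}

# brute-force Benjamini-Hochberg step-up q-values
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
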