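sim_small <- function(seed = 3) {
  sim <- simulate_community(n_taxa = 12, n_samples = 40, n_pos = 2,
                            n_neg = 1, seed = seed)
  normalize_columns(sim$table)
}

test_that("permutation distributions have the right shape and are seeded", {
  tab <- sim_small()
  pairs <- eligible_pairs(tab)[1:4, ]
  st <- permutation_distribution(tab, c("spearman", "bray_curtis"), pairs,
                                 iterations = 25, renormalize = TRUE,
                                 seed = 10)
  expect_equal(st$kind, "permutation")
  expect_length(st$scores, 8L)
  expect_true(all(lengths(st$scores) == 25L))
  st2 <- permutation_distribution(tab, c("spearman", "bray_curtis"), pairs,
                                  iterations = 25, renormalize = TRUE,
                                  seed = 10)
  expect_identical(st$scores, st2$scores)
  st3 <- permutation_distribution(tab, c("spearman", "bray_curtis"), pairs,
                                  iterations = 25, renormalize = TRUE,
                                  seed = 11)
  expect_false(identical(st$scores, st3$scores))

  raw <- simulate_community(n_taxa = 12, n_samples = 20, n_pos = 2,
                            n_neg = 1, seed = 4)$table
  expect_warning(permutation_distribution(raw, "spearman", pairs[1, ],
                                          iterations = 2,
                                          renormalize = TRUE, seed = 1),
                 "unit column sums")
})

test_that("renormalized permutation keeps unit column sums at every iteration", {
  # renormalization contract checked directly on the column-sum update the
  # null uses: swap a permuted pair into the matrix, re-close the columns
  tab <- sim_small()
  v <- tab$values
  cs <- colSums(v)
  set.seed(99)
  for (it in 1:20) {
    i <- sample(nrow(v), 2)
    pi <- sample(v[i[1], ]); pj <- sample(v[i[2], ])
    vv <- v
    vv[i[1], ] <- pi; vv[i[2], ] <- pj
    ncs <- cs - v[i[1], ] - v[i[2], ] + pi + pj
    expect_equal(unname(colSums(vv)), unname(ncs), tolerance = 1e-12)
    expect_true(all(abs(colSums(sweep(vv, 2, ncs, "/")) - 1) < 1e-9))
  }
})

test_that("bootstrap distributions track the observed score of a planted pair", {
  sim <- simulate_community(n_taxa = 12, n_samples = 100, n_pos = 2,
                            n_neg = 1, effect = 0.9, seed = 8)
  tab <- normalize_columns(sim$table)
  pair <- sim$truth$edges[sim$truth$edges$sign == "positive", ][1, c("a", "b")]
  obs <- compute_measure("pearson", tab$values[pair$a, ], tab$values[pair$b, ])
  st <- bootstrap_distribution(tab, "pearson", pair, iterations = 60,
                               seed = 5)
  boot <- st$scores[[paste(pair$a, pair$b, "pearson", sep = "||")]]
  expect_length(boot, 60L)
  expect_lt(abs(mean(boot) - obs), 2 * sd(boot))
  st2 <- bootstrap_distribution(tab, "pearson", pair, iterations = 60,
                                seed = 5)
  expect_identical(st$scores, st2$scores)
})

test_that("empirical permutation p-values follow the add-one tail formula", {
  null <- seq(-0.9, 0.9, length.out = 99)
  expect_equal(permutation_pvalue(0.95, null, "upper"), 1 / 100)
  expect_equal(permutation_pvalue(-0.95, null, "lower"), 1 / 100)
  p_med <- permutation_pvalue(0, null, "upper")
  expect_lt(abs(p_med - 0.5), 0.02)
  set.seed(2)
  for (i in 1:20) {
    p <- permutation_pvalue(rnorm(1), rnorm(50), "two_sided")
    expect_gte(p, 1 / 51)
    expect_lte(p, 1)
  }
})

test_that("parametric permutation-vs-bootstrap p-values behave like normal tails", {
  null <- rnorm(200, 0, 0.1)
  mu0 <- mean(null); s0 <- sd(null)
  expect_equal(reboot_pvalue(null, rep(mu0, 50)), 1)
  p196 <- reboot_pvalue(null, rep(mu0 + 1.96 * s0, 50))
  expect_lt(abs(p196 - 0.05), 0.001)
  expect_warning(pdeg <- reboot_pvalue(rep(0.3, 10), c(0.5, 0.6)),
                 "degenerate")
  expect_equal(pdeg, 1)

  # planted association in a seeded simulation
  sim <- simulate_community(n_taxa = 15, n_samples = 80, n_pos = 2,
                            n_neg = 1, seed = 12)
  tab <- normalize_columns(sim$table)
  planted <- sim$truth$edges[1, c("a", "b")]
  key <- function(a, b) paste(a, b, "spearman", sep = "||")
  nl <- permutation_distribution(tab, "spearman", planted, iterations = 80,
                                 renormalize = TRUE, seed = 3)
  bt <- bootstrap_distribution(tab, "spearman", planted, iterations = 80,
                               seed = 3)
  p_planted <- reboot_pvalue(nl$scores[[key(planted$a, planted$b)]],
                             bt$scores[[key(planted$a, planted$b)]])
  expect_lt(p_planted, 0.01)

  # pairs from a structure-free community are not systematically called:
  # p-values spread over (0, 1] instead of collapsing near zero
  null_sim <- simulate_community(n_taxa = 30, n_samples = 80, n_pos = 0,
                                 n_neg = 0, seed = 13)
  ntab <- normalize_columns(null_sim$table)
  rand <- eligible_pairs(ntab)[c(10, 80, 150, 220, 300, 380), ]
  nl0 <- permutation_distribution(ntab, "spearman", rand, iterations = 80,
                                  renormalize = TRUE, seed = 3)
  bt0 <- bootstrap_distribution(ntab, "spearman", rand, iterations = 80,
                                seed = 3)
  p_rand <- vapply(seq_len(nrow(rand)), function(i)
    reboot_pvalue(nl0$scores[[key(rand$a[i], rand$b[i])]],
                  bt0$scores[[key(rand$a[i], rand$b[i])]]), numeric(1))
  expect_gt(median(p_rand), 0.05)
})

test_that("the bootstrap stability filter keeps separated edges only", {
  boot <- seq(0.5, 0.8, length.out = 101)
  expect_true(stability_filter(0.0, boot, level = 0.95))
  boot2 <- seq(-0.1, 0.9, length.out = 101)
  expect_false(stability_filter(0.0, boot2, level = 0.95))
  expect_false(stability_filter(0.5, boot2, level = 1.0))
  expect_true(stability_filter(-0.2, boot2, level = 1.0))
})

test_that("fisher and brown merging match their chi-square forms", {
  # X = -4 ln 0.05, upper chi-square(4) tail
  expect_equal(merge_pvalues(c(0.05, 0.05), "fisher"),
               pchisq(-2 * sum(log(c(0.05, 0.05))), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(merge_pvalues(c(0.05, 0.05), "fisher") - 0.0175), 3e-3)

  # with zero correlation, brown collapses to fisher
  set.seed(6)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p <- runif(k, 0.001, 1)
    expect_equal(merge_pvalues(p, "brown", r = diag(k)),
                 merge_pvalues(p, "fisher"), tolerance = 1e-9)
  }

  # perfectly redundant measures: merged p stays near the single-measure p
  r1 <- matrix(1, 2, 2)
  for (p in c(0.001, 0.01, 0.2, 0.7))
    expect_equal(merge_pvalues(c(p, p), "brown", r = r1), p,
                 tolerance = 1e-9)

  expect_equal(merge_pvalues(0.03, "brown"), 0.03)
  expect_error(merge_pvalues(c(0, 0.5), "fisher"), "0, 1")
})

test_that("multiple-testing corrections match hand and brute-force oracles", {
  expect_equal(correct_multiple_testing(c(0.01, 0.5), "bonferroni", m = 2),
               c(0.02, 1.0))
  expect_equal(correct_multiple_testing(c(0.01, 0.02, 0.03, 0.04),
                                        "benjaminihochberg"),
               rep(0.04, 4))
  set.seed(14)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))
    q <- correct_multiple_testing(p, "benjaminihochberg")
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    qb <- correct_multiple_testing(p, "bonferroni")
    expect_true(all(qb >= p))
    # BH q non-increasing when read from largest p downwards
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("resampling stores survive a file round trip bit-for-bit", {
  tab <- sim_small()
  pairs <- eligible_pairs(tab)[c(1, 5, 9), ]
  st <- permutation_distribution(tab, c("spearman", "bray_curtis"), pairs,
                                 iterations = 15, renormalize = TRUE,
                                 seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_resampling_store(st, f)
  back <- read_resampling_store(f)
  expect_equal(back$kind, st$kind)
  expect_equal(back$iterations, st$iterations)
  expect_equal(back$seed, st$seed)
  expect_setequal(names(back$scores), names(st$scores))
  for (k in names(st$scores))
    expect_identical(back$scores[[k]], st$scores[[k]])
  expect_error(read_resampling_store(tempfile()), "not found")
})

test_that("permutation p-values are uniform when there is nothing to find", {
  # independent rows, no planted structure, no closure
  set.seed(20)
  n_draws <- 400
  v <- matrix(rlnorm(40 * 30), 40,
              dimnames = list(sprintf("r%02d", 1:40), sprintf("s%02d", 1:30)))
  tab <- abundance_table(v)
  pairs <- eligible_pairs(tab)[seq_len(n_draws), ]
  st <- permutation_distribution(tab, "pearson", pairs, iterations = 49,
                                 seed = 5)
  obs <- score_all_pairs(tab, "pearson", pairs)$pearson$scores
  ps <- vapply(seq_len(n_draws), function(i)
    permutation_pvalue(obs$score[i],
                       st$scores[[paste(obs$a[i], obs$b[i], "pearson",
                                        sep = "||")]], "upper"),
    numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
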