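test_that("Jaccard index handles the standard cases", {
  expect_equal(jaccard_index(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_index(c("A", "B"), c("B", "A")), 1)
  expect_equal(jaccard_index(c("A"), c("B")), 0)
  expect_equal(jaccard_index(character(0), c("A")), 0)
  expect_error(jaccard_index(character(0), character(0)), "empty")
})

test_that("Jaccard is symmetric and non-increasing under disjoint padding", {
  set.seed(7)
  for (i in 1:10) {
    a <- sample(LETTERS, sample(3:10, 1))
    b <- sample(LETTERS, sample(3:10, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    padded <- c(a, paste0("pad", 1:3))  # new elements not in b
    expect_lte(jaccard_index(padded, b), jaccard_index(a, b))
  }
})

test_that("disease similarity matrix reflects module-union overlap", {
  mk <- function(trait, genes) module_catalog(trait, list(genes), TRUE)
  m <- disease_similarity_matrix(list(mk("t1", LETTERS[1:6]),
                                      mk("t2", LETTERS[4:9])))
  expect_equal(m["t1", "t2"], 3 / 9)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(t1 = 1, t2 = 1))

  ident <- disease_similarity_matrix(list(mk("a", c("X", "Y")),
                                          mk("b", c("Y", "X"))))
  expect_equal(ident["a", "b"], 1)

  disjoint <- disease_similarity_matrix(list(mk("a", "P"), mk("b", "Q"),
                                             mk("c", "R")))
  expect_equal(unname(disjoint), diag(3))

  none <- module_catalog("empty", list(LETTERS[1:12]), FALSE)
  expect_warning(m2 <- disease_similarity_matrix(list(mk("a", "P"), none)),
                 "zero significant")
  expect_equal(unname(m2["a", "empty"]), 0)
})

test_that("module grouping links cross-trait chains above the threshold", {
  g1 <- sprintf("G%02d", 1:20)
  g2 <- c(sprintf("G%02d", 1:18), "H1", "H2")            # J(g1,g2) = 18/22
  g3 <- c(sprintf("G%02d", 1:17), "H1", "H2", "H3")       # J(g2,g3) = 19/21
  c1 <- module_catalog("t1", list(g1), TRUE)
  c2 <- module_catalog("t2", list(g2), TRUE)
  c3 <- module_catalog("t3", list(g3), TRUE)
  groups <- group_shared_modules(list(c1, c2, c3), threshold = 0.7)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$traits_covered, c("t1", "t2", "t3"))
  expect_equal(nrow(groups[[1]]$members), 3)

  # identical modules in two traits form a group; J = 0.5 does not reach 0.7
  same <- group_shared_modules(list(module_catalog("x", list(g1), TRUE),
                                    module_catalog("y", list(g1), TRUE)), 0.7)
  expect_length(same, 1)
  half <- group_shared_modules(list(
    module_catalog("x", list(LETTERS[1:12]), TRUE),
    module_catalog("y", list(LETTERS[5:16]), TRUE)), 0.7)  # J = 8/16
  expect_length(half, 0)
})

test_that("within-trait pairs never form groups", {
  g1 <- sprintf("G%02d", 1:20)
  one_trait <- module_catalog("t1", list(g1, g1), c(TRUE, TRUE))
  expect_length(group_shared_modules(list(one_trait), 0.7), 0)
})

test_that("groups at a higher threshold refine groups at a lower one", {
  core <- sprintf("G%02d", 1:20)
  cats <- list(
    module_catalog("t1", list(core), TRUE),
    module_catalog("t2", list(core), TRUE),                       # J = 1
    module_catalog("t3", list(c(core[1:14], paste0("H", 1:6))), TRUE))
  lo <- group_shared_modules(cats, 0.3)   # 14/26 = 0.54 links t3 in
  hi <- group_shared_modules(cats, 0.7)   # only the identical pair remains
  expect_length(lo, 1)
  expect_length(hi, 1)
  expect_equal(lo[[1]]$traits_covered, c("t1", "t2", "t3"))
  expect_equal(hi[[1]]$traits_covered, c("t1", "t2"))
  key <- function(g) paste(g$members$trait, g$members$module, sep = ":")
  expect_true(all(key(hi[[1]]) %in% key(lo[[1]])))

  # and on random catalogs every high-threshold group sits inside some
  # low-threshold group
  set.seed(12)
  rcats <- lapply(1:4, function(i) {
    mods <- lapply(1:3, function(j) sample(sprintf("G%03d", 1:40), 25))
    module_catalog(paste0("t", i), mods, rep(TRUE, 3))
  })
  rlo <- group_shared_modules(rcats, 0.2)
  rhi <- group_shared_modules(rcats, 0.35)
  expect_gte(length(rlo), 1)
  for (gh in rhi) {
    containing <- vapply(rlo, function(gl) all(key(gh) %in% key(gl)), TRUE)
    expect_true(any(containing))
  }
})

test_that("Fisher enrichment matches the hypergeometric tail oracle", {
  background <- sprintf("G%03d", 1:100)
  annotation <- list(term_full = background,
                     term_hit = background[1:10],
                     term_absent = c("ZZZ1", "ZZZ2"))
  query <- background[1:5]
  res <- fisher_enrichment(query, annotation, background)
  expect_false("term_absent" %in% res$term)  # zero background hits skipped
  expect_equal(res$p_raw[res$term == "term_full"], 1)
  p_hit <- res$p_raw[res$term == "term_hit"]
  expect_equal(p_hit, hyper_tail_oracle(5, 10, 5, 100), tolerance = 1e-12)
  expect_equal(p_hit, choose(10, 5) / choose(100, 5), tolerance = 1e-12)
})

test_that("Fisher p agrees with fisher.test and is monotone in k", {
  N <- 80; K <- 15; n <- 12
  background <- sprintf("B%02d", 1:N)
  prev <- 0
  for (k in c(8, 6, 4, 2)) {
    query <- c(background[1:k], background[(K + 1):(K + n - k)])
    res <- fisher_enrichment(query, list(t = background[1:K]), background)
    ft <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2),
                             alternative = "greater")$p.value
    expect_equal(res$p_raw, ft, tolerance = 1e-9)
    expect_gte(res$p_raw, prev)  # decreasing k never decreases p
    prev <- res$p_raw
  }
})

test_that("enrichment validates its inputs and adjusts across terms", {
  background <- LETTERS[1:20]
  expect_error(fisher_enrichment(character(0), list(t = "A"), background),
               "empty query")
  expect_error(fisher_enrichment(c("A", "zz"), list(t = "A"), background),
               "subset")
  annotation <- list(t1 = LETTERS[1:3], t2 = LETTERS[1:10], t3 = LETTERS[11:20])
  res <- fisher_enrichment(LETTERS[1:4], annotation, background)
  expect_equal(sort(res$p_adjusted), sort(bh_oracle(res$p_raw)))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_false(is.unsorted(res$p_adjusted))
})

test_that("GMT files parse into canonicalized gene sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("GO_A\tdesc\ttp53\tMDM2",
               "GO_B\tdesc\tsod1 \tKIF5A\tEAAT2"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("GO_A", "GO_B"))
  expect_equal(sets$GO_A, c("TP53", "MDM2"))
  expect_equal(sets$GO_B, c("SOD1", "KIF5A", "EAAT2"))
})
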