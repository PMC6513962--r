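test_that("Welch DE test matches stats::t.test and its symmetries", {
  set.seed(10)
  a <- matrix(rnorm(5 * 30, mean = 8), 5, 30, dimnames = list(paste0("g", 1:5), NULL))
  b <- matrix(rnorm(5 * 25, mean = 8), 5, 25, dimnames = list(paste0("g", 1:5), NULL))
  de <- de_test(a, b)
  for (g in rownames(a)) {
    tt <- t.test(a[g, ], b[g, ])
    expect_equal(de$p[de$gene == g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$t[de$gene == g], unname(tt$statistic), tolerance = 1e-12)
  }
  # swap flips direction, keeps p
  sw <- de_test(b, a)
  expect_equal(sw$p, de$p)
  expect_true(all((de$direction == "up") == (sw$direction == "down")))

  # identical groups: t = 0, p = 1
  same <- de_test(a, a)
  expect_true(all(same$p == 1))
  expect_true(all(same$t == 0))

  # a planted 1-log2-unit shift at sd 0.5 is overwhelming at n = 50/50
  set.seed(11)
  base <- matrix(rnorm(3 * 50, mean = 6, sd = 0.5), 3, 50,
                 dimnames = list(paste0("g", 1:3), NULL))
  shifted <- base + 1
  de2 <- de_test(shifted, base)
  expect_true(all(de2$p < 1e-10))
  expect_true(all(de2$direction == "up"))

  expect_error(de_test(a - 100, b, log2_transform = TRUE), "non-positive")
})

test_that("consensus DE applies the vote and tie rules", {
  t1 <- tibble::tibble(gene = c("a", "b", "c"), p = c(0.005, 0.5, 0.001),
                       direction = c("up", "up", "up"))
  t2 <- tibble::tibble(gene = c("a", "b", "c"), p = c(0.002, 0.002, 0.003),
                       direction = c("up", "down", "down"))
  t3 <- tibble::tibble(gene = c("a", "b", "c"), p = c(0.5, 0.004, 0.004),
                       direction = c("down", "down", "down"))

  # single dataset, min_datasets = 1: the simple path
  single <- consensus_de(list(t1), alpha = 0.01, min_datasets = 1)
  expect_equal(single$gene, c("a", "c"))

  # majority vote: c is up in 1, down in 2 (all significant) -> down
  cons <- consensus_de(list(t1, t2, t3), alpha = 0.01, min_datasets = 2)
  expect_equal(cons$direction[cons$gene == "c"], "down")
  expect_equal(cons$direction[cons$gene == "a"], "up")
  expect_equal(cons$direction[cons$gene == "b"], "down")

  # exact tie: dropped with a warning
  t4 <- tibble::tibble(gene = "a", p = 0.001, direction = "up")
  t5 <- tibble::tibble(gene = "a", p = 0.001, direction = "down")
  expect_warning(tied <- consensus_de(list(t4, t5), min_datasets = 2), "tied")
  expect_equal(nrow(tied), 0)

  # inconsistent universes: warning + intersection
  t6 <- tibble::tibble(gene = c("a", "z"), p = c(0.001, 0.001),
                       direction = c("up", "up"))
  expect_warning(ix <- consensus_de(list(t1, t6), min_datasets = 1),
                 "intersection")
  expect_false("z" %in% ix$gene)
})

test_that("enrichment test equals the hypergeometric tail enumeration", {
  # exhaustive small-universe check against brute-force enumeration
  for (n in c(12, 25, 40)) {
    set.seed(n)
    for (i in 1:20) {
      k <- sample(1:n, 1)
      K <- sample(1:n, 1)
      x <- sample(0:min(k, K), 1)
      expect_equal(enrichment_test(x, k, K, n), hyper_tail_enum(x, k, K, n),
                   tolerance = 1e-12)
    }
  }
  expect_equal(enrichment_test(0, 5, 10, 100), 1)
  expect_equal(enrichment_test(10, 10, 10, 10), 1)
  expect_equal(enrichment_test(5, 10, 10, 100), 6.2e-5, tolerance = 0.02)
  # decreasing in x
  ps <- enrichment_test(0:5, 10, 20, 100)
  expect_true(all(diff(ps) < 0))
  # the legacy literal matrix mode runs and is a one-sided fisher.test p
  expect_equal(
    enrichment_test(5, 10, 10, 100, mode = "literal"),
    fisher.test(matrix(c(5, 5, 5, 90), 2, byrow = TRUE),
                alternative = "greater")$p.value
  )
  expect_error(enrichment_test(11, 10, 10, 100), "impossible")
})

test_that("partner table is symmetric and obeys the handshake lemma", {
  dce <- tibble::tibble(
    gene_i = c("a", "a", "b", "c"), gene_j = c("b", "c", "c", "d"),
    p_adj = c(0.001, 0.5, 0.002, 0.003)
  )
  pt <- partner_table(dce, cutoff = 0.01)
  expect_equal(pt$n_partners[pt$gene == "a"], 1L)
  expect_equal(pt$partners[[which(pt$gene == "b")]], c("a", "c"))
  expect_equal(sum(pt$n_partners), 2 * 3)  # 2 x significant pairs
  # symmetry
  for (i in seq_len(nrow(pt))) {
    for (p in pt$partners[[i]]) {
      expect_true(pt$gene[i] %in% pt$partners[[which(pt$gene == p)]])
    }
  }
  # order invariance
  pt2 <- partner_table(dce[sample(4), ], cutoff = 0.01)
  expect_equal(pt, pt2)
  # universe completion
  pt3 <- partner_table(dce, cutoff = 0.01, universe = c(letters[1:5]))
  expect_equal(pt3$n_partners[pt3$gene == "e"], 0L)
  # empty DCE set: all zero
  pt4 <- partner_table(dce[0, ], universe = letters[1:3])
  expect_true(all(pt4$n_partners == 0))
})

test_that("selection criteria are applied literally", {
  base <- tibble::tibble(
    gene = c("fifty", "deg_hub", "ad_hub", "big_nothing", "deg_no_enrich"),
    n_partners = c(50L, 51L, 200L, 200L, 120L),
    de_p = c(0.001, 0.005, 0.5, 0.5, 0.004),
    is_ad = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    p_enrich_deg = c(0.001, 0.5, 0.002, 0.5, 0.5),
    p_enrich_ad = c(0.001, 0.01, 0.5, 0.5, 0.5)
  )
  sel <- select_dysregulated(base)
  picked <- sel$gene[sel$selected]
  # exactly 50 partners fails the strict "more than 50" rule
  expect_false("fifty" %in% picked)
  # DE gene whose partners are AD-enriched at p = 0.01 < 0.05 passes
  expect_true("deg_hub" %in% picked)
  # AD gene whose partners are DEG-enriched passes
  expect_true("ad_hub" %in% picked)
  # many partners alone is not enough
  expect_false("big_nothing" %in% picked)
  expect_false("deg_no_enrich" %in% picked)
  expect_error(select_dysregulated(base[, 1:2]), "lacks required")
})

test_that("a planted hub is recovered and selected from simulated data", {
  recovered <- vapply(1:5, function(s) {
    spec <- sim_spec(300, c(300, 300),
                     hubs = list(hub_spec(1, 2:41, 0.7, 0)),
                     de_genes = data.frame(gene = 1, lfc = 1), seed = s)
    ds <- simulate_dataset(spec)
    dce <- dce_table(coexpression_table(ds$expr_a),
                     coexpression_table(ds$expr_b))
    de <- de_test(ds$expr_a, ds$expr_b)
    ad <- c(sprintf("g%05d", 2:11), sprintf("g%05d", 200:219))
    gs <- gene_summary(dce, de, ad_genes = ad)
    sel <- select_dysregulated(gs, partner_threshold = 20)
    hub_is_max <- gs$n_partners[gs$gene == "g00001"] == max(gs$n_partners)
    hub_selected <- "g00001" %in% sel$gene[sel$selected]
    planted <- sprintf("g%05d", 1:41)
    only_planted <- all(sel$gene[sel$selected] %in% planted)
    hub_is_max && hub_selected && only_planted
  }, logical(1))
  expect_gte(sum(recovered), 4)
})

test_that("direction consistency counts the agreeing intersection", {
  d1 <- c(a = "up", b = "down", c = "up", x = "up")
  d2 <- c(a = "up", b = "up", c = "up", y = "down")
  res <- direction_consistency(d1, d2)
  expect_equal(res$consistent, 2)
  expect_equal(res$total, 3)
  expect_equal(direction_consistency(d1, d1)$consistent, 4)
  opp <- c(a = "down", b = "up", c = "down", x = "down")
  expect_equal(direction_consistency(d1, opp)$consistent, 0)
  expect_error(direction_consistency(d1, character(0)), "non-empty")

  # bookkeeping against a planted 80% agreement
  set.seed(13)
  genes <- sprintf("g%03d", 1:200)
  ref <- setNames(sample(c("up", "down"), 200, replace = TRUE), genes)
  obs <- ref
  flip <- sample(200, 40)
  obs[flip] <- ifelse(ref[flip] == "up", "down", "up")
  expect_equal(direction_consistency(obs, ref)$fraction, 0.8)
})
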