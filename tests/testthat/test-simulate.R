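test_that("generation is bit-reproducible and background pairs are null", {
  spec <- sim_spec(100, c(200, 200), seed = 11)
  ds1 <- simulate_dataset(spec)
  ds2 <- simulate_dataset(spec)
  expect_identical(ds1$expr_a, ds2$expr_a)
  expect_identical(ds1$expr_b, ds2$expr_b)
  expect_equal(nrow(ds1$truth$pairs), 0)

  # empirical correlations of independent genes: mean ~ 0, sd ~ 1/sqrt(n-1)
  pairs <- spearman_all_pairs(ds1$expr_a)
  expect_lt(abs(mean(pairs$r)), 3 / sqrt(nrow(pairs)) * (1 / sqrt(199)) + 1e-3)
  expect_equal(sd(pairs$r), 1 / sqrt(199), tolerance = 0.1)
})

test_that("planted block correlations hit the rank-attenuated target", {
  # Monte Carlo over seeds vs the closed form (6/pi) asin(rho/2)
  target <- spearman_target(0.6)
  means <- vapply(1:20, function(s) {
    ds <- simulate_dataset(sim_spec(
      10, c(500, 500), blocks = list(block_spec(1:10, 0.6, 0.6)), seed = s
    ))
    mean(c(spearman_pairs(ds$expr_a, truth_pairs(ds))$r,
           spearman_pairs(ds$expr_b, truth_pairs(ds))$r))
  }, numeric(1))
  expect_true(all(abs(means - target) < 0.05))
  expect_lt(abs(mean(means) - target), 0.02)

  # convergence at large n, tight tolerance
  ds <- simulate_dataset(sim_spec(
    4, c(2000, 50), blocks = list(block_spec(1:4, 0.6, 0.6)), seed = 1
  ))
  r <- spearman_pairs(ds$expr_a, truth_pairs(ds))$r
  expect_true(all(abs(r - target) < 0.03))
})

test_that("hub factor structure puts the differential signal on hub pairs only", {
  ds <- simulate_dataset(sim_spec(
    21, c(2000, 2000), hubs = list(hub_spec(1, 2:21, 0.7, 0)), seed = 5
  ))
  tp <- ds$truth$pairs
  expect_setequal(unique(tp$component), c("hub", "hub_partner"))
  ra <- spearman_pairs(ds$expr_a, tp)$r
  rb <- spearman_pairs(ds$expr_b, tp)$r
  hub <- tp$component == "hub"
  # hub-partner correlation is rho_a in A and rho_b in B
  expect_equal(mean(ra[hub]), spearman_target(0.7), tolerance = 0.03)
  expect_lt(max(abs(rb[hub])), 4 / sqrt(1999))
  # the partner module holds together identically in both conditions
  expect_equal(mean(ra[!hub]), spearman_target(0.7), tolerance = 0.03)
  expect_equal(mean(rb[!hub]), spearman_target(0.7), tolerance = 0.03)
  expect_equal(tp$rho_a[!hub], tp$rho_b[!hub])
})

test_that("invalid specs are rejected with informative errors", {
  expect_error(block_spec(1:5, rho_a = -0.3, rho_b = 0.5), "positive definite")
  expect_error(block_spec(1:5, rho_a = 1, rho_b = 0), "in \\(-1, 1\\)")
  expect_error(hub_spec(1, 1:4, 0.5, 0.5), "among its partners")
  expect_error(
    sim_spec(50, blocks = list(block_spec(1:5, .5, .5)),
             hubs = list(hub_spec(5, 6:10, .5, .5))),
    "overlaps"
  )
  expect_error(sim_spec(10, de_genes = data.frame(gene = 11, lfc = 1)),
               "outside")
  ds <- simulate_dataset(sim_spec(10, c(20, 20), seed = 1))
  expect_error(add_species_pair(ds, divergence = 1.2), "\\[0, 1\\]")
  expect_error(add_clinical_trait(ds, data.frame(gene = integer(), weight = numeric())),
               "non-empty")
})

test_that("DE offsets, transform and constant-gene guarantees hold", {
  spec <- sim_spec(30, c(400, 400), de_genes = data.frame(gene = 1:3, lfc = 2),
                   seed = 9)
  ds <- simulate_dataset(spec)
  shift <- rowMeans(ds$expr_a) - rowMeans(ds$expr_b)
  expect_equal(unname(shift[1:3]), rep(2, 3), tolerance = 0.25)
  expect_lt(max(abs(shift[4:30])), 0.5)
  expect_true(all(apply(ds$expr_a, 1, sd) > 0))

  # monotone transform changes values, not ranks
  spec_exp <- sim_spec(30, c(400, 400), de_genes = data.frame(gene = 1:3, lfc = 2),
                       transform = "exp", seed = 9)
  ds_exp <- simulate_dataset(spec_exp)
  expect_identical(ds_exp$expr_a, 2^ds$expr_a)
})

test_that("clinical traits follow the coupling closed form", {
  ds <- simulate_dataset(sim_spec(10, c(3000, 10), mean_sd = 0, seed = 2))

  # weight 1, no noise: perfect rank association
  ds0 <- add_clinical_trait(ds, data.frame(gene = 1, weight = 1), noise_sd = 0)
  expect_equal(cor(ds0$traits$trait1, ds0$expr_a[1, ], method = "spearman"), 1)

  # weight 1, unit noise, unit-variance gene: Pearson ~ 1/sqrt(2)
  ds1 <- add_clinical_trait(ds, data.frame(gene = 1, weight = 1), noise_sd = 1)
  expect_equal(cor(ds1$traits$trait1, ds1$expr_a[1, ]), 1 / sqrt(2),
               tolerance = 0.04)

  # two equal couplings on independent genes: each marginal ~ 1/sqrt(3)
  ds2 <- add_clinical_trait(ds, data.frame(gene = c(1, 2), weight = 1),
                            noise_sd = 1, name = "t2")
  r1 <- cor(ds2$traits$t2, ds2$expr_a[1, ])
  r2 <- cor(ds2$traits$t2, ds2$expr_a[2, ])
  expect_equal(c(r1, r2), rep(1 / sqrt(3), 2), tolerance = 0.05)
})

test_that("species divergence is recorded pair-by-pair and respects the rate", {
  spec <- pair_block_spec(20, rho_a = rep(c(0.3, 0.45, 0.6, 0.7), 5),
                          rho_b = 0.6, seed = 3)
  hits <- vapply(1:30, function(s) {
    ds <- add_species_pair(simulate_dataset(spec), divergence = 0.5, seed = s)
    sum(ds$truth$species_pairs$perturbed)
  }, numeric(1))
  expect_equal(mean(hits), 10, tolerance = 0.15)  # binomial(20, 0.5)
  expect_true(all(hits >= 2 & hits <= 18))

  ds0 <- add_species_pair(simulate_dataset(spec), divergence = 0)
  expect_false(any(ds0$truth$species_pairs$perturbed))
  expect_equal(ds0$truth$species_pairs$rho_sp, ds0$truth$species_pairs$rho_a)
  # conservation on the true correlation vectors is exactly 1 at divergence 0
  expect_equal(cor(ds0$truth$species_pairs$rho_a, ds0$truth$species_pairs$rho_sp), 1)

  ds1 <- add_species_pair(simulate_dataset(spec), divergence = 1, redraw = "zero")
  expect_true(all(ds1$truth$species_pairs$perturbed))
  expect_true(all(ds1$truth$species_pairs$rho_sp == 0))
  # shared per-gene means
  expect_equal(rowMeans(ds1$species_b), rowMeans(ds1$expr_a), tolerance = 0.5)
})

test_that("batch effects are additive, recorded exactly, and separate batches", {
  spec <- sim_spec(50, c(30, 30), batch_effects = c(b1 = 5, b2 = 5), seed = 21)
  clean <- simulate_dataset(spec)
  samples <- c(colnames(clean$expr_a), colnames(clean$expr_b))
  batches <- setNames(rep(c("b1", "b2"), length.out = length(samples)), samples)
  perturbed <- add_batch_effects(simulate_dataset(spec), batches)

  # bookkeeping identity: perturbed - clean equals the recorded offsets
  off <- perturbed$truth$batch_offsets
  delta <- perturbed$expr_a - clean$expr_a
  expect_equal(delta, off[, batches[colnames(delta)]], ignore_attr = TRUE)

  # scale 0 leaves the data untouched
  same <- add_batch_effects(simulate_dataset(spec), batches,
                            scale = c(b1 = 0, b2 = 0))
  expect_equal(same$expr_a, clean$expr_a)

  # strong offsets dominate the first principal component
  pc1 <- prcomp(t(cbind(perturbed$expr_a, perturbed$expr_b)))$x[, 1]
  grp <- batches[names(pc1)]
  gap <- abs(mean(pc1[grp == "b1"]) - mean(pc1[grp == "b2"]))
  spread <- sd(pc1[grp == "b1"]) + sd(pc1[grp == "b2"])
  expect_gt(gap, spread)

  expect_error(add_batch_effects(clean, batches[-1]), "every sample")
  expect_error(
    add_batch_effects(clean, c(batches, bogus = "b1")),
    "unknown sample"
  )
})

test_that("a written dataset round-trips its truth", {
  dir <- withr::local_tempdir()
  spec <- sim_spec(12, c(25, 20),
                   blocks = list(block_spec(1:3, 0.5, 0.2)),
                   hubs = list(hub_spec(5, 6:8, 0.6, 0)),
                   de_genes = data.frame(gene = 9, lfc = 1.5), seed = 4)
  ds <- simulate_dataset(spec)
  ds <- add_clinical_trait(ds, data.frame(gene = 5, weight = 1))
  write_dataset(ds, dir)
  expect_equal(read_expression(file.path(dir, "exprA.tsv")), ds$expr_a,
               tolerance = 1e-12)
  truth <- read_truth(dir)
  expect_equal(truth$spec, spec)
  expect_identical(simulate_dataset(truth$spec)$expr_a, ds$expr_a)
  expect_equal(as.data.frame(truth$pairs),
               as.data.frame(dplyr::mutate(ds$truth$pairs, class = NULL)))
})
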