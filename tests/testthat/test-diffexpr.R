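test_that("size factors implement median-of-ratios with geometric mean 1", {
  # sample2 = 2 x sample1 exactly
  counts <- matrix(c(4L, 10L, 20L, 8L, 20L, 40L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(tiny_es(counts))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical samples
  counts2 <- matrix(rep(c(3L, 9L, 27L), 3), nrow = 3,
                    dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(tiny_es(counts2))), rep(1, 3))

  # 200-feature synthetic matrix vs brute-force definition
  sim <- simulate_counts(small_sim_config(seed = 2))
  es <- sim$expr
  sf <- size_factors(es)
  eligible <- apply(es$counts, 1, function(x) all(x > 0))
  ref <- exp(rowMeans(log(es$counts[eligible, ])))
  brute <- apply(es$counts[eligible, ], 2, function(x) median(x / ref))
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(sf), unname(brute))
  expect_equal(exp(mean(log(sf))), 1)

  # all features contain a zero -> undefined
  z <- matrix(c(0L, 5L, 3L, 0L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(tiny_es(z)), "pseudo-reference")
})

test_that("method-of-moments dispersion matches hand arithmetic", {
  # grand mean 10, pooled within-group variance 20 -> alpha = 0.1
  counts <- matrix(c(6L, 14L, 8L, 12L), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:4)))
  es <- tiny_es(counts, groups = c("cold", "cold", "control", "control"))
  alpha <- estimate_dispersion(es, size_factors = rep(1, 4))
  expect_equal(unname(alpha), (20 - 10) / 100)

  # Poisson-like feature (s2 approximately m) floors at 0
  pois <- matrix(c(9L, 11L, 10L, 10L), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:4)))
  es2 <- tiny_es(pois, groups = c("cold", "cold", "control", "control"))
  expect_equal(unname(estimate_dispersion(es2, size_factors = rep(1, 4))), 0)

  # all-zero feature flagged as NA
  zz <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 5L, 6L), nrow = 2, byrow = TRUE,
               dimnames = list(c("z", "g"), paste0("s", 1:4)))
  es3 <- tiny_es(zz, groups = c("cold", "cold", "control", "control"))
  a3 <- estimate_dispersion(es3, size_factors = rep(1, 4))
  expect_true(is.na(a3[["z"]]))
  expect_false(is.na(a3[["g"]]))
})

test_that("dispersion moderation floors at the class median", {
  alpha <- c(0, 0.05, 0.2, 0.5, 0.3, 0.01)
  cls <- c("mRNA", "mRNA", "mRNA", "miRNA", "miRNA", "miRNA")
  mod <- moderate_dispersion(alpha, cls)
  expect_equal(mod, c(0.05, 0.05, 0.2, 0.5, 0.3, 0.3))
  expect_true(all(mod >= alpha))
})

test_that("the NB Wald test is symmetric, antisymmetric and scale-equivariant", {
  set.seed(7)
  counts <- matrix(rnbinom(600, mu = 50, size = 10), nrow = 100)
  dimnames(counts) <- list(paste0("g", 1:100), paste0("s", 1:6))
  es <- tiny_es(counts)

  # identical group means -> lfc 0, p 1
  eq <- matrix(c(10L, 20L, 30L, 30L, 20L, 10L), nrow = 1,
               dimnames = list("g1", paste0("s", 1:6)))
  res <- nb_wald_test(tiny_es(eq), size_factors = rep(1, 6),
                      dispersions = 0.1)
  expect_equal(res$log10_fc, 0)
  expect_equal(res$p, 1)

  # swapping the group labels negates the fold change, preserves p
  sf <- size_factors(es)
  al <- estimate_dispersion(es, sf)
  fwd <- nb_wald_test(es, sf, al)
  swapped <- es
  swapped$samples$group <- rev(swapped$samples$group)
  back <- nb_wald_test(swapped, sf, estimate_dispersion(swapped, sf))
  expect_equal(back$log10_fc, -fwd$log10_fc)
  expect_equal(back$p, fwd$p)

  # multiplying one sample's counts by a constant is absorbed by the
  # recomputed size factors up to one global factor (the geometric-mean-1
  # convention spreads the rescaling over all samples), so normalized
  # counts agree up to a single constant and the test statistics agree
  # closely
  scaled <- es$counts
  scaled[, 3] <- scaled[, 3] * 5L
  es2 <- tiny_es(scaled)
  sf2 <- size_factors(es2)
  ratio <- normalized_counts(es2, sf2) / normalized_counts(es, sf)
  expect_equal(max(ratio), min(ratio), tolerance = 1e-12)
  res2 <- nb_wald_test(es2, sf2, estimate_dispersion(es2, sf2))
  expect_lt(max(abs(res2$log10_fc - fwd$log10_fc)), 0.01)
  expect_identical(de_test(es2)$status, de_test(es)$status)
})

test_that("classification applies the printed class-specific thresholds", {
  rec <- tibble::tibble(
    feature_id = c("FOXO1-like", "PPARG-like", "mir-x", "mir-y", "lnc-x",
                   "circ-x", "m-boundary", "m-pboundary"),
    rna_class = c("mRNA", "mRNA", "miRNA", "miRNA", "lncRNA", "circRNA",
                  "mRNA", "mRNA"),
    log10_fc = c(0.68, -0.77, 0.9, -1.2, 0.59, 0.61, 0.6, 0.7),
    p = c(0.01, 0.01, 0.03, 0.005, 0.001, 0.009, 0.049, 0.05))
  out <- classify_features(rec)
  expect_equal(out$status,
               c("up",    # the 0.68 up-regulation pattern
                 "down",  # the -0.77 down-regulation pattern
                 "ns",    # miRNA needs p < 0.01, not 0.03
                 "down", "ns", "up",
                 "up",    # |lfc| = 0.6 boundary is inclusive
                 "ns"))   # p = cutoff is exclusive

  expect_error(classify_features(dplyr::mutate(rec, rna_class = "tRNA")),
               "no p cutoff")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")

  # hand-computed step-up oracle on random vectors
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    hand <- numeric(m)
    prev <- 1
    for (r in m:1) {
      prev <- min(prev, p[o[r]] * m / r)
      hand[o[r]] <- prev
    }
    mine <- bh_adjust(p)
    expect_equal(mine, hand)
    expect_true(all(mine >= p & mine <= 1))
    # weakly order-preserving: smaller raw p never gets larger adjusted p
    expect_true(all(diff(mine[order(p)]) >= -1e-15))
  }
})

test_that("PCA is deterministic, conservative and separates planted groups", {
  sim <- simulate_counts(small_sim_config(seed = 19))
  pca <- pca_samples(sim$expr)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-9)

  # sign convention makes repeated runs identical
  pca2 <- pca_samples(sim$expr)
  expect_identical(pca$scores, pca2$scores)

  # strong planted effects: PC1 linearly separates the groups
  cold <- pca$scores$PC1[pca$scores$group == "cold"]
  ctrl <- pca$scores$PC1[pca$scores$group == "control"]
  expect_true(max(cold) < min(ctrl) || max(ctrl) < min(cold))

  # duplicated samples get identical scores
  counts <- sim$expr$counts[, c(1, 1, 2, 4, 5, 5)]
  colnames(counts) <- paste0("s", 1:6)
  dup <- tiny_es(counts, classes = sim$expr$features$rna_class)
  sc <- pca_samples(dup)$scores
  expect_equal(unlist(sc[1, -(1:2)]), unlist(sc[2, -(1:2)]),
               tolerance = 1e-8)

  const <- matrix(5L, 4, 4, dimnames = list(paste0("g", 1:4),
                                            paste0("s", 1:4)))
  expect_error(pca_samples(tiny_es(const)), "no variance|constant")
})

test_that("the composed DE stage recovers planted features at strong effects", {
  sim <- simulate_counts(small_sim_config(seed = 23))
  de <- de_test(sim$expr)
  truth <- sim$truth$de_status
  joined <- dplyr::inner_join(de, truth, by = "feature_id",
                              suffix = c("", ".true"))
  planted <- joined[joined$status.true != "ns", ]
  expect_gt(mean(planted$status == planted$status.true), 0.9)
  nulls <- joined[joined$status.true == "ns", ]
  expect_lt(mean(nulls$status != "ns"), 0.01)
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})
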