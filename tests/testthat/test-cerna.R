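de_fixture <- function(...) {
  tibble::tibble(...)
}

test_that("triad assembly enforces the direction rules", {
  de <- tibble::tibble(
    feature_id = c("m1", "mi1", "c1", "l1"),
    rna_class = c("mRNA", "miRNA", "circRNA", "lncRNA"),
    status = c("up", "down", "up", "up"))
  ia <- tibble::tibble(
    mirna_id = c("mi1", "mi1", "mi1"),
    target_id = c("m1", "c1", "l1"),
    target_class = c("mRNA", "circRNA", "lncRNA"),
    n_sites = 1L, best_site_type = "8mer")
  lp <- tibble::tibble(lnc_id = "l1", mrna_id = "m1", mode = "cis",
                       evidence = 0)
  tr <- assemble_triads(de, ia, lp)
  # circRNA sponge passes on the interaction alone; the lncRNA sponge
  # additionally has the cis pair, so both triads emerge
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$sponge_id, c("c1", "l1"))
  expect_equal(tr$lnc_mode[tr$sponge_id == "l1"], "cis")
  expect_equal(tr$lnc_mode[tr$sponge_id == "c1"], "n/a")
  validate_triads(tr)

  # mRNA and miRNA in the same direction never form a triad
  de2 <- dplyr::mutate(de, status = c("up", "up", "up", "up"))
  expect_equal(nrow(assemble_triads(de2, ia, lp)), 0)

  # sponge direction must equal the mRNA direction
  de3 <- dplyr::mutate(de, status = c("up", "down", "down", "down"))
  expect_equal(nrow(assemble_triads(de3, ia, lp)), 0)

  # lncRNA sponge without a cis/trans pair to the core mRNA is dropped
  tr4 <- assemble_triads(de, ia, lp[0, ])
  expect_equal(tr4$sponge_id, "c1")

  # missing mu -> m interaction: nothing, even with a sponge interaction
  ia5 <- ia[ia$target_id != "m1", ]
  expect_equal(nrow(assemble_triads(de, ia5, lp)), 0)
})

test_that("triad assembly equals exhaustive triple enumeration", {
  set.seed(77)
  for (i in 1:12) {
    inst <- random_triad_instance(n_per_class = sample(4:10, 1))
    mine <- assemble_triads(inst$de, inst$interactions, inst$lnc_pairs)
    validate_triads(mine)
    brute <- brute_force_triads(inst$de, inst$interactions, inst$lnc_pairs)
    expect_equal(triad_key(mine), triad_key(brute))
  }
})

test_that("the term post-filter keeps triads whose core mRNA is annotated", {
  tr <- tibble::tibble(
    mrna_id = c("m1", "m2"), mirna_id = "mi", sponge_id = c("c1", "c2"),
    sponge_class = "circRNA", mrna_status = "up", mirna_status = "down",
    sponge_status = "up", mirna_targets_mrna = TRUE,
    sponge_binds_mirna = TRUE, lnc_mode = "n/a")
  expect_equal(filter_triads_by_term(tr, c("m2", "m9"))$mrna_id, "m2")
  expect_equal(nrow(filter_triads_by_term(tr, character(0))), 0)
})

test_that("venn overlap counts differential features with targeting links", {
  de0 <- tibble::tibble(feature_id = c("m1", "mi1"),
                        rna_class = c("mRNA", "miRNA"),
                        status = c("ns", "ns"))
  ia0 <- tibble::tibble(mirna_id = "mi1", target_id = "m1",
                        target_class = "mRNA")
  lp0 <- tibble::tibble(lnc_id = character(), mrna_id = character())
  v0 <- venn_overlap(de0, ia0, lp0)
  expect_equal(v0$n_de, rep(0, 4))
  expect_equal(v0$n_de_linked, rep(0, 4))

  de1 <- dplyr::mutate(de0, status = c("up", "down"))
  v1 <- venn_overlap(de1, ia0, lp0)
  expect_equal(v1$n_de_linked[v1$rna_class == "mRNA"], 1)
  expect_equal(v1$n_de_linked[v1$rna_class == "miRNA"], 1)

  # brute-force set recount on a synthetic run
  sim <- simulate_experiment(small_sim_config(seed = 6))
  de <- de_test(sim$expr)
  cls <- setNames(sim$expr$features$rna_class, sim$expr$features$feature_id)
  ia <- build_interactions(
    sim$sequences[cls[names(sim$sequences)] == "miRNA"],
    sim$sequences[cls[names(sim$sequences)] != "miRNA"], cls)
  cis <- lnc_cis_targets(
    dplyr::filter(sim$annotation, rna_class == "lncRNA"),
    dplyr::filter(sim$annotation, rna_class == "mRNA"))
  v <- venn_overlap(de, ia, cis)
  de_set <- de$feature_id[de$status != "ns"]
  for (cl in c("mRNA", "lncRNA", "miRNA", "circRNA")) {
    ids <- de$feature_id[de$status != "ns" & de$rna_class == cl]
    expect_equal(v$n_de[v$rna_class == cl], length(ids))
    linked <- vapply(ids, function(f) {
      in_ia <- (cl == "miRNA" &
                  any(ia$mirna_id == f & ia$target_id %in% de_set)) ||
        any(ia$target_id == f & ia$mirna_id %in% de_set)
      in_lp <- (cl == "lncRNA" &
                  any(cis$lnc_id == f & cis$mrna_id %in% de_set)) ||
        (cl == "mRNA" & any(cis$mrna_id == f & cis$lnc_id %in% de_set))
      in_ia || in_lp
    }, logical(1))
    expect_equal(v$n_de_linked[v$rna_class == cl], sum(linked))
  }
})

test_that("marker normalization follows the geometric-mean formula", {
  counts <- matrix(c(8L, 2L, 8L,   8L, 2L, 8L,
                     4L, 4L, 4L,   9L, 1L, 9L), nrow = 3,
                   dimnames = list(c("t", "a", "b"), paste0("s", 1:4)))
  es <- tiny_es(counts, groups = c("cold", "cold", "control", "control"))
  got <- marker_normalize(es, "t", "a", "b", size_factors = rep(1, 4))
  expect_equal(got$value[1], 8 / sqrt(2 * 8))      # 8 / sqrt(16) = 2
  expect_equal(got$value[3], 4 / sqrt(4 * 4))      # self-normalization -> 1
  expect_equal(got$value[4], 9 / sqrt(1 * 9))

  prod <- marker_normalize(es, "t", "a", "b", size_factors = rep(1, 4),
                           form = "product")
  expect_equal(prod$value[1], 8 / 16)

  # invariant under a common per-sample rescaling of all three features
  set.seed(12)
  base <- matrix(rnbinom(12, mu = 60, size = 5) + 1L, nrow = 3,
                 dimnames = list(c("t", "a", "b"), paste0("s", 1:4)))
  scale_by <- c(1L, 2L, 3L, 5L)
  scaled <- sweep(base, 2, scale_by, "*")
  storage.mode(scaled) <- "integer"
  es_b <- tiny_es(base, groups = c("cold", "cold", "control", "control"))
  es_s <- tiny_es(scaled, groups = c("cold", "cold", "control", "control"))
  v1 <- marker_normalize(es_b, "t", "a", "b", size_factors = rep(1, 4))
  v2 <- marker_normalize(es_s, "t", "a", "b", size_factors = rep(1, 4))
  expect_equal(v1$value, v2$value, tolerance = 1e-12)

  zero <- counts; zero["a", 2] <- 0L
  expect_error(marker_normalize(tiny_es(zero, groups = es$samples$group),
                                "t", "a", "b", size_factors = rep(1, 4)),
               "s2")
  expect_error(marker_normalize(es, "nope", "a", "b",
                                size_factors = rep(1, 4)), "not found")
})

test_that("the pooled t-test matches stats and a permutation oracle", {
  expect_equal(group_ttest(c(1, 2, 3, 1, 2, 3),
                           c("a", "a", "a", "b", "b", "b")),
               tibble::tibble(t = 0, p = 1))
  shifted <- group_ttest(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
  expect_lt(shifted$p, 1e-4)

  expect_error(group_ttest(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               "zero pooled variance")
  expect_equal(group_ttest(c(3, 3, 3, 3), rep(c("a", "b"), each = 2))$p, 1)

  # permutation oracle: moderate n, vectorized label permutations
  set.seed(55)
  x <- rnorm(15, 0.5)
  y <- rnorm(15, 0)
  got <- group_ttest(c(x, y), rep(c("a", "b"), each = 15))
  vals <- c(x, y)
  tstat <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  obs <- abs(tstat(x, y))
  perm <- replicate(20000, {
    idx <- sample(30, 15)
    abs(tstat(vals[idx], vals[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(got$p - p_perm), 0.02)
})

test_that("sign concordance counts matching fold-change signs", {
  a <- c(g1 = 1.2, g2 = -0.5, g3 = 0.3)
  expect_equal(sign_concordance(a, a), 1)
  expect_equal(sign_concordance(a, -a), 0)
  expect_error(sign_concordance(a, c(x = 1)), "no shared")

  set.seed(9)
  b <- setNames(rnorm(10), paste0("g", 1:10))
  d <- setNames(rnorm(10), paste0("g", 1:10))
  manual <- sum(sign(b) == sign(d)) / 10
  expect_equal(sign_concordance(b, d), manual)

  # zero disagrees with nonzero
  expect_equal(sign_concordance(c(g1 = 0, g2 = 1), c(g1 = 1, g2 = 1)), 0.5)
})
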