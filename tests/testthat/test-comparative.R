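star_tree <- function(n = 8L, depth = 1) {
  txt <- paste0("(", paste0("t", seq_len(n), ":", depth, collapse = ","),
                ");")
  ape::read.tree(text = txt)
}

test_that("Blomberg's K is 1 on a star phylogeny and matches the formula", {
  set.seed(1)
  star <- star_tree(10L)
  y <- setNames(rnorm(10L), star$tip.label)
  expect_equal(blomberg_k(star, y, n_perm = 0)$K, 1, tolerance = 1e-12)

  # two-path computation on an 8-tip tree (formula written independently)
  tr <- ape::rcoal(8L)
  y8 <- setNames(rnorm(8L), tr$tip.label)
  expect_equal(blomberg_k(tr, y8, n_perm = 0)$K, blomberg_k_oracle(tr, y8),
               tolerance = 1e-12)
  # and against the established implementation
  expect_equal(blomberg_k(tr, y8, n_perm = 0)$K,
               unname(phytools::phylosig(tr, y8, method = "K")[[1]]),
               tolerance = 1e-8)
  expect_error(blomberg_k(tr, setNames(rep(1, 8L), tr$tip.label)),
               "constant")
})

test_that("K and Kmult are invariant to branch scaling and trait shifts", {
  set.seed(2)
  tr <- ape::rcoal(12L)
  y <- setNames(rnorm(12L), tr$tip.label)
  k1 <- blomberg_k(tr, y, n_perm = 0)$K
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  expect_equal(blomberg_k(tr2, y, n_perm = 0)$K, k1, tolerance = 1e-10)
  expect_equal(blomberg_k(tr, y + 100, n_perm = 0)$K, k1, tolerance = 1e-8)

  Y <- bm_tips(tr, d = 4L)
  km <- k_mult(tr, Y, n_perm = 0)$K
  expect_equal(k_mult(tr2, Y, n_perm = 0)$K, km, tolerance = 1e-10)
  expect_equal(k_mult(tr, Y + 5, n_perm = 0)$K, km, tolerance = 1e-8)
})

test_that("Kmult reduces to K in one dimension and is 1 on a star", {
  set.seed(3)
  tr <- ape::rcoal(9L)
  y <- setNames(rnorm(9L), tr$tip.label)
  Y1 <- matrix(y, ncol = 1L, dimnames = list(names(y), NULL))
  expect_equal(k_mult(tr, Y1, n_perm = 0)$K,
               blomberg_k(tr, y, n_perm = 0)$K, tolerance = 1e-10)
  star <- star_tree(9L)
  Ys <- matrix(rnorm(27L), 9L, dimnames = list(star$tip.label, NULL))
  expect_equal(k_mult(star, Ys, n_perm = 0)$K, 1, tolerance = 1e-12)
})

test_that("signal permutation p-values are reproducible and in (0, 1]", {
  set.seed(4)
  tr <- ape::rcoal(10L)
  y <- setNames(rnorm(10L), tr$tip.label)
  p1 <- blomberg_k(tr, y, n_perm = 200L, seed = 9L)$p
  p2 <- blomberg_k(tr, y, n_perm = 200L, seed = 9L)$p
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lte(p1, 1)
})

test_that("Brownian simulation calibrates mean K and Kmult near 1", {
  # reduced-size calibration; the full 500-replicate run is in acceptance
  tr <- callitrichid_tree()
  set.seed(5)
  k_vals <- replicate(60L, blomberg_k(tr, setNames(drop(bm_tips(tr)),
                                                   tr$tip.label),
                                      n_perm = 0)$K)
  expect_gt(mean(k_vals), 0.8)
  expect_lt(mean(k_vals), 1.2)
})

test_that("phylogenetic ANOVA reduces to the standard one on a star tree", {
  set.seed(6)
  star <- near_star(20L)
  y <- setNames(rnorm(20L), star$tip.label)
  g <- setNames(rep(c("a", "b"), 10L), star$tip.label)  # independent of tree
  res <- phyl_anova(star, g, y, n_sim = 2000L, seed = 1L)
  expect_equal(res$p_phylo, res$p_standard, tolerance = 0.05)
  # same F as phytools (statistic is deterministic)
  pt <- phytools::phylANOVA(star, factor(g[star$tip.label]), y,
                            nsim = 10L, posthoc = FALSE)
  expect_equal(res$F, pt$F, tolerance = 1e-8)
})

test_that("phylogenetic ANOVA has power for a large group effect", {
  set.seed(7)
  tr <- ape::rcoal(20L)
  g <- setNames(rep(c("a", "b"), each = 10L), tr$tip.label)
  y <- drop(bm_tips(tr))
  y[g == "b"] <- y[g == "b"] + 10 * sd(y)   # 10-sigma offset
  res <- phyl_anova(tr, g, setNames(y, tr$tip.label), n_sim = 1000L,
                    seed = 2L)
  expect_lt(res$p_phylo, 0.01)
  expect_error(phyl_anova(tr, setNames(rep("a", 20L), tr$tip.label), y),
               "two groups")
})

test_that("PC retention picks the smallest axis set reaching the threshold", {
  set.seed(8)
  # rank-1 data: one axis
  u <- rnorm(10); v <- rnorm(6)
  expect_equal(retain_pcs(outer(u, v))$n_axes, 1L)
  # isotropic 3D cloud: all three axes needed at 95%
  expect_equal(retain_pcs(matrix(rnorm(3000), 1000L, 3L))$n_axes, 3L)
  # synthetic spectrum 0.5/0.3/0.15/0.05: 95% reached at 3 axes
  Z <- matrix(rnorm(4 * 5000), 5000L, 4L)
  Z <- scale(Z, scale = apply(Z, 2, sd))
  Y <- Z %*% diag(sqrt(c(0.5, 0.3, 0.15, 0.05)))
  expect_equal(retain_pcs(Y)$n_axes, 3L)
})

test_that("sequential Pillai MANCOVA matches stats::manova", {
  set.seed(9)
  n <- 30L
  size <- rnorm(n)
  g <- factor(rep(c("HL", "VCL"), each = 15L))
  Y <- matrix(rnorm(n * 4L), n)
  Y[, 1L] <- Y[, 1L] + 0.8 * size + ifelse(g == "VCL", 0.7, 0)
  mine <- mancova_pillai(Y, size, g)
  ref <- summary(stats::manova(Y ~ size * g), test = "Pillai")$stats
  expect_equal(mine$Pillai[1:3], unname(ref[1:3, "Pillai"]),
               tolerance = 1e-10)
  expect_equal(mine$approx_F[1:3], unname(ref[1:3, "approx F"]),
               tolerance = 1e-10)
  expect_equal(mine$p_value[1:3], unname(ref[1:3, "Pr(>F)"]),
               tolerance = 1e-10)
  expect_equal(mine$Df[4L], n - 4L)
})

test_that("one response axis reduces Pillai's F to the univariate ANCOVA F", {
  set.seed(10)
  n <- 24L
  size <- rnorm(n)
  g <- factor(rep(c("a", "b"), each = 12L))
  y <- 0.5 * size + ifelse(g == "b", 1, 0) + rnorm(n)
  mine <- mancova_pillai(matrix(y), size, g)
  uni <- stats::anova(stats::lm(y ~ size * g))   # sequential Type I
  expect_equal(mine$approx_F[1:3], uni$`F value`[1:3], tolerance = 1e-8)
  expect_equal(mine$p_value[1:3], uni$`Pr(>F)`[1:3], tolerance = 1e-8)
})

test_that("MANCOVA p-values are near-uniform under the null", {
  set.seed(11)
  ps <- replicate(120L, {
    n <- 25L
    mancova_pillai(matrix(rnorm(n * 3L), n), rnorm(n),
                   factor(rep(c("a", "b"), length.out = n)))$p_value[2L]
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.12)
})

test_that("MANCOVA rejects degenerate designs by name", {
  n <- 20L
  g <- factor(rep(c("a", "b"), each = 10L))
  size <- as.numeric(g == "b")   # size aliased with group
  Y <- matrix(rnorm(n * 2L), n)
  expect_error(mancova_pillai(Y, size, g), "aliased")
  expect_error(mancova_pillai(matrix(rnorm(60L), 5L, 12L), rnorm(5L),
                              factor(c("a", "a", "b", "b", "b"))),
               "n > q")
})

test_that("ridge-regression rates solve the two-tip system in closed form", {
  t2 <- ape::read.tree(text = "(A:2,B:2);")
  rf <- rr_rates(t2, setNames(c(1.5, -1.5), c("A", "B")), lambda = 1e-12)
  expect_equal(unname(rf$rates), c(0.75, 0.75), tolerance = 1e-6)
  expect_equal(unname(rf$root_estimate), 0, tolerance = 1e-12)

  # identical tip values: all rates zero
  rf0 <- rr_rates(t2, setNames(c(2, 2), c("A", "B")))
  expect_lt(max(rf0$rates), 1e-10)
})

test_that("rates are equivariant to scaling the data", {
  set.seed(12)
  tr <- ape::rcoal(12L)
  Y <- bm_tips(tr, d = 3L)
  rf1 <- rr_rates(tr, Y, lambda = 0.5)
  rf2 <- rr_rates(tr, 4 * Y, lambda = 0.5)
  expect_equal(rf2$rates, 4 * rf1$rates, tolerance = 1e-9)
})

test_that("training error is non-increasing as the ridge penalty shrinks", {
  set.seed(13)
  tr <- ape::rcoal(10L)
  Y <- bm_tips(tr)
  sse <- vapply(10^seq(2, -6, by = -1), function(lam) {
    rf <- rr_rates(tr, Y, lambda = lam)
    sum((Y[rownames(rf$fitted), ] - rf$fitted)^2)
  }, 0)
  expect_true(all(diff(sse) <= 1e-10))
})

test_that("clade shift search flags nothing when rates carry no signal", {
  set.seed(14)
  tr <- ape::rcoal(16L)
  # equal raw magnitudes, compared on the raw scale
  rep_raw <- search_shift_clades(tr, rep(1, nrow(tr$edge)), n_rand = 200L,
                                 seed = 1L, standardize = FALSE)
  expect_true(all(rep_raw$direction == "ns"))
  expect_true(all(rep_raw$p > 0.05))
  expect_true(all(rep_raw$n_tips >= 2 & rep_raw$n_tips <= 8))
  # magnitudes exactly on the Brownian sampling scale (1/sqrt(t)), compared
  # with the default length standardization
  rep_std <- search_shift_clades(tr, 1 / sqrt(tr$edge.length),
                                 n_rand = 200L, seed = 1L)
  expect_true(all(rep_std$direction == "ns"))
  expect_true(all(rep_std$p > 0.05))
})

test_that("clade shift p-values are bit-reproducible given the seed", {
  set.seed(15)
  tr <- ape::rcoal(14L)
  rf <- rr_rates(tr, bm_tips(tr, d = 2L))
  r1 <- search_shift_clades(tr, rf, n_rand = 300L, seed = 42L)
  r2 <- search_shift_clades(tr, rf, n_rand = 300L, seed = 42L)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p > 0 & r1$p <= 1))
})

test_that("a planted rate shift is recovered as a higher-rate clade", {
  tr <- tree_with_6clade()
  clade_node <- ape::getMRCA(tr, paste0("c", 1:6))
  rec <- simulation_recipe(
    tree = tr,
    group_map = setNames(rep("HL", 30L), tr$tip.label),
    base_rate = 0.01, group_offset_magnitude = 0,
    clade_rate_multipliers = list(list(tips = paste0("c", 1:6),
                                       multiplier = 8)),
    seed = 16L)
  hits <- 0L
  for (r in 1:15) {
    Y <- simulate_bm_shapes(rec, rep(0, 6L), rng_offset = r)
    rf <- rr_rates(tr, Y)
    ss <- search_shift_clades(tr, rf, n_rand = 300L, seed = r)
    row <- ss[ss$node == clade_node, ]
    if (row$p <= 0.05 && row$direction == "higher") hits <- hits + 1L
  }
  expect_gte(hits, 12L)
})

test_that("size comparison reproduces the clade-confounding pattern", {
  # groups equal to the two root clades of a balanced tree: the t-test sees
  # a difference that the phylogenetic ANOVA attributes to shared ancestry
  tr <- ape::stree(16L, "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  halves <- setNames(rep(c("VCL", "HL"), each = 8L), tr$tip.label)
  set.seed(17)
  t_small <- 0L; phylo_small <- 0L
  for (r in 1:25) {
    y <- setNames(drop(bm_tips(tr)), tr$tip.label)
    res <- size_comparison(y, halves, tr, n_sim = 200L, seed = r)
    t_small <- t_small + (res$t_p < 0.05)
    phylo_small <- phylo_small + (res$phyl_anova$p_phylo < 0.05)
  }
  expect_gt(t_small, phylo_small)
  expect_lte(phylo_small, 5L)
})
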