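two_group_matrix <- function() {
  # groups {s1,s2} and {s3,s4}: within 0.1, between 0.9
  v <- matrix(0.9, 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  v[1, 2] <- v[2, 1] <- 0.1
  v[3, 4] <- v[4, 3] <- 0.1
  diag(v) <- 0
  dist_matrix(v)
}

test_that("PERMANOVA matches the hand-expanded example exactly", {
  m <- two_group_matrix()
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  res <- permanova(m, g)
  # SS_T = (2*0.01 + 4*0.81)/4 = 0.815; SS_W = 0.005 + 0.005 = 0.01
  # F = (0.805/1)/(0.01/2) = 161; exact p over the 3 distinct splits = 1/3
  expect_equal(res$pseudo_F, 161)
  expect_equal(res$p, 1 / 3)
  expect_true(res$exact)
  expect_equal(res$df_among, 1L)
  expect_equal(res$df_within, 2L)
})

test_that("PERMANOVA permutation F values match a brute-force oracle", {
  m <- random_dist(8, seed = 21)
  g <- setNames(rep(c("A", "B"), each = 4), rownames(m))
  res <- permanova(m, g)            # 70 distinct arrangements -> exact
  expect_true(res$exact)
  expect_equal(res$pseudo_F, oracle_pseudo_F(m, g[rownames(m)]))
  # recompute the exact p by enumerating complete relabelings
  splits <- combn(8, 4)
  f_all <- apply(splits, 2, function(idx) {
    gp <- rep("B", 8); gp[idx] <- "A"
    oracle_pseudo_F(m, gp)
  })
  expect_equal(res$p, mean(f_all >= res$pseudo_F - 1e-12))
  # and against the reference implementation's statistic
  ad <- vegan::adonis2(as.dist(unclass(m)) ~ grp,
                       data = data.frame(grp = g[rownames(m)]),
                       permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to sample order and label names", {
  m <- random_dist(9, seed = 5)
  g <- setNames(rep(c("x", "y", "z"), each = 3), rownames(m))
  r1 <- permanova(m, g)
  perm <- sample(rownames(m))
  m2 <- dist_matrix(unclass(m)[perm, perm])
  r2 <- permanova(m2, g[perm])
  g3 <- setNames(c(x = "north", y = "south", z = "west")[g], names(g))
  r3 <- permanova(m, g3)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$pseudo_F, r3$pseudo_F)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$p, r3$p)
  # Monte-Carlo p-values obey the add-one floor and determinism
  r4 <- permanova(m, g, n_perm = 99, seed = 2, exact = "never")
  r5 <- permanova(m, g, n_perm = 99, seed = 2, exact = "never")
  expect_identical(r4$p, r5$p)
  expect_gte(r4$p, 1 / 100)
  expect_error(permanova(random_dist(5, seed = 1, missing_pairs = 1),
                         setNames(c("a", "a", "b", "b", "b"),
                                  sprintf("s%02d", 1:5))),
               "missing")
})

test_that("pairwise PERMANOVA tests each pair and BH-adjusts", {
  set.seed(8)
  v <- matrix(0.8, 9, 9, dimnames = list(paste0("s", 1:9), paste0("s", 1:9)))
  v[1:3, 1:3] <- 0.1; v[4:6, 4:6] <- 0.1; v[7:9, 7:9] <- 0.15
  v <- (v + t(v)) / 2; diag(v) <- 0
  m <- dist_matrix(v)
  g <- setNames(rep(c("A", "B", "C"), each = 3), rownames(m))
  pw <- pairwise_permanova(m, g, n_perm = 99, seed = 3)
  expect_equal(nrow(pw), 3)            # C(3,2)
  expect_equal(pw$p_adj, p.adjust(pw$p, "BH"))
  expect_true(all(pw$p_adj >= pw$p))   # BH never decreases a raw p
  # hand example of the step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  # two groups: single unadjusted test
  g2 <- setNames(rep(c("A", "B"), c(5, 4)), rownames(m))
  pw2 <- pairwise_permanova(m, g2, n_perm = 99, seed = 3)
  expect_equal(nrow(pw2), 1)
  expect_equal(pw2$p, pw2$p_adj)
})

test_that("dispersion homogeneity flags unequal spreads and drops singletons", {
  # group A tight (around 0.2), group B wide (around 0.8)
  set.seed(44)
  v <- matrix(0.5, 10, 10,
              dimnames = list(paste0("s", 1:10), paste0("s", 1:10)))
  v[1:5, 1:5] <- 0.2; v[6:10, 6:10] <- 0.8
  jit <- matrix(runif(100, 0, 0.02), 10, 10)
  v <- v + jit + t(jit)
  diag(v) <- 0
  m <- dist_matrix(v)
  g <- setNames(rep(c("A", "B"), each = 5), rownames(m))
  res <- beta_dispersion(m, g, n_perm = 999, seed = 4)
  expect_lt(res$p, 0.05)
  expect_lt(res$group_dispersion[["A"]], res$group_dispersion[["B"]])
  # a singleton group is excluded rather than breaking the test
  g3 <- setNames(c(rep("A", 5), rep("B", 4), "C"), rownames(m))
  res3 <- beta_dispersion(m, g3, n_perm = 99, seed = 4)
  expect_identical(res3$dropped_groups, "C")
})

test_that("Mantel-Spearman is exact for monotone relations", {
  m1 <- random_dist(6, seed = 10)
  expect_equal(mantel_spearman(m1, m1)$rho, 1)
  m2 <- dist_matrix(unclass(m1)^2)              # monotone transform
  res <- mantel_spearman(m1, m2)
  expect_equal(res$rho, 1)
  expect_true(res$exact)
  expect_equal(res$p, 1 / factorial(6))         # only identity-equivalent top
  expect_error(mantel_spearman(m1, random_dist(5, seed = 2)),
               "different sample sets")
})

test_that("Mantel p matches the exhaustive 4-permutation oracle", {
  m1 <- random_dist(4, seed = 31)
  m2 <- random_dist(4, seed = 32)
  res <- mantel_spearman(m1, m2)
  expect_true(res$exact)
  expect_equal(res$n_perm, 24)
  v1 <- unclass(m1); v2 <- unclass(m2)
  lt <- lower.tri(v1)
  rhos <- apply(metaphylo:::all_permutations(4), 1, function(p) {
    vp <- v2[p, p]
    cor(v1[lt], vp[lt], method = "spearman")
  })
  expect_equal(res$p, mean(rhos >= res$rho - 1e-12))
  # reference implementation agrees on the statistic
  vm <- vegan::mantel(as.dist(v1), as.dist(v2), method = "spearman",
                      permutations = 99)
  expect_equal(res$rho, vm$statistic, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("adjusted Rand matches the contingency-table formula", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  # hand-computed: sum_ij = 0, a = b = 2, exp = 2/3, max = 2 -> -0.5
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  l1 <- c(1, 1, 1, 2, 2, 3)
  l2 <- c(1, 2, 1, 2, 3, 3)
  expect_equal(adjusted_rand(l1, l2), mclust::adjustedRandIndex(l1, l2))
})

test_that("k-means recovers separable regions and excludes wetlands", {
  ds <- generate_dataset(synth_config(n_regions = 4, samples_per_region = 8,
                                      n_species = 3,
                                      n_wetland_per_region = 1, seed = 11))
  ra <- kmeans_regions(ds$metadata, 4, seed = 3)
  expect_false(any(ds$metadata$sample_id[ds$metadata$wetland] %in%
                     names(ra$regions)))
  truth <- ds$truth$sample_regions[names(ra$regions)]
  expect_equal(adjusted_rand(ra$regions, truth), 1)
  # k = n gives zero within-cluster sum of squares
  md <- ds$metadata[!ds$metadata$wetland, ][1:6, ]
  expect_equal(kmeans_regions(md, 6, seed = 1)$wss, 0)
  expect_error(kmeans_regions(md, 7, seed = 1), "exceeds")
  # determinism under a fixed seed
  expect_identical(kmeans_regions(ds$metadata, 4, seed = 9)$regions,
                   kmeans_regions(ds$metadata, 4, seed = 9)$regions)
})

test_that("stability is perfect up to the true k and decays past it", {
  ds <- generate_dataset(synth_config(n_regions = 4, samples_per_region = 8,
                                      n_species = 3, seed = 11))
  ks <- kmeans_stability(ds$metadata, k_range = 2:6, n_pairs = 30, seed = 3)
  expect_equal(ks$stability$mean_ari[ks$stability$k == 4], 1)
  expect_lt(ks$stability$mean_ari[ks$stability$k == 6], 1)
  expect_equal(stable_k(ks), 4)
  expect_true(all(diff(ks$wss$wss) < 0))  # wss decreases in k
  ks2 <- kmeans_stability(ds$metadata, k_range = 2:3, n_pairs = 5, seed = 3)
  ks3 <- kmeans_stability(ds$metadata, k_range = 2:3, n_pairs = 5, seed = 3)
  expect_identical(ks2$ari, ks3$ari)
})

test_that("geodesic distances sit on the WGS84 ellipsoid", {
  md <- data.frame(sample_id = c("o", "e", "n"),
                   lat = c(0, 0, 1), lon = c(0, 1, 0),
                   year = 2020, wetland = FALSE)
  g <- geodesic_matrix(md)
  # one degree of longitude on the equator: 111319.4908 m (ellipsoidal);
  # one degree of latitude from the equator: 110574.3886 m
  expect_equal(g["o", "e"], 111319.4908, tolerance = 1e-9)
  expect_equal(g["o", "n"], 110574.3886, tolerance = 1e-8)
  expect_equal(g["o", "o"], 0)
  # triangle inequality on random coordinate triples
  set.seed(12)
  for (i in 1:10) {
    md2 <- data.frame(sample_id = c("a", "b", "c"),
                      lat = runif(3, 49, 52), lon = runif(3, -118, -113),
                      year = 2020, wetland = FALSE)
    G <- geodesic_matrix(md2)
    expect_lte(G["a", "c"], G["a", "b"] + G["b", "c"] + 1e-6)
  }
})

test_that("per-cluster PERMANOVA excludes untestable clusters from the FDR family", {
  set.seed(3)
  reg <- setNames(rep(c("r1", "r2"), each = 5), sprintf("s%02d", 1:10))
  strong <- two_group_like <- matrix(0.9, 10, 10,
                                     dimnames = list(names(reg), names(reg)))
  strong[1:5, 1:5] <- 0.05; strong[6:10, 6:10] <- 0.05; diag(strong) <- 0
  m_strong <- dist_matrix(strong)
  # a cluster matrix confined to one region is untestable
  m_one_region <- restrict_matrix(m_strong, sprintf("s%02d", 1:4))
  out <- per_cluster_permanova(list(a = m_strong, b = m_strong,
                                    c = m_one_region),
                               reg, n_perm = 199, seed = 6)
  expect_equal(attr(out, "n_testable"), 2)
  expect_false(out$testable[out$cluster == "c"])
  expect_true(all(out$p_adj[out$testable] < 0.05))
  expect_equal(attr(out, "frac_significant"), 1)
})
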