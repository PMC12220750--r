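test_that("Sorensen formula on simple presence profiles", {
  m <- presence_matrix(matrix(
    c(TRUE, TRUE, FALSE, FALSE,
      TRUE, TRUE, FALSE, FALSE,
      FALSE, FALSE, TRUE, TRUE,
      TRUE, TRUE, TRUE, FALSE), 4, 4, byrow = TRUE,
    dimnames = list(c("i", "j", "k", "l"), paste0("f", 1:4))))
  s <- sorensen_matrix(m)
  expect_equal(s["i", "j"], 0)            # identical rows
  expect_equal(s["i", "k"], 1)            # disjoint rows
  expect_equal(s["i", "l"], 1 / 5)        # a=2, b=0, c=1
  # a = 2, b = 1, c = 1 -> 1/3
  m2 <- presence_matrix(matrix(c(TRUE, TRUE, TRUE, FALSE,
                                 TRUE, TRUE, FALSE, TRUE), 2, 4,
                               byrow = TRUE,
                               dimnames = list(c("x", "y"), paste0("g", 1:4))))
  expect_equal(sorensen_matrix(m2)["x", "y"], 1 / 3)
})

test_that("Sorensen agrees with the set-arithmetic oracle and flags empty pairs", {
  set.seed(6)
  for (rep in 1:5) {
    pres <- random_presence(7, 10, p = 0.4)
    pres[2, ] <- FALSE                    # one empty sample
    pres <- presence_matrix(pres)
    s <- sorensen_matrix(pres)
    o <- oracle_sorensen(pres)
    diag(o) <- 0                          # diagonal fixed at zero
    expect_equal(unclass(s), o, tolerance = 1e-12, ignore_attr = TRUE)
    # an empty-vs-empty pair is undefined; empty-vs-occupied is 1
    expect_true(all(unclass(s)[2, -2] == 1))
  }
  # vegan cross-check on a non-degenerate instance
  pres <- random_presence(6, 12, p = 0.6, seed = 7)
  s <- sorensen_matrix(pres)
  v <- as.matrix(vegan::vegdist(unclass(pres) * 1, method = "bray"))
  expect_equal(unclass(s), v, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("per-cluster matrices restrict to occupied samples", {
  pres <- presence_matrix(matrix(
    c(TRUE, FALSE,
      FALSE, TRUE,
      TRUE, TRUE,
      FALSE, FALSE), 4, 2, byrow = TRUE,
    dimnames = list(c("X", "Y", "B", "Z"), c("e1", "e2"))))
  mats <- per_cluster_matrices(pres, list(c1 = c("e1", "e2")))
  m <- mats$c1
  expect_setequal(rownames(m), c("X", "Y", "B"))   # Z excluded
  expect_equal(m["X", "Y"], 1)                     # disjoint members
  expect_equal(m["X", "B"], 1 / 3)                 # a=1, b=0, c=1
  # cluster present in fewer than two samples: no pairs, no error
  empty <- per_cluster_matrices(pres[, 1, drop = FALSE][
    c("X"), , drop = FALSE], list(c1 = "e1"))
  expect_equal(nrow(empty$c1), 1)
})

test_that("intraspecific selection needs 2 haplotypes and 3+3 samples in 2 regions", {
  regions <- setNames(rep(c("r1", "r2"), each = 5),
                      sprintf("s%02d", 1:10))
  pres <- matrix(FALSE, 10, 3,
                 dimnames = list(names(regions), c("e1", "e2", "e3")))
  # qualifying cluster: 2 ESVs, present in 3 samples of each region
  pres[c(1:3, 6:8), "e1"] <- TRUE
  pres[c(1, 6), "e2"] <- TRUE
  # single-ESV cluster present everywhere
  pres[, "e3"] <- TRUE
  pres <- presence_matrix(pres)
  clusters <- list(good = c("e1", "e2"), single = "e3")
  expect_equal(select_intraspecific_clusters(clusters, pres, regions),
               "good")
  # same cluster with only one occupied region is excluded
  pres2 <- unclass(pres)
  pres2[6:8, "e1"] <- FALSE
  pres2[6, "e2"] <- FALSE
  expect_length(select_intraspecific_clusters(
    clusters["good"], presence_matrix(pres2), regions), 0)
  # 2+3 samples across the two regions is one short of the minimum six
  pres3 <- unclass(pres)
  pres3[3, c("e1", "e2")] <- FALSE
  expect_length(select_intraspecific_clusters(
    clusters["good"], presence_matrix(pres3), regions), 0)
})

test_that("mean dissimilarity averages over defined pairs only", {
  m1 <- dist_matrix(matrix(c(0, 0.2, 0.2, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  m2 <- dist_matrix(matrix(c(0, 0.6, 0.6, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  m3 <- dist_matrix(matrix(c(0, 0.7, 0.7, 0), 2, 2,
                           dimnames = list(c("a", "c"), c("a", "c"))))
  expect_equal(mean_dissimilarity(list(m1))["a", "b"], 0.2)
  expect_equal(mean_dissimilarity(list(m1, m2))["a", "b"], 0.4)
  mm <- mean_dissimilarity(list(m1, m3))
  expect_equal(mm["a", "c"], 0.7)          # defined in one matrix only
  expect_true(is.na(mm["b", "c"]))         # defined in none
  expect_error(mean_dissimilarity(list()), "no matrices")
  # with identical inputs the mean reproduces them exactly
  r <- random_dist(5, seed = 2)
  expect_equal(unclass(mean_dissimilarity(list(r, r, r))), unclass(r),
               ignore_attr = TRUE)
})

test_that("matrix completion removes greedy worst samples deterministically", {
  m <- random_dist(5, seed = 3)
  expect_equal(unclass(complete_matrix(m)), unclass(m),
               ignore_attr = TRUE)       # already complete
  # one sample missing all its pairs is the one removed
  v <- unclass(random_dist(5, seed = 4))
  v["s03", -3] <- NA; v[-3, "s03"] <- NA
  out <- complete_matrix(dist_matrix(v))
  expect_identical(attr(out, "removed"), "s03")
  expect_false(any(is.na(unclass(out))))
  # two samples missing only their mutual pair: exactly one goes, by id order
  v2 <- unclass(random_dist(4, seed = 5))
  v2["s01", "s02"] <- NA; v2["s02", "s01"] <- NA
  out2 <- complete_matrix(dist_matrix(v2))
  expect_identical(attr(out2, "removed"), "s01")
  expect_equal(nrow(out2), 3)
})
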