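test_that("distance_matrix matches hand values and the naive oracle", {
  d1 <- distance_matrix(rbind(c(0, 0), c(1, 1)), "manhattan")
  expect_equal(d1$d[1, 2], 2)
  d2 <- distance_matrix(rbind(c(0, 0), c(3, 4)), "euclidean")
  expect_equal(d2$d[1, 2], 5)

  set.seed(61)
  X <- matrix(rnorm(12), 6, 2)
  for (m in c("manhattan", "euclidean"))
    expect_equal(unname(distance_matrix(X, m)$d), naive_dist(X, m),
                 tolerance = 1e-12)

  Xna <- rbind(X, c(NA, 1))
  expect_warning(dna <- distance_matrix(Xna, "euclidean"), "dropped")
  expect_equal(nrow(dna$d), 6)
  expect_error(distance_matrix(matrix(1, 1, 2)), "at least 2")
})

test_that("ANOSIM gives R = 1 for perfectly separated groups", {
  set.seed(63)
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  res <- anosim(distance_matrix(X, "euclidean"), rep(c("a", "b"), each = 5),
                n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 100)
})

test_that("ANOSIM R agrees with a hand-computed rank table", {
  # 6 points on a line: groups {0,1,2} vs {10,11,12}; Manhattan distances.
  # Within pairs: 1,2,1 and 1,2,1; between: 10,11,12,9,10,11,8,9,10.
  # Average-tie ranks: the four 1s get 2.5, the two 2s get 5.5, then
  # 8 -> 7, the two 9s -> 8.5, the three 10s -> 11, the two 11s -> 13.5,
  # 12 -> 15. mean_within = (4*2.5 + 2*5.5)/6 = 3.5,
  # mean_between = (7 + 2*8.5 + 3*11 + 2*13.5 + 15)/9 = 11, M = 15,
  # so R = (11 - 3.5)/(15/2) = 1 exactly.
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(distance_matrix(x, "manhattan"), g, n_perm = 19, seed = 2)
  expect_equal(res$R, (11 - 3.5) / (15 / 2), tolerance = 1e-12)
})

test_that("ANOSIM matches vegan and is rank-transform invariant", {
  skip_if_not_installed("vegan")
  set.seed(67)
  for (k in 1:5) {
    n <- 18
    g <- sample(rep(c("a", "b", "c"), each = 6))
    X <- matrix(rnorm(n * 2) + (g == "a"), n)
    d <- dist(X, method = "manhattan")
    mine <- anosim(d, g, n_perm = 9)
    veg <- vegan::anosim(d, g, permutations = 2)
    expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-12)
    # strictly monotone transform of dissimilarities leaves R unchanged
    mono <- anosim(as.matrix(d)^3, g, n_perm = 9)
    expect_equal(mono$R, mine$R, tolerance = 1e-12)
    expect_true(mine$R >= -1 && mine$R <= 1)
  }
})

test_that("permutation p-values are reproducible and bounded below", {
  set.seed(71)
  X <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), 6)
  r1 <- anosim(dist(X), g, n_perm = 99, seed = 5)
  r2 <- anosim(dist(X), g, n_perm = 99, seed = 5)
  expect_identical(r1$R, r2$R)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 100)

  Y <- X + rnorm(24)
  m1 <- mantel_test(dist(X), dist(Y), n_perm = 99, seed = 6)
  m2 <- mantel_test(dist(X), dist(Y), n_perm = 99, seed = 6)
  expect_identical(m1$p, m2$p)
  expect_gte(m1$p, 1 / 100)
})

test_that("two-way ANOSIM averages the per-stratum one-way statistics", {
  set.seed(73)
  # two strata of 8 points each, 2 groups of 4 inside each stratum
  Xs <- lapply(1:2, function(s) matrix(rnorm(16) + rep(c(0, s), each = 4), 8))
  X <- rbind(Xs[[1]], Xs[[2]])
  a <- rep(rep(c("g1", "g2"), each = 4), 2)
  b <- rep(c("s1", "s2"), each = 8)
  two <- anosim_twoway(dist(X, "manhattan"), a, b, n_perm = 19, seed = 3)
  r1 <- anosim(dist(Xs[[1]], "manhattan"), a[1:8], n_perm = 1)$R
  r2 <- anosim(dist(Xs[[2]], "manhattan"), a[9:16], n_perm = 1)$R
  expect_equal(two$a$R, mean(c(r1, r2)), tolerance = 1e-12)

  # perfect separation of A within every stratum -> averaged R = 1
  Xp <- rbind(matrix(rnorm(8, 0, .01), 4), matrix(rnorm(8, 9, .01), 4),
              matrix(rnorm(8, 0, .01), 4), matrix(rnorm(8, 9, .01), 4))
  twop <- anosim_twoway(dist(Xp), a, b, n_perm = 19, seed = 4)
  expect_equal(twop$a$R, 1)

  expect_error(anosim_twoway(dist(X), rep("g1", 16), b, n_perm = 9),
               "cell|stratum|2 ")
})

test_that("pairwise ANOSIM builds the Bonferroni table", {
  set.seed(79)
  X <- matrix(rnorm(54 * 2), 54)
  g <- rep(paste0("t", 1:9), each = 6)
  tab <- anosim_pairwise(dist(X), g, n_perm = 19, seed = 7)
  expect_equal(nrow(tab), choose(9, 2))
  expect_true(all(tab$p_adj >= tab$p))
  expect_true(all(tab$p_adj <= 1))

  # three identical groups: every distance ties, R = 0, adjusted p = 1
  Xi <- matrix(rep(c(1, 2), each = 12), 12)
  gi <- rep(c("a", "b", "c"), 4)
  ti <- anosim_pairwise(dist(Xi), gi, n_perm = 19, seed = 8)
  expect_true(all(ti$p_adj == 1))
  expect_error(anosim_pairwise(dist(X[1:12, ]), rep(c("a", "b"), 6)),
               ">= 3 groups")
})

test_that("Mantel test handles identity, monotone transforms and errors", {
  set.seed(83)
  d <- dist(matrix(rnorm(20), 10, 2))
  same <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(same$r, 1)

  # order-preserving transform keeps Spearman r = 1; reversing gives -1
  up <- mantel_test(d, as.matrix(d)^2, n_perm = 9, seed = 2)
  expect_equal(up$r, 1)
  m <- as.matrix(d); mx <- max(m) + 1
  rev <- mx - m; diag(rev) <- 0
  dn <- mantel_test(d, rev, n_perm = 9, seed = 3)
  expect_equal(dn$r, -1)

  expect_error(mantel_test(d, dist(matrix(rnorm(8), 4))), "size")
  cst <- matrix(1, 10, 10); diag(cst) <- 0
  expect_error(mantel_test(d, cst), "constant")

  # invariance under joint relabeling of both matrices
  p <- sample(10)
  ma <- as.matrix(d); mb <- as.matrix(d)^1.7
  r0 <- mantel_test(ma, mb, n_perm = 9, seed = 4)$r
  r1 <- mantel_test(ma[p, p], mb[p, p], n_perm = 9, seed = 4)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("Mantel Spearman statistic matches vegan", {
  skip_if_not_installed("vegan")
  set.seed(89)
  for (k in 1:5) {
    d1 <- dist(matrix(rnorm(24), 12))
    d2 <- dist(matrix(rnorm(24), 12))
    mine <- mantel_test(d1, d2, n_perm = 9)
    veg <- vegan::mantel(d1, d2, method = "spearman", permutations = 2)
    expect_equal(mine$r, unname(veg$statistic), tolerance = 1e-12)
  }
})

test_that("ANOVA F matches the textbook formula and letters behave", {
  set.seed(97)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 4))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- anova_tukey(v, g)
  expect_equal(res$F, naive_anova_F(v, g), tolerance = 1e-10)
  # far-apart group must carry a letter not shared with the others
  lt <- setNames(res$table$letters, res$table$group)
  shared_ac <- intersect(strsplit(lt[["a"]], "")[[1]],
                         strsplit(lt[["c"]], "")[[1]])
  expect_equal(length(shared_ac), 0)

  expect_error(anova_tukey(rep(1, 10), rep(c("a", "b"), 5)),
               "zero within-group variance")

  # a single shuffled normal sample should usually share one letter
  hits <- 0
  for (k in 1:20) {
    vv <- rnorm(45)
    gg <- sample(rep(paste0("t", 1:5), 9))
    r <- anova_tukey(vv, gg)
    if (length(unique(r$table$letters)) == 1 &&
        r$table$letters[1] == "a") hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of runs
})
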