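test_that("KS statistic equals the brute-force ECDF-gap oracle on exhaustive small samples", {
  sets <- list()
  for (size in 1:4) sets <- c(sets, all_multisets(size, values = 1:3))
  mismatches <- 0
  for (x in sets) {
    for (y in sets) {
      D <- ks_two_sample(x, y)$D
      if (abs(D - brute_ks_D(x, y)) > 1e-12) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(ks_two_sample(c(0, 1), c(2, 3))$D, 1)
})

test_that("the asymptotic p-value matches the reference KS implementation", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1))
    y <- rnorm(sample(10:200, 1), mean = runif(1, 0, 1))
    mine <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-10)
    # reference evaluates the Kolmogorov series to a fixed 1e-6 tolerance
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-4)
  }
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("exhaustive permutation recovers the enumerated null", {
  # fully separated n = m = 2: 2 of the C(4,2) = 6 splits reach D = 1
  k <- ks_two_sample(c(0, 1), c(2, 3), method = "permutation")
  expect_equal(k$D, 1)
  expect_equal(k$p_value, 2 / 6)
  expect_equal(k$method, "permutation_exhaustive")
  # Monte Carlo mode is seeded and reproducible
  x <- rpois(30, 2); y <- rpois(40, 2)
  p1 <- ks_two_sample(x, y, method = "permutation", n_perm = 500, seed = 3)$p_value
  p2 <- ks_two_sample(x, y, method = "permutation", n_perm = 500, seed = 3)$p_value
  expect_equal(p1, p2)
})

test_that("asymptotic p-values are calibrated on continuous same-distribution samples", {
  # unequal sample sizes keep the lattice of attainable D values fine, so
  # the continuous-data asymptotic approximation applies
  set.seed(99)
  n_rep <- 2000
  rejected <- vapply(seq_len(n_rep), function(i) {
    ks_two_sample(rnorm(300), rnorm(451))$p_value < 0.05
  }, logical(1))
  rate <- mean(rejected)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("category comparisons report all pairs, symmetries and missing groups", {
  census <- tibble::tibble(gene_id = paste0("g", 1:60),
                           n_7mer = c(rpois(20, 3), rpois(20, 3), rpois(20, 3)))
  cats <- tibble::tibble(gene_id = census$gene_id,
                         category = rep(c("up", "down", "unchanged"), each = 20))
  res <- compare_categories(census, cats, field = "n_7mer")
  expect_equal(nrow(res), 3)
  expect_equal(res$n1, c(20L, 20L, 20L))
  # label swap of equal-size groups leaves D unchanged
  swapped <- cats
  swapped$category[swapped$category == "up"] <- "tmp"
  swapped$category[swapped$category == "down"] <- "up"
  swapped$category[swapped$category == "tmp"] <- "down"
  res2 <- compare_categories(census, swapped, field = "n_7mer")
  expect_equal(res$D[res$group1 == "up" & res$group2 == "down"],
               res2$D[res2$group1 == "up" & res2$group2 == "down"])
  # an empty category is reported as a missing comparison, not an error
  cats3 <- cats
  cats3$category[cats3$category == "down"] <- "unchanged"
  res3 <- compare_categories(census, cats3, field = "n_7mer")
  expect_true(all(is.na(res3$D[res3$group1 == "down" | res3$group2 == "down"])))
  expect_false(anyNA(res3$D[res3$group2 == "unchanged" & res3$group1 == "up"]))
  # excluded genes are dropped
  cats4 <- cats
  cats4$category[1:5] <- "excluded"
  res4 <- compare_categories(census, cats4, field = "n_7mer")
  expect_equal(res4$n1[1], 15L)
})

test_that("a planted +2 shift is detected with high power at n = 300 per side", {
  set.seed(123)
  detected <- vapply(1:50, function(i) {
    census <- tibble::tibble(gene_id = paste0("g", 1:600),
                             n_7mer = c(rpois(300, 2) + 2, rpois(300, 2)))
    cats <- tibble::tibble(gene_id = census$gene_id,
                           category = rep(c("up", "unchanged"), each = 300))
    res <- compare_categories(census, cats, field = "n_7mer")
    res$p_asymptotic[res$group1 == "up" & res$group2 == "unchanged"] < 0.05
  }, logical(1))
  expect_true(all(detected))
})

test_that("null categories give no spuriously extreme p-values", {
  set.seed(321)
  extreme <- vapply(1:100, function(i) {
    census <- tibble::tibble(gene_id = paste0("g", 1:450),
                             n_7mer = rpois(450, 1))
    cats <- tibble::tibble(gene_id = census$gene_id,
                           category = rep(c("up", "down", "unchanged"), each = 150))
    any(compare_categories(census, cats, field = "n_7mer")$p_asymptotic < 0.001)
  }, logical(1))
  expect_gte(mean(!extreme), 0.95)
})

test_that("GAAA binning uses left-open right-closed edges and the five standard bins", {
  census <- tibble::tibble(gene_id = paste0("g", 1:4), n_GAAA = c(5, 10, 11, 31))
  cats <- tibble::tibble(gene_id = census$gene_id, category = rep("up", 4))
  b <- bin_gaaa(census, cats)
  up <- b$bins[b$bins$category == "up", ]
  expect_equal(up$count[up$bin == "(0,10]"], 2L)   # 10 falls in (0,10]
  expect_equal(up$count[up$bin == "(10,20]"], 1L)
  expect_equal(up$count[up$bin == ">30"], 1L)
  expect_equal(b$summary$fraction_gt_10[b$summary$category == "up"], 0.5)
  expect_equal(b$summary$fraction_with_motif[b$summary$category == "up"], 1)

  # all-zero counts land in the "0" bin; absent categories are flagged empty
  census0 <- tibble::tibble(gene_id = paste0("g", 1:3), n_GAAA = c(0, 0, 0))
  cats0 <- tibble::tibble(gene_id = census0$gene_id, category = rep("down", 3))
  b0 <- bin_gaaa(census0, cats0)
  expect_equal(b0$bins$fraction[b0$bins$category == "down" & b0$bins$bin == "0"], 1)
  expect_equal(b0$summary$n[b0$summary$category == "up"], 0L)
  expect_true(is.na(b0$summary$fraction_gt_10[b0$summary$category == "up"]))
  # bin counts sum to category size
  expect_equal(sum(b0$bins$count[b0$bins$category == "down"]), 3L)
})

test_that("hypergeometric machinery matches enumeration and the pmf sums to one", {
  # pmf normalization over the full (N, n, m) grid up to N = 60
  worst <- 0
  for (N in 1:60) {
    for (n in 0:N) {
      for (m in 0:N) {
        supp <- max(0, n + m - N):min(n, m)
        pmf <- choose(m, supp) * choose(N - m, n - supp) / choose(N, n)
        worst <- max(worst, abs(sum(pmf) - 1))
      }
    }
  }
  expect_lt(worst, 1e-9)

  # exact tail equals enumeration on random configurations
  set.seed(17)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    n <- sample(0:N, 1)
    m <- sample(0:N, 1)
    k <- sample(max(0, n + m - N):min(n, m), 1)
    expect_equal(phyper(k - 1, m, N - m, n, lower.tail = FALSE),
                 enum_hyper_tail(k, n, m, N), tolerance = 1e-10)
  }
})

test_that("overlap_test reports counts, enrichment and both tail probabilities", {
  universe <- paste0("g", 1:10)
  ov <- overlap_test(universe[1:5], universe[1:5], universe)
  expect_equal(ov$k, 5L)
  expect_equal(ov$expected, 2.5)
  expect_equal(ov$fold, 2)
  expect_equal(ov$p_exact, 1 / 252)

  full <- overlap_test(universe, universe, universe)
  expect_equal(full$k, 10L)
  expect_equal(full$fold, 1)
  expect_equal(full$p_exact, 1)

  expect_warning(overlap_test(c(universe[1:3], "zz"), universe[1:3], universe),
                 "dropped 1")
  expect_error(overlap_test("a", "b", character()), "non-empty")
})

test_that("normal approximation converges to the exact tail for large universes", {
  # grid chosen so the expected overlap n*m/N is large enough for a normal
  # regime (a handful of expected genes is Poisson-like and out of scope)
  for (N in c(1e4, 5e4)) {
    n <- round(0.1 * N)
    m <- round(0.2 * N)
    universe <- c(paste0("a", 1:n), paste0("b", 1:(N - n)))
    for (k in round(c(0.9, 1, 1.1) * n * m / N)) {
      ov_p <- overlap_test(paste0("a", 1:n),
                           c(paste0("a", 1:k), paste0("b", 1:(m - k))),
                           universe)
      expect_lt(abs(ov_p$p_normal - ov_p$p_exact), 0.01)
    }
  }
})

test_that("random-list overlap enrichment averages to one", {
  set.seed(55)
  universe <- paste0("g", 1:2000)
  folds <- vapply(1:1000, function(i) {
    overlap_test(sample(universe, 100), sample(universe, 100), universe)$fold
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1), 3 * se)
})
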