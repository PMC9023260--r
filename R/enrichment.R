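# Distribution comparisons across DE categories, GAAA-count binning, and
# hypergeometric gene-list overlap.

# Two-sample KS statistic: sup over observed values of |ECDF_x - ECDF_y|.
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- findInterval(v, sort(x)) / length(x)
  Fy <- findInterval(v, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

# P(K <= t) for the Kolmogorov distribution. Series in the right tail;
# Jacobi-theta form for small t where the alternating series converges
# slowly.
pkolmogorov <- function(t) {
  if (t <= 0) return(0)
  if (t < 1) {
    k <- 1:20
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
    return(min(1, max(0, sqrt(2 * pi) / t * s)))
  }
  k <- 1:100
  min(1, max(0, 1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum distance between the two empirical CDFs, with
#' a p-value either from the asymptotic Kolmogorov distribution at
#' effective sample size `n1*n2/(n1+n2)` (the default, mirroring common
#' practice for genome-scale count comparisons) or from a seeded label
#' permutation. Motif counts are discrete, so the samples are heavily
#' tied; the asymptotic p is then conservative and the permutation mode is
#' the statistically safer choice. When the number of distinct splits
#' `choose(n1+n2, n1)` is at most `n_perm`, the permutation null is
#' enumerated exhaustively and `p = #\{D* >= D\}/n_splits`; otherwise `p =
#' (1 + #\{D* >= D\}) / (1 + n_perm)` over `n_perm` random splits.
#'
#' @param x,y non-empty numeric vectors (`NA` dropped).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm number of random permutations (default 10000).
#' @param seed optional integer seed for the permutation draw; the
#'   caller's RNG state is preserved.
#' @return an object of class `ks2_test`: a list with elements `D`,
#'   `p_value`, `n1`, `n2`, `method`.
#' @examples
#' ks_two_sample(c(0, 1), c(2, 3), method = "permutation")$p_value  # 2/6
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  D <- ks_statistic(x, y)
  eps <- 1e-12
  if (method == "asymptotic") {
    n_eff <- n1 * n2 / (n1 + n2)
    p <- 1 - pkolmogorov(sqrt(n_eff) * D)
  } else {
    pooled <- c(x, y)
    n_splits <- suppressWarnings(choose(n1 + n2, n1))
    if (is.finite(n_splits) && n_splits <= n_perm) {
      splits <- utils::combn(n1 + n2, n1)
      dstar <- apply(splits, 2L, function(i) ks_statistic(pooled[i], pooled[-i]))
      p <- mean(dstar >= D - eps)
      method <- "permutation_exhaustive"
    } else {
      p <- with_seed(seed, {
        dstar <- replicate(n_perm, {
          i <- sample.int(n1 + n2, n1)
          ks_statistic(pooled[i], pooled[-i])
        })
        (1 + sum(dstar >= D - eps)) / (1 + n_perm)
      })
    }
  }
  structure(
    list(D = D, p_value = min(1, max(0, p)), n1 = n1, n2 = n2, method = method),
    class = "ks2_test"
  )
}

#' @export
print.ks2_test <- function(x, ...) {
  cat(sprintf("Two-sample Kolmogorov-Smirnov test (%s)\n", x$method))
  cat(sprintf("  D = %.4g, p = %.4g  (n1 = %d, n2 = %d)\n", x$D, x$p_value, x$n1, x$n2))
  invisible(x)
}

category_values <- function(categories) {
  if (is.data.frame(categories)) {
    stopifnot(all(c("gene_id", "category") %in% names(categories)))
    cats <- stats::setNames(as.character(categories$category), categories$gene_id)
  } else {
    stopifnot(!is.null(names(categories)))
    cats <- stats::setNames(as.character(categories), names(categories))
  }
  cats
}

#' Compare a motif statistic across DE categories
#'
#' Pairwise two-sample KS comparisons (up vs unchanged, down vs unchanged,
#' up vs down) of a per-gene field, typically `n_5mer`, `n_7mer`, `n_GAAA`
#' (from [motif_census()]) or `score` (from [arescore()]). Genes in the
#' `excluded` category, and genes missing from either input, are dropped.
#' An empty category yields a row with `NA` statistics rather than an
#' error. Raw (uncorrected) p-values are reported for the three pairs.
#'
#' @param census a tibble with `gene_id` and the column named by `field`.
#' @param categories a tibble with `gene_id`, `category` (e.g. the output
#'   of [read_de_table()]), or a named character vector.
#' @param field name of the column of `census` to compare.
#' @param n_perm if greater than 0, also report a seeded permutation
#'   p-value (`p_permutation`) with this many permutations.
#' @param seed seed for the permutation draws.
#' @return a tibble with one row per category pair: `field`, `group1`,
#'   `group2`, `n1`, `n2`, `mean1`, `mean2`, `median1`, `median2`, `D`,
#'   `p_asymptotic`, `p_permutation`.
#' @export
compare_categories <- function(census, categories, field = "n_7mer",
                               n_perm = 0L, seed = NULL) {
  stopifnot(is.data.frame(census), "gene_id" %in% names(census))
  if (!field %in% names(census)) {
    stop(sprintf("column '%s' not found in `census`", field), call. = FALSE)
  }
  cats <- category_values(categories)
  cat_of <- unname(cats[match(census$gene_id, names(cats))])
  keep <- !is.na(cat_of) & cat_of %in% c("up", "down", "unchanged")
  vals <- split(census[[field]][keep], cat_of[keep])
  pairs <- list(c("up", "unchanged"), c("down", "unchanged"), c("up", "down"))
  rows <- lapply(pairs, function(pr) {
    v1 <- vals[[pr[1L]]]
    v2 <- vals[[pr[2L]]]
    base <- tibble::tibble(
      field = field, group1 = pr[1L], group2 = pr[2L],
      n1 = length(v1), n2 = length(v2),
      mean1 = if (length(v1)) mean(v1) else NA_real_,
      mean2 = if (length(v2)) mean(v2) else NA_real_,
      median1 = if (length(v1)) median(v1) else NA_real_,
      median2 = if (length(v2)) median(v2) else NA_real_
    )
    if (length(v1) == 0L || length(v2) == 0L) {
      base$D <- NA_real_
      base$p_asymptotic <- NA_real_
      base$p_permutation <- NA_real_
      return(base)
    }
    ks <- ks_two_sample(v1, v2, method = "asymptotic")
    base$D <- ks$D
    base$p_asymptotic <- ks$p_value
    base$p_permutation <- if (n_perm > 0L) {
      ks_two_sample(v1, v2, method = "permutation", n_perm = n_perm, seed = seed)$p_value
    } else {
      NA_real_
    }
    base
  })
  do.call(rbind, rows)
}

#' Bin per-gene GAAA counts into the five standard categories
#'
#' Bins a per-gene motif count into `n = 0`, `(0,10]`, `(10,20]`,
#' `(20,30]`, `> 30` (left-open, right-closed: a count of exactly 10 falls
#' in `(0,10]`). Also reports, per category, the share of genes above the
#' second bin edge (`fraction_gt_10`) and the share with at least one
#' occurrence (`fraction_with_motif`, the quantity behind
#' "lacking vs containing one or more" pie charts).
#'
#' @inheritParams compare_categories
#' @param field count column of `census` to bin (default `"n_GAAA"`).
#' @param breaks increasing vector of inner bin edges (default
#'   `c(0, 10, 20, 30)`).
#' @return a list with `bins` (tibble: `category`, `bin`, `count`,
#'   `fraction`) and `summary` (tibble: `category`, `n`, `fraction_gt_10`,
#'   `fraction_with_motif`); categories absent from the data appear with
#'   `n = 0` and `NA` fractions.
#' @export
bin_gaaa <- function(census, categories, field = "n_GAAA", breaks = c(0, 10, 20, 30)) {
  stopifnot(is.data.frame(census), field %in% names(census), length(breaks) >= 2L,
            !is.unsorted(breaks, strictly = TRUE))
  cats <- category_values(categories)
  cat_of <- unname(cats[match(census$gene_id, names(cats))])
  keep <- !is.na(cat_of) & cat_of %in% c("up", "down", "unchanged")
  x <- census[[field]][keep]
  g <- factor(cat_of[keep], levels = c("up", "down", "unchanged"))
  edges <- c(-Inf, breaks, Inf)
  labels <- c(
    sprintf("%g", breaks[1L]),
    sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1L]),
    sprintf(">%g", breaks[length(breaks)])
  )
  binned <- cut(x, breaks = edges, labels = labels, right = TRUE)
  tab <- table(category = g, bin = binned)
  bins <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(bins)[names(bins) == "Freq"] <- "count"
  n_per <- as.integer(table(g)[bins$category])
  bins$fraction <- ifelse(n_per > 0L, bins$count / n_per, NA_real_)
  summary <- tibble::tibble(
    category = levels(g),
    n = as.integer(table(g)),
    fraction_gt_10 = vapply(levels(g), function(lv) {
      xv <- x[g == lv]
      if (length(xv) == 0L) NA_real_ else mean(xv > breaks[2L])
    }, numeric(1L), USE.NAMES = FALSE),
    fraction_with_motif = vapply(levels(g), function(lv) {
      xv <- x[g == lv]
      if (length(xv) == 0L) NA_real_ else mean(xv >= 1)
    }, numeric(1L), USE.NAMES = FALSE)
  )
  list(bins = bins, summary = summary)
}

#' Hypergeometric gene-list overlap test
#'
#' Tests whether two gene lists drawn from a common universe share more
#' genes than expected by chance. Reports the observed overlap `k`, the
#' expected overlap `n*m/N`, the fold enrichment `k/expected`, the exact
#' hypergeometric upper-tail probability `P(K >= k)`, and the normal
#' approximation of that tail with continuity correction (the
#' approximation commonly used for genome-scale Venn overlap analysis; the
#' exact tail is its oracle and the two converge as the universe grows).
#' Identifiers outside the universe are dropped with a warning.
#'
#' @param list_a,list_b character vectors of gene identifiers.
#' @param universe character vector: all genes the lists were drawn from.
#' @return an object of class `overlap_test`: a list with `k`, `n`, `m`,
#'   `N`, `expected`, `fold`, `p_exact`, `p_normal`.
#' @examples
#' overlap_test(letters[1:5], letters[1:5], letters[1:10])$p_exact  # 1/252
#' @export
overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("`universe` must be non-empty", call. = FALSE)
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  drop_a <- setdiff(a, universe)
  drop_b <- setdiff(b, universe)
  if (length(drop_a) + length(drop_b) > 0L) {
    warning(sprintf("dropped %d id(s) from list_a and %d from list_b not in the universe",
                    length(drop_a), length(drop_b)), call. = FALSE)
  }
  a <- intersect(a, universe)
  b <- intersect(b, universe)
  k <- length(intersect(a, b))
  n <- as.numeric(length(a))
  m <- as.numeric(length(b))
  N <- as.numeric(length(universe))
  expected <- n * m / N
  fold <- if (expected > 0) k / expected else NA_real_
  p_exact <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  mu <- expected
  sigma2 <- n * m * (N - n) * (N - m) / (N^2 * (N - 1))
  p_normal <- if (sigma2 > 0) {
    pnorm(k - 0.5, mean = mu, sd = sqrt(sigma2), lower.tail = FALSE)
  } else {
    as.numeric(k >= mu)  # degenerate draw: overlap is deterministic
  }
  structure(
    list(k = k, n = n, m = m, N = N, expected = expected, fold = fold,
         p_exact = p_exact, p_normal = min(1, max(0, p_normal))),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric gene-list overlap\n")
  cat(sprintf("  overlap k = %d of lists n = %d, m = %d in universe N = %d\n",
              x$k, as.integer(x$n), as.integer(x$m), as.integer(x$N)))
  cat(sprintf("  expected = %.3g, fold enrichment = %.3g\n", x$expected, x$fold))
  cat(sprintf("  p (exact upper tail) = %.3g, p (normal approx.) = %.3g\n",
              x$p_exact, x$p_normal))
  invisible(x)
}
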