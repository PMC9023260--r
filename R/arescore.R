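# AREScore-like scoring of 3'UTRs. The score summarizes the three classic
# ARE features: how many AUUUA pentamers a UTR carries, how tightly they
# cluster, and how AU-rich their immediate flanks are. This is a
# re-parameterization of the published AREScore idea with documented,
# user-settable constants -- not a reproduction of the original program's
# numbers; every result carries the parameters that produced it.

#' Parameters for the AREScore-like function
#'
#' @param pentamer_weight score contributed by each AUUUA occurrence
#'   (default 1).
#' @param cluster_bonus score added for each consecutive pentamer pair in
#'   close proximity (default 1.5).
#' @param cluster_max_gap maximum gap (nt between the end of one pentamer
#'   and the start of the next, i.e. start-to-start distance minus 5) for a
#'   pair to earn the cluster bonus; overlapping pentamers (negative gap)
#'   always qualify (default 10).
#' @param au_context_weight score added per qualifying flank side of a
#'   pentamer, up to two sides (default 0.5).
#' @param au_context_window flank width in nt examined on each side
#'   (default 5); a flank truncated by the sequence end is evaluated on its
#'   available bases, and an empty flank never qualifies.
#' @param au_context_min_fraction minimum A+U fraction for a flank to
#'   qualify (default 0.8).
#' @return an object of class `arescore_params`.
#' @export
arescore_params <- function(pentamer_weight = 1,
                            cluster_bonus = 1.5,
                            cluster_max_gap = 10,
                            au_context_weight = 0.5,
                            au_context_window = 5,
                            au_context_min_fraction = 0.8) {
  p <- list(
    pentamer_weight = pentamer_weight,
    cluster_bonus = cluster_bonus,
    cluster_max_gap = cluster_max_gap,
    au_context_weight = au_context_weight,
    au_context_window = au_context_window,
    au_context_min_fraction = au_context_min_fraction
  )
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!all(vapply(p, num1, logical(1L)))) {
    stop("all AREScore parameters must be single finite numbers", call. = FALSE)
  }
  if (p$pentamer_weight < 0 || p$cluster_bonus < 0 || p$au_context_weight < 0) {
    stop("AREScore weights must be non-negative", call. = FALSE)
  }
  if (p$au_context_min_fraction < 0 || p$au_context_min_fraction > 1) {
    stop("`au_context_min_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (p$au_context_window < 0) stop("`au_context_window` must be >= 0", call. = FALSE)
  structure(p, class = "arescore_params")
}

#' @export
print.arescore_params <- function(x, ...) {
  cat("AREScore-like parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

au_fraction <- function(chars) {
  if (length(chars) == 0L) return(NA_real_)
  mean(chars == "A" | chars == "U")
}

.arescore1 <- function(sequence, params) {
  hits <- find_motif(sequence, "AUUUA")
  n_pent <- nrow(hits)
  if (n_pent == 0L) {
    return(c(score = 0, n_pentamers = 0, n_cluster_bonuses = 0, n_context_bonuses = 0))
  }
  n_clust <- 0L
  if (n_pent >= 2L) {
    gaps <- hits$start[-1L] - hits$end[-n_pent] - 1L  # nt between consecutive pentamers
    n_clust <- sum(gaps <= params$cluster_max_gap)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  w <- as.integer(params$au_context_window)
  n_ctx <- 0L
  span <- function(lo, hi) if (hi < lo) character() else chars[lo:hi]
  for (i in seq_len(n_pent)) {
    left <- span(max(1L, hits$start[i] - w), hits$start[i] - 1L)
    right <- span(hits$end[i] + 1L, min(n, hits$end[i] + w))
    fl <- au_fraction(left)
    fr <- au_fraction(right)
    n_ctx <- n_ctx + sum(!is.na(fl) && fl >= params$au_context_min_fraction,
                         !is.na(fr) && fr >= params$au_context_min_fraction)
  }
  score <- params$pentamer_weight * n_pent +
    params$cluster_bonus * n_clust +
    params$au_context_weight * n_ctx
  c(score = score, n_pentamers = n_pent, n_cluster_bonuses = n_clust,
    n_context_bonuses = n_ctx)
}

#' AREScore-like score of 3'UTR sequences
#'
#' `score = pentamer_weight * n_pentamers + cluster_bonus *
#' n_cluster_bonuses + au_context_weight * n_context_bonuses`, where
#' pentamers are overlapping AUUUA occurrences, a cluster bonus is earned
#' by each consecutive pentamer pair whose gap is at most
#' `cluster_max_gap`, and a context bonus by each flank side (up to two
#' per pentamer) whose `au_context_window` is sufficiently A/U-rich. A
#' sequence without pentamers scores exactly 0.
#'
#' @param utrs a UTR set (tibble with `gene_id`, `sequence`) or a
#'   character vector of sequences (names taken as gene ids).
#' @param params an [arescore_params()] object.
#' @return a tibble with columns `gene_id`, `score`, `n_pentamers`,
#'   `n_cluster_bonuses`, `n_context_bonuses`.
#' @examples
#' arescore("GGGGGAUUUAGGGGG")$score  # 1: one pentamer, no bonuses
#' @export
arescore <- function(utrs, params = arescore_params()) {
  if (!inherits(params, "arescore_params")) {
    stop("`params` must be created with arescore_params()", call. = FALSE)
  }
  s <- as_sequence_set(utrs)
  m <- vapply(s$sequence, .arescore1, numeric(4L), params = params, USE.NAMES = FALSE)
  out <- tibble::tibble(
    gene_id = s$gene_id,
    score = m[1L, ],
    n_pentamers = as.integer(m[2L, ]),
    n_cluster_bonuses = as.integer(m[3L, ]),
    n_context_bonuses = as.integer(m[4L, ])
  )
  attr(out, "params") <- params
  out
}
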