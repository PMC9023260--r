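# Seeded generator of synthetic 3'UTR cohorts with planted,
# category-dependent motif densities, plus a matching DE table. The
# defaults emulate the structure of a knockout-spleen transcriptome:
# 549 up / 603 down / 15684 unchanged genes, AU-biased UTRs with a
# log-normal length law, and a higher planted 7-mer rate in the
# upregulated category.

#' Configuration for a synthetic 3'UTR cohort
#'
#' Planted motif counts per gene are Poisson at a category-specific rate,
#' so enrichment is distributional (many genes with none, some with
#' several), mirroring the many-vs-none structure of real motif censuses.
#'
#' @param n_up,n_down,n_unchanged gene counts per category (defaults
#'   549/603/15684, the cohort sizes of the study design emulated).
#' @param utr_length_median median UTR length in nt of the log-normal
#'   length law (default 900).
#' @param utr_length_sdlog dispersion (sd of log length, default 0.9).
#' @param min_utr_length lower clamp on lengths in nt (default 50).
#' @param background_AU_fraction A+U share of the i.i.d. background
#'   (default 0.55; A and U equiprobable within it, likewise G and C).
#' @param planted_7mer_rate named vector of mean planted UAUUUAU motifs
#'   per gene for `up`, `down`, `unchanged` (default 1.2/0.3/0.3).
#' @param planted_5mer_extra_rate mean additional lone AUUUA pentamers per
#'   gene, per category (default 0.5 each).
#' @param planted_GAAA_rate mean planted GAAA motifs per gene, per
#'   category (default 4/2/2; background occurrences add to these).
#' @param effect_log2fc mean |log2 fold change| drawn for DE genes
#'   (default 3).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_up = 549L, n_down = 603L, n_unchanged = 15684L,
                             utr_length_median = 900, utr_length_sdlog = 0.9,
                             min_utr_length = 50L,
                             background_AU_fraction = 0.55,
                             planted_7mer_rate = c(up = 1.2, down = 0.3, unchanged = 0.3),
                             planted_5mer_extra_rate = c(up = 0.5, down = 0.5, unchanged = 0.5),
                             planted_GAAA_rate = c(up = 4, down = 2, unchanged = 2),
                             effect_log2fc = 3,
                             seed = 1L) {
  rate_vec <- function(r, what) {
    if (length(r) == 1L && is.null(names(r))) r <- c(up = r, down = r, unchanged = r)
    if (!all(c("up", "down", "unchanged") %in% names(r)) || any(r < 0)) {
      stop(sprintf("`%s` needs non-negative rates named up/down/unchanged", what),
           call. = FALSE)
    }
    r[c("up", "down", "unchanged")]
  }
  stopifnot(n_up >= 0, n_down >= 0, n_unchanged >= 0,
            utr_length_median > 0, utr_length_sdlog >= 0, min_utr_length >= 1,
            background_AU_fraction >= 0, background_AU_fraction <= 1,
            effect_log2fc >= 0)
  structure(list(
    n_up = as.integer(n_up), n_down = as.integer(n_down),
    n_unchanged = as.integer(n_unchanged),
    utr_length_median = utr_length_median,
    utr_length_sdlog = utr_length_sdlog,
    min_utr_length = as.integer(min_utr_length),
    background_AU_fraction = background_AU_fraction,
    planted_7mer_rate = rate_vec(planted_7mer_rate, "planted_7mer_rate"),
    planted_5mer_extra_rate = rate_vec(planted_5mer_extra_rate, "planted_5mer_extra_rate"),
    planted_GAAA_rate = rate_vec(planted_GAAA_rate, "planted_GAAA_rate"),
    effect_log2fc = effect_log2fc,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate one synthetic 3'UTR with planted motifs
#'
#' Background bases are i.i.d. with the given A+U share (A and U
#' equiprobable within it, G and C within the rest). Each planted motif
#' copy is written at a uniformly chosen position such that planted copies
#' never overlap one another; the result therefore contains at least the
#' planted number of occurrences of each motif (the background can create
#' extra occurrences by chance). Uses the current RNG stream; seed with
#' `set.seed()` or via [generate_cohort()].
#'
#' @param length sequence length in nt.
#' @param AU_fraction A+U share of the background in `[0,1]`.
#' @param planted named integer vector of motif copy numbers, e.g.
#'   `c(UAUUUAU = 3, GAAA = 2)` (or `NULL` for none).
#' @return a single RNA string.
#' @examples
#' set.seed(1)
#' generate_utr(7, 0.5, c(UAUUUAU = 1))  # "UAUUUAU": no room for background
#' @export
generate_utr <- function(length, AU_fraction, planted = NULL) {
  stopifnot(is.numeric(length), length >= 0, AU_fraction >= 0, AU_fraction <= 1)
  length <- as.integer(length)
  prob <- c(AU_fraction / 2, (1 - AU_fraction) / 2, (1 - AU_fraction) / 2, AU_fraction / 2)
  chars <- sample(RNA_BASES, length, replace = TRUE, prob = prob)
  if (!is.null(planted)) {
    planted <- planted[planted > 0]
  }
  if (!is.null(planted) && length(planted) > 0L) {
    if (is.null(names(planted))) stop("`planted` must be a named vector", call. = FALSE)
    motifs <- rep(normalize_rna(names(planted)), times = planted)
    widths <- nchar(motifs)
    if (sum(widths) > length) {
      stop(sprintf("cannot plant %d nt of motifs into a %d nt sequence",
                   sum(widths), length), call. = FALSE)
    }
    # uniform non-overlapping placement by the gap-composition construction:
    # shuffle the motif identities into a left-to-right order, distribute the
    # slack uniformly among the k+1 gaps, and lay the motifs down in turn.
    # Always succeeds when the total planted width fits, even at high density.
    k <- length(motifs)
    perm <- if (k > 1L) sample.int(k) else 1L
    motifs <- motifs[perm]
    widths <- widths[perm]
    slack <- length - sum(widths)
    u <- sort(sample.int(slack + k, k))
    gaps_before <- u - seq_len(k)            # cumulative slack, in [0, slack]
    starts <- gaps_before + c(0L, cumsum(widths[-k])) + 1L
    for (i in seq_len(k)) {
      chars[starts[i]:(starts[i] + widths[i] - 1L)] <- strsplit(motifs[i], "", fixed = TRUE)[[1L]]
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic cohort: UTRs, DE table and planted truth
#'
#' Draws per-gene UTR lengths from the configured log-normal law, plants
#' Poisson-distributed UAUUUAU / lone-AUUUA / GAAA motif counts at the
#' category rates, and emits a matching DE table in which up/down genes
#' have `|log2fc|` above threshold and `padj < 0.05` while unchanged genes
#' do not, so [categorize_de()] with default thresholds recovers exactly
#' the configured category sizes. Fully reproducible from `config$seed`
#' (one seeded stream per cohort; the caller's RNG state is untouched).
#'
#' @param config a [synthetic_config()] object.
#' @return an object of class `synthetic_cohort`: a list with `utrs` (a
#'   UTR set), `de` (a DE tibble as from [read_de_table()]) and `truth`
#'   (tibble: `gene_id`, `category`, `planted_7mer`, `planted_5mer_extra`,
#'   `planted_GAAA`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- c(up = config$n_up, down = config$n_down, unchanged = config$n_unchanged)
    category <- rep(names(n), times = n)
    total <- length(category)
    gene_id <- sprintf("gene%05d", seq_len(total))
    k7 <- rpois(total, config$planted_7mer_rate[category])
    k5 <- rpois(total, config$planted_5mer_extra_rate[category])
    kg <- rpois(total, config$planted_GAAA_rate[category])
    need <- 7L * k7 + 5L * k5 + 4L * kg
    len <- pmax(
      config$min_utr_length,
      round(rlnorm(total, log(config$utr_length_median), config$utr_length_sdlog)),
      3L * need  # leave room so non-overlapping placement always succeeds
    )
    sequence <- vapply(seq_len(total), function(i) {
      generate_utr(len[i], config$background_AU_fraction,
                   c(UAUUUAU = k7[i], AUUUA = k5[i], GAAA = kg[i]))
    }, character(1L))
    utrs <- tibble::tibble(
      gene_id = gene_id,
      transcript_id = paste0(gene_id, ".t1"),
      sequence = sequence,
      length = nchar(sequence)
    )
    log2fc <- numeric(total)
    draw_de <- function(idx, sign) {
      # |log2fc| around effect_log2fc, redrawn into the DE region (> 1)
      v <- rnorm(length(idx), config$effect_log2fc, 0.5)
      while (any(v <= 1)) v[v <= 1] <- rnorm(sum(v <= 1), config$effect_log2fc, 0.5)
      sign * v
    }
    is_up <- category == "up"
    is_down <- category == "down"
    is_unch <- category == "unchanged"
    if (any(is_up)) log2fc[is_up] <- draw_de(which(is_up), 1)
    if (any(is_down)) log2fc[is_down] <- draw_de(which(is_down), -1)
    if (any(is_unch)) {
      v <- rnorm(sum(is_unch), 0, 0.3)
      while (any(abs(v) >= 1)) v[abs(v) >= 1] <- rnorm(sum(abs(v) >= 1), 0, 0.3)
      log2fc[is_unch] <- v
    }
    padj <- numeric(total)
    padj[is_up | is_down] <- 10^(-runif(sum(is_up | is_down), 1.5, 16))
    padj[is_unch] <- runif(sum(is_unch), 0.05, 1)
    read_support <- 10 + round(rlnorm(total, log(300), 1.2))
    de <- tibble::tibble(
      gene_id = gene_id,
      read_support = read_support,
      log2fc = log2fc,
      padj = padj,
      category = categorize_de(read_support, log2fc, padj)
    )
    truth <- tibble::tibble(
      gene_id = gene_id,
      category = category,
      planted_7mer = k7,
      planted_5mer_extra = k5,
      planted_GAAA = kg
    )
    structure(list(utrs = utrs, de = de, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic 3'UTR cohort\n")
  cat(sprintf("  genes: %d (up %d / down %d / unchanged %d), seed %d\n",
              nrow(x$utrs), x$config$n_up, x$config$n_down, x$config$n_unchanged,
              x$config$seed))
  cat(sprintf("  UTR length: median %d nt (range %d-%d)\n",
              as.integer(median(x$utrs$length)), min(x$utrs$length), max(x$utrs$length)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the dialects the readers consume: a 3'UTR FASTA
#' (headers `gene_id|transcript_id`), a DE TSV (`gene_id`, `read_support`,
#' `log2fc`, `padj`) and a planted-truth TSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    utr_fasta = file.path(dir, "utrs.fasta"),
    de_table = file.path(dir, "de_table.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_utr_fasta(cohort$utrs, paths[["utr_fasta"]])
  de <- cohort$de[, c("gene_id", "read_support", "log2fc", "padj")]
  write.table(de, paths[["de_table"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
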