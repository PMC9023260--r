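# Readers and writers for the formats the pipeline touches: 3'UTR FASTA,
# DE results TSV, and the packaged gel-shift probe panel.

#' Read a 3'UTR FASTA file
#'
#' Headers are `gene_id|transcript_id` (pipe-delimited); a header with a
#' single token is taken as both identifiers. Sequences may be DNA or RNA in
#' any case and are normalized to upper-case RNA (`T -> U`) at ingest, so a
#' single alphabet is used internally for both AU-rich (UAUUUAU) and
#' GAAA-type motifs. Record order is preserved; multiple transcripts per
#' gene are retained (isoform selection happens in [select_longest_utr()]).
#'
#' @param path path to a FASTA file.
#' @return a tibble (one row per record) with columns `gene_id`,
#'   `transcript_id`, `sequence`, `length` (nt).
#' @seealso [write_utr_fasta()], [select_longest_utr()]
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^[[:space:]]*$", lines))
  if (length(nonblank) == 0L) {
    return(tibble::tibble(gene_id = character(), transcript_id = character(),
                          sequence = character(), length = integer()))
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop(sprintf("malformed FASTA in '%s': line %d does not start with '>'",
                 path, nonblank[1L]), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  headers <- names(set)
  ids <- stringi::stri_split_fixed(headers, "|", n = 2L)
  gene_id <- vapply(ids, `[[`, "", 1L)
  transcript_id <- vapply(ids, function(f) if (length(f) > 1L) f[[2L]] else f[[1L]], "")
  seqs <- normalize_rna(as.character(set), ids = headers)
  tibble::tibble(
    gene_id = gene_id,
    transcript_id = transcript_id,
    sequence = unname(seqs),
    length = nchar(seqs)
  )
}

#' Write a UTR set to FASTA
#'
#' Inverse of [read_utr_fasta()]: headers are `gene_id|transcript_id`, and
#' re-reading the written file reproduces the input records.
#'
#' @param utrs a UTR set as returned by [read_utr_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  stopifnot(is_utr_set(utrs), "transcript_id" %in% names(utrs))
  set <- Biostrings::BStringSet(utrs$sequence)
  names(set) <- paste(utrs$gene_id, utrs$transcript_id, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Select the longest 3'UTR isoform per gene
#'
#' Keeps exactly one record per `gene_id`: the one with maximal `length`.
#' Equal-length ties are broken by the lexicographically smallest
#' `transcript_id`, a deterministic convention. Genes appear in order of
#' first appearance in the input.
#'
#' @param utrs a UTR set as returned by [read_utr_fasta()].
#' @return a UTR set with one row per gene.
#' @export
select_longest_utr <- function(utrs) {
  stopifnot(is_utr_set(utrs))
  if (nrow(utrs) == 0L) return(utrs)
  idx <- split(seq_len(nrow(utrs)), factor(utrs$gene_id, levels = unique(utrs$gene_id)))
  pick <- vapply(idx, function(i) {
    cand <- i[utrs$length[i] == max(utrs$length[i])]
    cand[order(utrs$transcript_id[cand])][1L]
  }, integer(1L))
  utrs[unname(pick), , drop = FALSE]
}

#' Assign differential-expression categories
#'
#' The categorization rule of the study design: a gene is `excluded` when
#' its read support is below the detection threshold (default 10 reads);
#' otherwise `up` when `log2fc > fc_threshold` and `padj < p_threshold`,
#' `down` when `log2fc < -fc_threshold` and `padj < p_threshold`, else
#' `unchanged`. A detected gene with missing `log2fc` or `padj` is
#' `unchanged`, not excluded: DE tools emit missing adjusted p-values for
#' independence-filtered genes that are nonetheless detected.
#'
#' @param read_support non-negative numeric vector (mean counts/reads).
#' @param log2fc numeric vector, may contain `NA`.
#' @param padj numeric vector in `[0,1]`, may contain `NA`.
#' @param detection_threshold minimum read support for a gene to count as
#'   detected (default 10).
#' @param p_threshold adjusted p-value cutoff (default 0.05).
#' @param fc_threshold absolute log2 fold-change cutoff (default 1).
#' @return character vector over `{"up","down","unchanged","excluded"}`.
#' @export
categorize_de <- function(read_support, log2fc, padj,
                          detection_threshold = 10, p_threshold = 0.05, fc_threshold = 1) {
  stopifnot(length(log2fc) == length(read_support), length(padj) == length(read_support))
  if (any(!is.na(padj) & (padj < 0 | padj > 1))) {
    stop("`padj` must lie in [0, 1]", call. = FALSE)
  }
  sig <- !is.na(padj) & !is.na(log2fc) & padj < p_threshold
  out <- rep("unchanged", length(read_support))
  out[sig & log2fc > fc_threshold] <- "up"
  out[sig & log2fc < -fc_threshold] <- "down"
  out[!is.na(read_support) & read_support < detection_threshold] <- "excluded"
  out
}

#' Read a differential-expression results table
#'
#' Consumes (never computes) the output of a standard DE tool: a TSV with
#' header columns `gene_id`, `read_support`, `log2fc`, `padj`; missing
#' values encoded as `NA` or empty fields. Each row is categorized with
#' [categorize_de()].
#'
#' @inheritParams categorize_de
#' @param path path to the TSV file.
#' @return a tibble with columns `gene_id`, `read_support`, `log2fc`,
#'   `padj`, `category`.
#' @export
read_de_table <- function(path, detection_threshold = 10, p_threshold = 0.05,
                          fc_threshold = 1) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    na.strings = c("NA", ""), comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "read_support", "log2fc", "padj")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("DE table '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  as_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("DE table '%s': non-numeric value '%s' in column '%s' at data row %d",
                   path, raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
    v
  }
  read_support <- as_num("read_support")
  log2fc <- as_num("log2fc")
  padj <- as_num("padj")
  tibble::tibble(
    gene_id = raw$gene_id,
    read_support = read_support,
    log2fc = log2fc,
    padj = padj,
    category = categorize_de(read_support, log2fc, padj,
                             detection_threshold, p_threshold, fc_threshold)
  )
}

#' Load the packaged gel-shift RNA probe panel
#'
#' The 17 RNA oligomer probes used in electrophoretic mobility shift assays
#' of ZFP36L2 binding, shipped as a plain-text fixture. Each probe carries
#' its ARE class (`7mer` when the sequence contains at least one UAUUUAU,
#' `5mer_only` when it contains AUUUA but no UAUUUAU), the binding outcome
#' reported for it (`bind`/`no_bind`), and whether that outcome is stated
#' for the probe in the source assay description or inferred from the
#' panel-wide statement that every single-7-mer probe formed a complex
#' (`provenance` of `stated_in_text` vs `inferred`).
#'
#' @return a tibble with columns `name`, `sequence`, `are_class`,
#'   `reported_binding`, `provenance`.
#' @seealso [classify_probe()]
#' @export
load_probe_panel <- function() {
  path <- system.file("extdata", "probe_panel.tsv", package = "aremotif", mustWork = TRUE)
  raw <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  tibble::as_tibble(raw)
}

#' Write the probe panel (or any probe table) to TSV
#'
#' @param probes a probe tibble as returned by [load_probe_panel()],
#'   optionally with extra columns (e.g. a `predicted` column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
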