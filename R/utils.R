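# Internal helpers: one RNA alphabet ({A,C,G,U}, upper case) everywhere
# downstream of ingest, and a scoped RNG so seeded operations never clobber
# the caller's random stream.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Input may be DNA or RNA, any case;
#' characters outside `A,C,G,T,U` (either case) are rejected.
#'
#' @param x character vector of sequences.
#' @param ids optional identifiers used in error messages (recycled names
#'   of `x` when `NULL`).
#' @return character vector over `{A,C,G,U}`.
#' @examples
#' normalize_rna("tatttat")
#' @export
normalize_rna <- function(x, ids = NULL) {
  stopifnot(is.character(x))
  if (is.null(ids)) ids <- if (is.null(names(x))) seq_along(x) else names(x)
  bad <- stringi::stri_locate_first_regex(x, "[^ACGTUacgtu]")[, 1L]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop(sprintf(
      "record '%s': illegal character '%s' at position %d (allowed: A,C,G,T,U any case)",
      ids[i], substr(x[i], bad[i], bad[i]), bad[i]
    ), call. = FALSE)
  }
  stringi::stri_replace_all_fixed(stringi::stri_trans_toupper(x), "T", "U")
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Single non-empty motif over the RNA alphabet, or stop.
check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif) || nchar(motif) == 0L) {
    stop("`motif` must be a single non-empty string", call. = FALSE)
  }
  normalize_rna(motif, ids = "motif")
}

is_utr_set <- function(x) {
  is.data.frame(x) && all(c("gene_id", "sequence") %in% names(x))
}

# Accept either a UTR set (tibble with gene_id/sequence) or a character
# vector of sequences (names taken as gene ids), and return a normalized
# two-column tibble.
as_sequence_set <- function(x) {
  if (is_utr_set(x)) {
    tibble::tibble(gene_id = as.character(x$gene_id), sequence = as.character(x$sequence))
  } else if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    tibble::tibble(gene_id = ids, sequence = normalize_rna(unname(x), ids = ids))
  } else {
    stop("expected a UTR set (data frame with gene_id, sequence) or a character vector",
         call. = FALSE)
  }
}
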