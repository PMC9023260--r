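# Overlapping k-mer scanning primitives. Class II AREs are blocks of
# overlapping AUUUA pentamers, so every start position counts by default;
# non-overlapping mode is exposed for comparison.

#' Locate all occurrences of a motif in a sequence
#'
#' Returns every start position at which `motif` occurs in `sequence`,
#' overlapping occurrences included, in ascending order. Coordinates are
#' 1-based and inclusive.
#'
#' @param sequence a single RNA/DNA string (normalized internally).
#' @param motif a single non-empty motif string (e.g. `"UAUUUAU"`).
#' @param overlap logical; count overlapping occurrences (default `TRUE`).
#' @return a tibble with columns `motif`, `start`, `end` (one row per hit).
#' @examples
#' find_motif("UAUUUAUUUAU", "UAUUUAU")  # hits at 1 and 5
#' @export
find_motif <- function(sequence, motif, overlap = TRUE) {
  motif <- check_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- normalize_rna(sequence, ids = "sequence")
  empty <- tibble::tibble(motif = character(), start = integer(), end = integer())
  if (nchar(sequence) < nchar(motif)) return(empty)
  loc <- stringi::stri_locate_all_fixed(sequence, motif, overlap = overlap)[[1L]]
  if (is.na(loc[1L, 1L])) return(empty)
  tibble::tibble(motif = motif, start = as.integer(loc[, 1L]), end = as.integer(loc[, 2L]))
}

#' Count motif occurrences
#'
#' Vectorized over sequences; overlapping occurrences are counted by
#' default (see [find_motif()]).
#'
#' @param sequences character vector of sequences.
#' @inheritParams find_motif
#' @return integer vector of counts.
#' @examples
#' count_motif("UUUAUUUAUUUAUUUAAGUUCAUAUUCCAU", "AUUUA")    # 3
#' count_motif("UUUAUUUAUUUAUUUAAGUUCAUAUUCCAU", "UAUUUAU")  # 2
#' @export
count_motif <- function(sequences, motif, overlap = TRUE) {
  motif <- check_motif(motif)
  stopifnot(is.character(sequences))
  sequences <- normalize_rna(sequences)
  out <- stringi::stri_count_fixed(sequences, motif, overlap = overlap)
  as.integer(out)
}

#' Per-gene census of ARE and GAAA motifs
#'
#' Counts the AUUUA pentamer, the UAUUUAU 7-mer and the GAAA motif in each
#' 3'UTR (overlapping occurrences included). With overlapping counting,
#' `n_5mer >= n_7mer` always holds: every UAUUUAU contains an AUUUA.
#'
#' @param utrs a UTR set (tibble with `gene_id`, `sequence`, as from
#'   [read_utr_fasta()] or [select_longest_utr()]) or a character vector of
#'   sequences whose names are taken as gene ids.
#' @param overlap logical; count overlapping occurrences (default `TRUE`).
#' @return a tibble with columns `gene_id`, `utr_length`, `n_5mer`,
#'   `n_7mer`, `n_GAAA`.
#' @export
motif_census <- function(utrs, overlap = TRUE) {
  s <- as_sequence_set(utrs)
  tibble::tibble(
    gene_id = s$gene_id,
    utr_length = nchar(s$sequence),
    n_5mer = count_motif(s$sequence, "AUUUA", overlap = overlap),
    n_7mer = count_motif(s$sequence, "UAUUUAU", overlap = overlap),
    n_GAAA = count_motif(s$sequence, "GAAA", overlap = overlap)
  )
}

#' Predict probe binding by the 7-mer rule
#'
#' The binding rule established by the gel-shift panel: ZFP36L2 binding
#' requires at least one UAUUUAU 7-mer; a lone AUUUA pentamer is not
#' sufficient. Predicts `"bind"` iff the sequence contains one or more
#' UAUUUAU occurrences.
#'
#' @param sequences character vector of probe sequences.
#' @return character vector over `{"bind","no_bind"}`.
#' @examples
#' classify_probe("GUGGGGUCUUGCUGUCAUCUAUUUAUUUGAUCUCUC")  # "bind"
#' @export
classify_probe <- function(sequences) {
  ifelse(count_motif(sequences, "UAUUUAU") >= 1L, "bind", "no_bind")
}

#' Delete all occurrences of a motif from a sequence
#'
#' Repeatedly removes the leftmost occurrence until none remains, so
#' occurrences re-formed by the joining flanks are deleted too; the result
#' is guaranteed motif-free and shorter by a multiple of the motif length.
#' For three non-overlapping UAUUUAU motifs (and no re-formation) the
#' length drops by exactly 21 nt, the arithmetic of an ARE-deletion
#' reporter construct.
#'
#' @param sequence a single sequence string.
#' @inheritParams find_motif
#' @return the motif-free sequence.
#' @examples
#' delete_motif("AAUAUUUAUGG", "UAUUUAU")  # "AAGG"
#' @export
delete_motif <- function(sequence, motif) {
  motif <- check_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  s <- normalize_rna(sequence, ids = "sequence")
  repeat {
    loc <- stringi::stri_locate_first_fixed(s, motif)
    if (is.na(loc[1L, 1L])) break
    s <- paste0(
      stringi::stri_sub(s, 1L, loc[1L, 1L] - 1L),
      stringi::stri_sub(s, loc[1L, 2L] + 1L)
    )
  }
  s
}

#' Extract sequence windows around motif hits
#'
#' For each occurrence of `motif`, returns the subsequence spanning
#' `flank` nt on either side of the hit, clipped to the sequence bounds.
#' The default flank of 12 nt gives 31-nt windows around a 7-mer seed,
#' matching the ~30-nt probe-sized context used for de novo motif
#' discovery around ARE seeds.
#'
#' @inheritParams find_motif
#' @param flank non-negative number of nt on each side (default 12).
#' @return a tibble with columns `hit` (index), `start`, `end` (window
#'   coordinates, 1-based inclusive) and `window` (the subsequence).
#' @export
extract_windows <- function(sequence, motif, flank = 12L) {
  stopifnot(is.numeric(flank), length(flank) == 1L, flank >= 0)
  flank <- as.integer(flank)
  hits <- find_motif(sequence, motif)
  sequence <- normalize_rna(sequence, ids = "sequence")
  n <- nchar(sequence)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(hit = integer(), start = integer(), end = integer(),
                          window = character()))
  }
  start <- pmax(1L, hits$start - flank)
  end <- pmin(n, hits$end + flank)
  tibble::tibble(
    hit = seq_len(nrow(hits)),
    start = start,
    end = end,
    window = stringi::stri_sub(sequence, start, end)
  )
}

#' Gaps between consecutive motif occurrences
#'
#' For consecutive hits i, i+1 of `motif`, the number of nt strictly
#' between the end of hit i and the start of hit i+1. Negative for
#' overlapping occurrences. A secondary ARE 7-mer observed "11 nt
#' downstream" of a seed corresponds to a gap of 11.
#'
#' @inheritParams find_motif
#' @return integer vector of gaps (empty for fewer than two hits).
#' @examples
#' intermotif_distances("UAUUUAUUUAU", "UAUUUAU")  # -3
#' @export
intermotif_distances <- function(sequence, motif) {
  hits <- find_motif(sequence, motif)
  if (nrow(hits) < 2L) return(integer())
  as.integer(hits$start[-1L] - hits$end[-nrow(hits)] - 1L)
}

#' Export motif-hit windows for a UTR set as FASTA
#'
#' Writes the [extract_windows()] result for every gene to a FASTA file
#' with headers `gene_id|hit_index`, the input format expected by external
#' de novo motif discovery tools.
#'
#' @param utrs a UTR set or named character vector (see [motif_census()]).
#' @inheritParams extract_windows
#' @param path output FASTA path.
#' @return number of windows written, invisibly.
#' @export
write_windows_fasta <- function(utrs, motif, path, flank = 12L) {
  s <- as_sequence_set(utrs)
  wins <- lapply(seq_len(nrow(s)), function(i) {
    w <- extract_windows(s$sequence[i], motif, flank = flank)
    if (nrow(w) == 0L) return(NULL)
    stats::setNames(w$window, paste(s$gene_id[i], w$hit, sep = "|"))
  })
  wins <- unlist(wins)
  if (is.null(wins)) wins <- character()
  set <- Biostrings::BStringSet(wins)
  Biostrings::writeXStringSet(set, path)
  invisible(length(wins))
}
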