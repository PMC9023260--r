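test_that("find_motif reports all overlapping hits in ascending order", {
  hits <- find_motif("UAUUUAUUUAU", "UAUUUAU")
  expect_equal(hits$start, c(1L, 5L))
  expect_equal(hits$end, c(7L, 11L))
  expect_equal(nrow(find_motif("", "AUUUA")), 0)
  expect_equal(nrow(find_motif("GGGGG", "AUUUA")), 0)
  expect_error(find_motif("ACGU", ""), "non-empty")
  # non-overlapping mode collapses overlapping runs
  expect_equal(nrow(find_motif("UAUUUAUUUAU", "UAUUUAU", overlap = FALSE)), 1)
})

test_that("motif scanning agrees with a naive character-by-character oracle", {
  set.seed(42)
  motifs <- c("AUUUA", "UAUUUAU", "GAAA", "AU", "C")
  n_cases <- 10000
  mismatches <- 0L
  for (i in seq_len(n_cases)) {
    s <- random_rna(sample(0:200, 1), au = runif(1, 0.2, 0.9))
    m <- sample(motifs, 1)
    starts <- find_motif(s, m)$start
    oracle <- naive_find_starts(s, m)
    if (!identical(starts, oracle) || count_motif(s, m) != length(oracle)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("counts reproduce the probe worked examples", {
  gmcsf <- "UUUAUUUAUUUAUUUAAGUUCAUAUUCCAU"
  expect_equal(count_motif(gmcsf, "AUUUA"), 3L)
  expect_equal(find_motif(gmcsf, "AUUUA")$start, c(4L, 8L, 12L))
  expect_equal(count_motif(gmcsf, "UAUUUAU"), 2L)
  expect_equal(count_motif("GUUAAUCUGAUUUAAAGACCCCAACAGGUAAAC", "UAUUUAU"), 0L)
})

test_that("the census keeps the pentamer/7-mer nesting invariant", {
  set.seed(7)
  seqs <- vapply(1:200, function(i) random_rna(sample(0:300, 1), au = runif(1, 0.3, 0.9)),
                 character(1))
  cen <- motif_census(stats::setNames(seqs, paste0("g", 1:200)))
  expect_true(all(cen$n_5mer >= cen$n_7mer))
  expect_true(all(cen[, c("n_5mer", "n_7mer", "n_GAAA")] >= 0))
  # worked examples
  fgf23 <- motif_census(c(Fgf23 = "GUUAAUCUGAUUUAAAGACCCCAACAGGUAAAC"))
  expect_equal(fgf23$n_5mer, 1L)
  expect_equal(fgf23$n_7mer, 0L)
  expect_equal(motif_census(c(g = "GAAAGAAA"))$n_GAAA, 2L)
  empty <- motif_census(c(g = ""))
  expect_equal(unlist(empty[, c("n_5mer", "n_7mer", "n_GAAA")], use.names = FALSE),
               c(0L, 0L, 0L))
})

test_that("delete_motif removes every occurrence, including re-formed ones", {
  expect_equal(delete_motif("AAUAUUUAUGG", "UAUUUAU"), "AAGG")
  expect_equal(delete_motif("GGCCGG", "UAUUUAU"), "GGCCGG")
  # flank joining re-creates the motif: deleting the leftmost occurrence
  # re-forms another from the joined flanks, and iteration removes it too
  s <- "UAUUAUUUAUUUAU"
  expect_equal(count_motif(s, "UAUUUAU"), 2L)
  expect_equal(delete_motif(s, "UAUUUAU"), "")
  # property: output motif-free, length drop a multiple of the motif length
  set.seed(11)
  for (i in 1:200) {
    s <- random_rna(sample(0:120, 1), au = 0.8)
    out <- delete_motif(s, "AUUUA")
    expect_equal(count_motif(out, "AUUUA"), 0L)
    expect_equal((nchar(s) - nchar(out)) %% 5, 0)
  }
})

test_that("window extraction clips to sequence bounds and sizes to ~31 nt", {
  s <- paste0(strrep("G", 12), "UAUUUAU", strrep("C", 12))  # centered 7-mer, 31 nt
  w <- extract_windows(s, "UAUUUAU")
  expect_equal(nrow(w), 1)
  expect_equal(w$window, s)
  # hit at the very start is left-clipped
  w2 <- extract_windows("UAUUUAUGGGGGGGGGGGGGGG", "UAUUUAU")
  expect_equal(w2$start, 1L)
  expect_equal(nchar(w2$window), 7 + 12)
  expect_equal(nrow(extract_windows("GGGG", "UAUUUAU")), 0)
})

test_that("inter-motif gaps match the downstream-spacing convention", {
  expect_equal(intermotif_distances("UAUUUAUUUAU", "UAUUUAU"), -3L)
  expect_equal(intermotif_distances(paste0("UAUUUAU", strrep("G", 11), "UAUUUAU"),
                                    "UAUUUAU"), 11L)
  expect_equal(intermotif_distances("UAUUUAU", "UAUUUAU"), integer())
  expect_equal(intermotif_distances("GGGG", "UAUUUAU"), integer())
})

test_that("windows export to FASTA with gene|hit headers", {
  utrs <- make_utrs(c("g1", "g2"), c("t1", "t2"),
                    c(paste0("CC", "UAUUUAU", strrep("G", 20), "UAUUUAU", "CC"), "GGGG"))
  path <- tmpfile(".fasta")
  n <- write_windows_fasta(utrs, "UAUUUAU", path)
  expect_equal(n, 2)
  set <- Biostrings::readBStringSet(path)
  expect_equal(names(set), c("g1|1", "g1|2"))
})
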