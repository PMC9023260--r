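# Independent oracles and fixture builders. These deliberately use a
# different route than the package implementation: character-by-character
# scanning instead of stringi, explicit ECDF grids instead of the packaged
# KS statistic, and choose()-enumeration instead of phyper.

# Naive overlapping motif scan: compare every window explicitly.
naive_find_starts <- function(sequence, motif) {
  n <- nchar(sequence)
  w <- nchar(motif)
  if (n < w) return(integer())
  starts <- seq_len(n - w + 1L)
  starts[substring(sequence, starts, starts + w - 1L) == motif]
}

random_rna <- function(len, au = 0.5) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
               prob = c(au / 2, (1 - au) / 2, (1 - au) / 2, au / 2)),
        collapse = "")
}

# Brute-force two-sample KS: max ECDF gap evaluated on a fine grid of all
# observed values via mean(<=).
brute_ks_D <- function(x, y) {
  v <- c(x, y)
  max(vapply(v, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# All multisets of given size over a small value alphabet.
all_multisets <- function(size, values = 1:3) {
  grid <- do.call(expand.grid, rep(list(values), size))
  unique(lapply(seq_len(nrow(grid)), function(i) sort(as.numeric(grid[i, ]))))
}

# Exact hypergeometric upper tail by direct enumeration over the support.
enum_hyper_tail <- function(k, n, m, N) {
  supp <- max(0L, n + m - N):min(n, m)
  pmf <- choose(m, supp) * choose(N - m, n - supp) / choose(N, n)
  sum(pmf[supp >= k])
}

# Small in-memory UTR set builder.
make_utrs <- function(gene_id, transcript_id, sequence) {
  tibble::tibble(gene_id = gene_id, transcript_id = transcript_id,
                 sequence = sequence, length = nchar(sequence))
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
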