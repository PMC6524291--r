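# Shared internals: seeded RNG scoping, k-mer indexing of nucleotide
# sequences, and the seed-and-extend fragment mapper used by ANI, the
# novelty screen's chromosomal comparisons, and nucleotide-mode binning.

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed deterministically from a parent seed and a tag;
# stays below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  h <- utils::head(utf8ToInt(paste0(tag)), 50)
  as.integer((as.numeric(seed) %% 1e6 * 48271 + sum(h * seq_along(h))) %% 2147483647)
}

# character vector of sequences with names preserved (as.character on a
# plain named character vector would drop them)
as_named_chr <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (is.null(names(out)) && !is.null(nm)) names(out) <- nm
  out
}

# first id of a sequence container, or a default when unnamed
id_or <- function(x, default) {
  if (is(x, "XStringSet") && !is.null(names(x))) return(seq_ids(x)[1])
  default
}

# k-mer index of a nucleotide sequence: data.table(kmer, spos) keyed by kmer
# (spos is 1-based start). N-containing k-mers are retained; they simply
# never seed (queries are N-free in practice, N never matches exactly).
nt_index <- function(seq, k = 15L) {
  s <- as.character(seq)
  n <- nchar(s)
  if (n < k) return(data.table(kmer = character(0), spos = integer(0), key = "kmer"))
  pos <- seq_len(n - k + 1L)
  dt <- data.table(kmer = substring(s, pos, pos + k - 1L), spos = pos)
  setkey(dt, kmer)
  dt
}

# Map one query fragment onto an indexed subject. Seeds exact k-mers,
# takes the modal diagonal, and scores the implied gapless placement; if
# seed support is spread across nearby diagonals (indels), falls back to a
# local affine-gap alignment of the fragment against the subject window.
# Returns list(identity = percent or NA, coverage = fraction of fragment).
map_fragment <- function(frag, index, subject_chr, k = 15L, band = 60L) {
  f <- as.character(frag)
  flen <- nchar(f)
  miss <- list(identity = NA_real_, coverage = 0)
  if (flen < k) return(miss)
  qpos <- seq_len(flen - k + 1L)
  qdt <- data.table(kmer = substring(f, qpos, qpos + k - 1L), qpos = qpos)
  hits <- index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(miss)
  offs <- hits$spos - hits$qpos
  tab <- sort(table(offs), decreasing = TRUE)
  best <- as.integer(names(tab)[1L])
  exact <- tab[[1L]]
  banded <- sum(abs(offs - best) <= band)
  slen <- nchar(subject_chr)
  if (exact >= 0.9 * banded) {
    # gapless placement at the modal diagonal
    s1 <- max(1L, best + 1L)
    s2 <- min(slen, best + flen)
    q1 <- s1 - best
    q2 <- s2 - best
    if (q2 <= q1) return(miss)
    a <- utf8ToInt(substr(f, q1, q2))
    b <- utf8ToInt(substr(subject_chr, s1, s2))
    nN <- utf8ToInt("N")
    keep <- a != nN & b != nN
    if (!sum(keep)) return(miss)
    list(identity = 100 * sum(a[keep] == b[keep]) / sum(keep),
         coverage = sum(keep) / flen)
  } else {
    w1 <- max(1L, best + 1L - band)
    w2 <- min(slen, best + flen + band)
    pa <- align_pair(DNAString(f), DNAString(substr(subject_chr, w1, w2)),
                     mode = "local", kind = "nucleotide")
    list(identity = pa$identity, coverage = pa$query_coverage)
  }
}

# Cut a sequence into consecutive non-overlapping fragments and map each
# onto the subject. Returns a data.frame with one row per fragment:
# qstart (1-based), len, identity, coverage.
map_fragments <- function(query_chr, index, subject_chr,
                          fragment_len = 1020L, k = 15L) {
  q <- as.character(query_chr)
  n <- nchar(q)
  starts <- seq(1L, n, by = fragment_len)
  lens <- pmin(fragment_len, n - starts + 1L)
  keep <- lens >= k
  starts <- starts[keep]; lens <- lens[keep]
  res <- lapply(seq_along(starts), function(i) {
    m <- map_fragment(substr(q, starts[i], starts[i] + lens[i] - 1L),
                      index, subject_chr, k = k)
    data.frame(qstart = starts[i], len = lens[i],
               identity = m$identity, coverage = m$coverage)
  })
  do.call(rbind, res)
}

# 5-mer amino-acid index over a protein set: data.table(kmer, sidx).
aa_kmer_table <- function(proteins, k = 5L) {
  res <- lapply(seq_along(proteins), function(i) {
    p <- proteins[i]
    n <- nchar(p)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    data.table(kmer = unique(substring(p, pos, pos + k - 1L)), sidx = i)
  })
  dt <- rbindlist(res)
  if (nrow(dt)) setkey(dt, kmer)
  dt
}

# Candidate subject indices sharing >= min_shared k-mers with the query.
aa_prefilter <- function(query, table, k = 5L, min_shared = 2L) {
  n <- nchar(query)
  if (n < k || !nrow(table)) return(integer(0))
  pos <- seq_len(n - k + 1L)
  qdt <- data.table(kmer = unique(substring(query, pos, pos + k - 1L)))
  hits <- table[qdt, on = "kmer", nomatch = NULL]
  if (!nrow(hits)) return(integer(0))
  cnt <- hits[, .N, by = sidx]
  cnt$sidx[cnt$N >= min_shared]
}
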