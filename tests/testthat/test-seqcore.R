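# Translation, ORF calling, and pairwise alignment primitives.

# independently coded standard/bacterial codon table (code 11 shares all
# 64 codon meanings with the standard table)
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- paste0("FFLLSSSSYY**CC*W",
               "LLLLPPPPHHQQRRRR",
               "IIIMTTTTNNKKSSRR",
               "VVVVAAAADDEEGGGG")
  codons <- as.vector(t(outer(bases, as.vector(t(outer(bases, bases,
    paste0))), paste0)))
  setNames(strsplit(aa, "")[[1]], codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  cod <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(unname(oracle_codon_table[cod]), collapse = "")
}

test_that("translation matches direct codon lookup, stops and partials", {
  expect_equal(translate_dna("ATGGCT"), "MA")
  expect_equal(translate_dna("ATGTAA"), "M*")
  expect_equal(translate_dna("ATGGCTG"), "MA")   # trailing partial ignored
  set.seed(11)
  orf <- random_dna(999)
  expect_equal(translate_dna(orf), oracle_translate(orf))
  # 1000 random codons, codon by codon
  cods <- replicate(1000, random_dna(3))
  expect_equal(vapply(cods, translate_dna, character(1), USE.NAMES = FALSE),
               unname(oracle_codon_table[cods]))
})

test_that("invalid nucleotide characters are rejected with a position", {
  expect_error(translate_dna("ATGRCT"), "position 4")
  expect_error(normalize_dna("ACGTQ"), "position 5")
  expect_equal(normalize_dna("acgu"), "ACGT")
})

test_that("implanted genes are recovered with exact coordinates", {
  set.seed(21)
  g <- simulate_genome(10000, seed = 7, id = "g1")
  calls <- find_orfs(g$seq, min_aa = 80, contig_id = "g1")
  tr <- g$truth_orfs
  big <- tr[(tr$end - tr$start) / 3 - 1 >= 80, ]
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(big) %in% key(calls)))
  # protein length invariant: (end - start)/3 - 1
  expect_equal(nchar(calls$protein), (calls$end - calls$start) / 3 - 1)
})

test_that("ORF calling degenerate inputs", {
  expect_equal(nrow(find_orfs(strrep("N", 2000))), 0L)
  expect_equal(nrow(find_orfs("ACGT")), 0L)
  expect_error(find_orfs(random_dna(1000), min_aa = 10), "min_aa")
})

test_that("ORF calls are strand-symmetric under reverse complement", {
  set.seed(31)
  g <- simulate_genome(20000, seed = 9, id = "g")
  s <- g$seq
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- find_orfs(s, min_aa = 80)
  b <- find_orfs(rc, min_aa = 80)
  n <- nchar(s)
  mirrored <- data.frame(start = n - b$end, end = n - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$start, d$end, d$strand))
  expect_equal(key(a), key(mirrored))
})

test_that("alignment identity, coverage, and error contracts", {
  set.seed(41)
  x <- random_dna(500)
  pa <- align_pair(Biostrings::DNAString(x), Biostrings::DNAString(x),
                   "global")
  expect_equal(pa$identity, 100)
  expect_equal(pa$query_coverage, 1)
  # exactly 50 substitutions in 1 kb -> 95.0 global identity
  b <- strsplit(random_dna(1000), "")[[1]]
  i <- sample(1000, 50)
  b2 <- b
  for (k in i) b2[k] <- sample(setdiff(c("A", "C", "G", "T"), b[k]), 1)
  pa <- align_pair(Biostrings::DNAString(paste(b, collapse = "")),
                   Biostrings::DNAString(paste(b2, collapse = "")), "global")
  expect_equal(pa$identity, 95.0)
  # local alignment of an exact substring: identity 100, full coverage
  src <- random_dna(10000)
  pal <- align_pair(Biostrings::DNAString(substr(src, 4001, 4200)),
                    Biostrings::DNAString(src), "local")
  expect_equal(pal$identity, 100)
  expect_equal(pal$query_coverage, 1)
  # mixed kinds rejected
  expect_error(align_pair(Biostrings::DNAString("ACGTACGT"),
                          Biostrings::AAString("MKVL"), "global"),
               "different kinds")
})

test_that("global identity is symmetric and N columns are excluded", {
  set.seed(51)
  for (r in 1:5) {
    a <- random_dna(400)
    bb <- strsplit(a, "")[[1]]
    i <- which(runif(400) < 0.1)
    for (k in i) bb[k] <- sample(setdiff(c("A", "C", "G", "T"), bb[k]), 1)
    b <- paste(bb, collapse = "")
    ab <- align_pair(Biostrings::DNAString(a), Biostrings::DNAString(b),
                     "global")$identity
    ba <- align_pair(Biostrings::DNAString(b), Biostrings::DNAString(a),
                     "global")$identity
    expect_equal(ab, ba, tolerance = 1e-12)
  }
  # a run of N matches nothing and is excluded from the denominator
  a <- paste0(strrep("A", 100), strrep("N", 20), strrep("G", 100))
  b <- paste0(strrep("A", 100), strrep("C", 20), strrep("G", 100))
  pa <- align_pair(Biostrings::DNAString(a), Biostrings::DNAString(b),
                   "global")
  expect_equal(pa$identity, 100)
})

test_that("gene calls export as 1-based inclusive GFF3 CDS features", {
  g <- simulate_genome(8000, seed = 3, id = "ctgX")
  calls <- find_orfs(g$seq, contig_id = "ctgX")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(calls, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  f <- read.delim(path, header = FALSE, comment.char = "#")
  expect_equal(f$V4, calls$start + 1L)
  expect_equal(f$V5, calls$end)
  expect_true(all(f$V3 == "CDS"))
})
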