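# Synthetic-fixture generators: determinism, composition targets, truth
# logs, and cross-module consistency.

test_that("genome simulation is seed-deterministic and hits the GC target", {
  g1 <- simulate_genome(100000, gc = 0.6, seed = 801, id = "g")
  g2 <- simulate_genome(100000, gc = 0.6, seed = 801, id = "g")
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$truth_orfs, g2$truth_orfs)
  gc_obs <- sum(strsplit(g1$seq, "")[[1]] %in% c("G", "C")) / 100000
  expect_equal(gc_obs, 0.6, tolerance = 0.005)
  # ORFs cover at least 60% of the genome
  cov <- sum(g1$truth_orfs$end - g1$truth_orfs$start) / 100000
  expect_gte(cov, 0.6)
  expect_error(simulate_genome(100000, gc = 0.9), "gc")
})

test_that("truth ORFs are rediscovered by the ORF caller", {
  g <- simulate_genome(50000, seed = 802, id = "g")
  calls <- find_orfs(g$seq, min_aa = 80)
  tr <- g$truth_orfs
  big <- tr[(tr$end - tr$start) / 3 - 1 >= 80, ]
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(big) %in% key(calls)))
})

test_that("mutation realizes the requested substitution rate", {
  g <- simulate_genome(100000, seed = 803, id = "g")
  m0 <- mutate_genome(g, 0, seed = 804)
  expect_identical(m0$seq, g$seq)
  m <- mutate_genome(g, 0.05, seed = 805)
  n <- 100000
  expect_equal(m$n_substitutions, 0.05 * n,
               tolerance = 3 * sqrt(0.05 * 0.95 * n) / (0.05 * n))
  # realized identity equals 1 - rate
  same <- mapply(identical, strsplit(g$seq, "")[[1]],
                 strsplit(m$seq, "")[[1]])
  expect_equal(sum(!same), m$n_substitutions)
})

test_that("ORF-preserving mutation keeps every truth gene callable", {
  g <- simulate_genome(40000, seed = 806, id = "g")
  m <- mutate_genome(g, 0.10, seed = 807, preserve_orfs = TRUE)
  calls <- find_orfs(m$seq, min_aa = 80)
  tr <- m$truth_orfs
  big <- tr[(tr$end - tr$start) / 3 - 1 >= 80, ]
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(big) %in% key(calls)))
  expect_error(mutate_genome(random_dna(5000), 0.1, preserve_orfs = TRUE),
               "truth log")
})

test_that("indel mutation drops the stale truth log", {
  g <- simulate_genome(30000, seed = 808, id = "g")
  m <- mutate_genome(g, 0.01, seed = 809, indel_rate = 0.001)
  expect_null(m$truth_orfs)
  expect_false(identical(nchar(m$seq), nchar(g$seq)))
})

test_that("reverse translation round-trips through translation", {
  set.seed(810)
  p <- random_protein(120)
  cds <- reverse_translate(p, seed = 811)
  expect_equal(translate_dna(cds), paste0(p, "*"))
  expect_identical(reverse_translate(p, seed = 811),
                   reverse_translate(p, seed = 811))
})

test_that("implants land outside truth ORFs and shift coordinates", {
  set.seed(812)
  g <- simulate_genome(20000, seed = 813, id = "g")
  pro <- c(impA = random_protein(150), impB = random_protein(200))
  gi <- implant_genes(g, pro, seed = 814)
  expect_equal(nrow(gi$truth_implants), 2L)
  expect_gt(nchar(gi$seq), nchar(g$seq))
  # implanted CDS is recovered verbatim at the logged coordinates
  for (r in seq_len(2)) {
    cds <- substr(gi$seq, gi$truth_implants$start[r] + 1,
                  gi$truth_implants$end[r])
    expect_equal(translate_dna(cds), paste0(pro[[r]], "*"))
  }
  # shifted truth ORFs still translate cleanly (no stop disruption)
  calls <- find_orfs(gi$seq, min_aa = 80)
  tr <- gi$truth_orfs
  big <- tr[(tr$end - tr$start) / 3 - 1 >= 80, ]
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(big) %in% key(calls)))
  expect_error(implant_genes(g, unname(pro)), "named")
})

test_that("fragmentation conserves bp and approximates the target N50", {
  g <- simulate_genome(200000, seed = 815, id = "g")
  fr <- fragment_contigs(g, n50 = 8000, seed = 816)
  expect_equal(sum(Biostrings::width(fr$contigs)), 200000)
  expect_lte(abs(fr$n50 - 8000), 0.2 * 8000)
  # provenance: contigs reassemble the genome in src order
  tr <- fr$truth
  expect_equal(tr$src_start[1], 0)
  expect_equal(tr$src_end[nrow(tr)], 200000)
  joined <- paste(as.character(fr$contigs), collapse = "")
  expect_identical(joined, g$seq)
  expect_identical(fragment_contigs(g, 8000, seed = 816)$truth, fr$truth)
})

test_that("spike-in series realizes decreasing bp fractions", {
  g <- simulate_genome(400000, seed = 817, id = "bg")
  bg <- fragment_contigs(g, n50 = 6000, seed = 818)$contigs
  t_g <- simulate_genome(60000, seed = 819, id = "target")
  sets <- spike_in_titration(bg, t_g, fractions = c(0.1, 0.01, 0.001),
                             seed = 820)
  real <- vapply(sets, `[[`, numeric(1), "realized")
  expect_true(all(diff(real) < 0))
  expect_equal(real[1], 0.1, tolerance = 0.02)
  expect_equal(real[3], 0.001, tolerance = 0.01)   # bp-rounding granularity
  # spike contigs are labeled and present
  expect_true(all(vapply(sets, function(s)
    all(s$spike_ids %in% seq_ids(s$contigs)), logical(1))))
})

test_that("community simulation respects abundances and truth labels", {
  fx <- test_panel()
  members <- data.frame(id = c("m1", "m2"), abundance = c(0.7, 0.3),
                        source = c("bifA", "lacD"),
                        is_novel = c(FALSE, FALSE))
  comm <- simulate_community(members,
                             list(bifA = fx$genomes$bifA,
                                  lacD = fx$genomes$lacD),
                             total_bp = 8e4, n50 = 6000, seed = 821)
  bp <- tapply(Biostrings::width(comm$contigs),
               comm$truth$member[match(seq_ids(comm$contigs),
                                       comm$truth$contig_id)], sum)
  expect_equal(unname(bp["m1"] / sum(bp)), 0.7, tolerance = 0.05)
  comm2 <- simulate_community(members,
                              list(bifA = fx$genomes$bifA,
                                   lacD = fx$genomes$lacD),
                              total_bp = 8e4, n50 = 6000, seed = 821)
  expect_identical(as.character(comm$contigs), as.character(comm2$contigs))
})
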