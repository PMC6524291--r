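# Novelty screen: per-contig verdicts and sample aggregation.

test_that("verbatim panel contigs are known_species with the right match", {
  fx <- test_panel()
  v <- screen_contig(substr(fx$genomes$bifA$seq, 10001, 18000), fx$panel,
                     contig_id = "k1")
  expect_equal(v$status, "known_species")
  expect_equal(v$matched_species, "bif_alpha")
})

test_that("the length filter is strictly greater-than 5000 bp", {
  fx <- test_panel()
  v1 <- screen_contig(substr(fx$genomes$bifA$seq, 1, 4999), fx$panel)
  v2 <- screen_contig(substr(fx$genomes$bifA$seq, 1, 5000), fx$panel)
  v3 <- screen_contig(substr(fx$genomes$bifA$seq, 1, 5001), fx$panel)
  expect_equal(v1$status, "too_short")
  expect_equal(v2$status, "too_short")
  expect_equal(v3$status, "known_species")
})

test_that("contigs at 12% divergence from the panel are novel candidates", {
  fx <- test_panel()
  nov <- mutate_genome(fx$genomes$bifA, 0.12, seed = 301)
  v <- screen_contig(substr(nov$seq, 20001, 28000), fx$panel,
                     contig_id = "n1")
  expect_equal(v$status, "novel_candidate")
  # the nucleotide evidence cannot reach the 95% known threshold at 12%
  expect_lt(v$evidence$nt_best_cov, 0.75)
  expect_lt(v$evidence$prot_mean_identity, 96)
})

test_that("mobile-marker dominated contigs are flagged mobile_element", {
  fx <- test_panel()
  mob <- fx$panel$mobile_markers
  host <- simulate_genome(6000, seed = 303, id = "mob1")
  pro <- setNames(as.character(mob[1:6]), seq_ids(mob)[1:6])
  hostI <- implant_genes(host, pro, seed = 304)
  v <- screen_contig(hostI$seq, fx$panel, contig_id = "mob1")
  expect_equal(v$status, "mobile_element")
  expect_gte(v$evidence$mobile_fraction, 0.5)
})

test_that("lowering the nt identity threshold only moves novel -> known", {
  fx <- test_panel()
  nov <- mutate_genome(fx$genomes$bifB, 0.08, seed = 305)
  slices <- list(substr(nov$seq, 1, 8000), substr(nov$seq, 9001, 17000))
  strict <- vapply(slices, function(s)
    screen_contig(s, fx$panel, screen_thresholds())$status, character(1))
  loose <- vapply(slices, function(s)
    screen_contig(s, fx$panel,
                  screen_thresholds(nt_known_identity = 85))$status,
    character(1))
  # anything known under the strict threshold stays known under the loose
  expect_true(all(loose[strict == "known_species"] == "known_species"))
  # at 8% divergence the strict screen calls novel, the loose calls known
  expect_true(all(strict == "novel_candidate"))
  expect_true(all(loose == "known_species"))
})

test_that("screening a panel genome's own contigs yields no novel bp", {
  fx <- test_panel()
  frag <- fragment_contigs(fx$genomes$bifC, n50 = 9000, seed = 306)
  keep <- Biostrings::width(frag$contigs) > 5000
  rep <- screen_sample(frag$contigs[keep][1:4], fx$panel)
  expect_equal(rep$summary$bp[rep$summary$status == "novel_candidate"], 0)
})

test_that("sample aggregation recovers truth counts and writes artifacts", {
  fx <- test_panel()
  kn <- mutate_genome(fx$genomes$bifA, 0.02, seed = 307)
  nov <- mutate_genome(fx$genomes$bifB, 0.12, seed = 308)
  ctgs <- Biostrings::DNAStringSet(c(
    k1 = substr(kn$seq, 1, 8000), k2 = substr(kn$seq, 9001, 16000),
    n1 = substr(nov$seq, 1, 8000),
    s1 = substr(kn$seq, 40001, 44000)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  rep <- screen_sample(ctgs, fx$panel, novel_fasta = fa)
  write_screen_report(rep, tsv = tsv, json = json)
  s <- rep$summary
  expect_equal(s$n[s$status == "known_species"], 2L)
  expect_equal(s$n[s$status == "novel_candidate"], 1L)
  expect_equal(s$n[s$status == "too_short"], 1L)
  novel <- read_fasta(fa, "nucleotide")
  expect_equal(seq_ids(novel), "n1")
  expect_match(readLines(tsv, n = 1), "nt_known_identity=95")
  j <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(j$thresholds$min_len, 5000)
})

test_that("novel bp fraction is non-decreasing in divergence", {
  fx <- test_panel()
  fracs <- vapply(c(0.02, 0.08, 0.20), function(d) {
    g <- mutate_genome(fx$genomes$bifA, d, seed = 310 + round(100 * d))
    ctgs <- Biostrings::DNAStringSet(c(a = substr(g$seq, 1, 8000),
                                       b = substr(g$seq, 20001, 28000)))
    rep <- screen_sample(ctgs, fx$panel)
    s <- rep$summary
    s$bp[s$status == "novel_candidate"] / sum(s$bp)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})
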