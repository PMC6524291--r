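# Ortholog clustering, core-genome extraction, and core distances.

make_clade_proteomes <- function(n_genomes = 3, n_core = 10, n_acc = 5,
                                 within = 0.05) {
  fam <- vapply(seq_len(n_core), function(i)
    random_protein(sample(200:350, 1)), character(1))
  out <- lapply(seq_len(n_genomes), function(g) {
    core <- vapply(fam, mutate_protein, character(1), rate = within)
    acc <- vapply(seq_len(n_acc), function(i) random_protein(250),
                  character(1))
    s <- c(core, acc)
    names(s) <- sprintf("g%d_p%02d", g, seq_along(s))
    s
  })
  names(out) <- paste0("gen", seq_len(n_genomes))
  out
}

test_that("shared gene families yield exactly the expected core clusters", {
  set.seed(501)
  pro <- make_clade_proteomes()
  cl <- cluster_orthologs(pro)
  cc <- core_single_copy(cl)
  expect_equal(cc$n_core, 10L)
  expect_equal(cc$n_single_copy, 10L)
  expect_equal(cc$n_paralogous_core, 0L)
  # the partition covers every input gene exactly once
  expect_equal(nrow(cl$membership), sum(lengths(pro)))
  expect_equal(anyDuplicated(paste(cl$membership$genome_id,
                                   cl$membership$gene_id)), 0L)
})

test_that("a duplicated core gene makes its cluster core but not single-copy", {
  set.seed(502)
  pro <- make_clade_proteomes()
  dup <- mutate_protein(pro$gen1[["g1_p01"]], 0.05)
  pro$gen1 <- c(pro$gen1, g1_dup = dup)
  cc <- core_single_copy(cluster_orthologs(pro))
  expect_equal(cc$n_core, 10L)
  expect_equal(cc$n_single_copy, 9L)
  expect_equal(cc$n_paralogous_core, 1L)
})

test_that("unrelated proteomes form no multi-genome clusters", {
  set.seed(503)
  pro <- list(a = setNames(vapply(1:6, function(i) random_protein(200),
                                  character(1)), paste0("a", 1:6)),
              b = setNames(vapply(1:6, function(i) random_protein(200),
                                  character(1)), paste0("b", 1:6)))
  cl <- cluster_orthologs(pro)
  m <- as.data.frame(table(cl$membership$cluster_id))
  expect_true(all(m$Freq == 1))
  expect_warning(core_single_copy(cl), "empty core")
})

test_that("a genome with zero proteins is a hard error", {
  set.seed(504)
  pro <- make_clade_proteomes(2)
  pro$gen2 <- character(0)
  expect_error(cluster_orthologs(pro), "zero proteins")
})

test_that("core distances are length-weighted mean p-distances", {
  set.seed(505)
  pro <- make_clade_proteomes(3, n_core = 4, n_acc = 0, within = 0.02)
  cl <- cluster_orthologs(pro)
  pd <- core_gene_pdistances(cl, pro)
  D <- core_distances(pd)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # identical proteomes give a zero matrix
  same <- list(x = pro$gen1, y = pro$gen1, z = pro$gen1)
  Dz <- core_distances(core_gene_pdistances(cluster_orthologs(same), same))
  expect_equal(max(Dz), 0)
  # single-gene core: D equals that gene's p-distance matrix exactly
  one <- core_gene_pdistances(cl, pro, single_copy = pd$genes[1])
  expect_equal(core_distances(one), one$p[, , 1])
})

test_that("divergence scales recovered p-distances", {
  set.seed(506)
  fam <- vapply(1:8, function(i) random_protein(300), character(1))
  pro <- list(
    t1 = setNames(fam, paste0("x", 1:8)),
    t2 = setNames(vapply(fam, mutate_protein, character(1), rate = 0.02),
                  paste0("y", 1:8)),
    t3 = setNames(vapply(fam, mutate_protein, character(1), rate = 0.10),
                  paste0("z", 1:8)))
  D <- core_distances(core_gene_pdistances(cluster_orthologs(pro), pro))
  # count-based oracle: length-weighted Hamming fraction over the fixture
  hamming_p <- function(x, y) {
    a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
    sum(a != b) / length(a)
  }
  oracle <- function(p1, p2) {
    w <- nchar(p1)
    sum(w * mapply(hamming_p, p1, p2)) / sum(w)
  }
  expect_equal(D["t1", "t2"], oracle(pro$t1, pro$t2), tolerance = 1e-3)
  expect_equal(D["t1", "t3"], oracle(pro$t1, pro$t3), tolerance = 1e-3)
  # and the realized distances sit near the nominal rates
  expect_lt(abs(D["t1", "t2"] - 0.02 * 19 / 20), 0.005)
  expect_lt(abs(D["t1", "t3"] - 0.10 * 19 / 20), 0.012)
})
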