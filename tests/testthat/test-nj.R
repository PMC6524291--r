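# Neighbor joining, rooting, bipartitions, and bootstrap supports.

test_that("three taxa use the closed-form three-point lengths", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(D)
  pl <- ape::cophenetic.phylo(phy)[rownames(D), colnames(D)]
  expect_equal(pl, D, tolerance = 1e-12)
})

test_that("degenerate distance matrices are hard errors", {
  D <- matrix(c(0, 1, 2, 1, 0, NA, 2, NA, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D), "NA")
  D2 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D2), "symmetric")
  D3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3, outgroup = "zz"), "outgroup")
})

test_that("NJ agrees with an independent implementation on noisy data", {
  set.seed(601)
  fx <- random_additive_matrix(8)
  D <- fx$D + matrix(runif(64, 0, 0.002), 8, 8)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  mine <- nj_tree(D)
  ref <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("outgroup rooting yields a rooted binary tree", {
  set.seed(602)
  fx <- random_additive_matrix(7)
  og <- rownames(fx$D)[1]
  phy <- nj_tree(fx$D, outgroup = og)
  expect_true(ape::is.rooted(phy))
  expect_true(ape::is.binary(phy))
  expect_setequal(phy$tip.label, rownames(fx$D))
})

test_that("bootstrap supports separate two well-diverged clades", {
  set.seed(603)
  fam <- vapply(1:50, function(i) random_protein(sample(150:300, 1)),
                character(1))
  ancA <- vapply(fam, mutate_protein, character(1), rate = 0.025)
  ancB <- vapply(fam, mutate_protein, character(1), rate = 0.025)
  tip <- function(anc) {
    s <- vapply(anc, mutate_protein, character(1), rate = 0.005)
    names(s) <- sprintf("g%02d", seq_along(s))
    s
  }
  pro <- list(a1 = tip(ancA), a2 = tip(ancA), a3 = tip(ancA),
              b1 = tip(ancB), b2 = tip(ancB), b3 = tip(ancB))
  pd <- core_gene_pdistances(cluster_orthologs(pro), pro)
  bs <- bootstrap_supports(pd, n_reps = 100, seed = 604, outgroup = "b3")
  # the clade-separating bipartition {a1,a2,a3} | {b1,b2,b3}
  key <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_true(key %in% names(bs$supports))
  expect_gte(bs$supports[[key]], 95)
  # same seed twice: identical supports
  bs2 <- bootstrap_supports(pd, n_reps = 100, seed = 604, outgroup = "b3")
  expect_identical(bs$supports, bs2$supports)
  expect_identical(ape::write.tree(bs$tree), ape::write.tree(bs2$tree))
  # n_reps = 0: tree without supports, with a warning
  expect_warning(b0 <- bootstrap_supports(pd, n_reps = 0, seed = 1),
                 "n_reps")
  expect_length(b0$supports, 0)
})

test_that("bipartition supports are invariant to taxon input order", {
  set.seed(605)
  fam <- vapply(1:20, function(i) random_protein(200), character(1))
  mk <- function(r) {
    s <- vapply(fam, mutate_protein, character(1), rate = r)
    names(s) <- sprintf("g%02d", seq_along(s))
    s
  }
  pro <- list(t1 = mk(0.01), t2 = mk(0.02), t3 = mk(0.08), t4 = mk(0.09))
  sup1 <- bootstrap_supports(core_gene_pdistances(cluster_orthologs(pro),
                                                  pro),
                             n_reps = 50, seed = 606)$supports
  pro_r <- rev(pro)
  sup2 <- bootstrap_supports(core_gene_pdistances(cluster_orthologs(pro_r),
                                                  pro_r),
                             n_reps = 50, seed = 606)$supports
  expect_setequal(names(sup1), names(sup2))
})

test_that("Newick output carries supports as internal node labels", {
  set.seed(607)
  fx <- random_additive_matrix(6)
  phy <- nj_tree(fx$D, outgroup = rownames(fx$D)[1])
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(phy, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(fx$D))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(fx$D, path2)
  expect_equal(readLines(path2, n = 1), "6")
})
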