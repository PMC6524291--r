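# GH family assignment, glycobiome profiles, and substrate rules.

test_that("GH references assign to themselves at identity 100", {
  gh <- gh_refs()
  asn <- assign_gh(gh[5], gh)
  expect_equal(nrow(asn), 1L)
  expect_equal(asn$identity, 100)
  meta_fam <- sub("_.*$", "", seq_ids(gh)[5])
  expect_equal(asn$gh_family, meta_fam)
})

test_that("implanted GH genes are recovered with correct families", {
  set.seed(111)
  gh <- gh_refs()
  ids <- seq_ids(gh)
  want <- c(grep("^GH13", ids, value = TRUE),        # pullulanase + amylase
            grep("^GH43", ids, value = TRUE),        # 2 exemplars
            grep("^GH10", ids, value = TRUE)[1],
            grep("^GH53", ids, value = TRUE)[1])
  pro <- setNames(as.character(gh)[match(want, ids)], want)
  host <- simulate_genome(20000, seed = 112, id = "dark")
  hostI <- implant_genes(host, pro, seed = 113)
  calls <- find_orfs(hostI$seq, contig_id = "dark", nonoverlapping = TRUE)
  prot <- setNames(calls$protein, sprintf("g%03d", seq_len(nrow(calls))))
  asn <- assign_gh(prot, gh)
  expect_equal(nrow(asn), 6L)
  expect_equal(sort(table(asn$gh_family)),
               sort(table(sub("_.*$", "", want))))
  # background ORFs with no GH homology get no assignment
  bg <- find_orfs(host$seq, contig_id = "bg", nonoverlapping = TRUE)
  expect_equal(nrow(assign_gh(setNames(bg$protein,
                                       paste0("b", seq_len(nrow(bg)))), gh)),
               0L)
})

test_that("profiles normalize to 1 and empty profiles carry a notice", {
  asn <- data.frame(gene_id = c("a", "b", "c"),
                    gh_family = c("GH13", "GH13", "GH53"),
                    subfamily_label = c("pullulanase", "amylase",
                                        "galactanase"),
                    identity = 100, coverage = 1)
  prof <- glycobiome_profile(asn)
  expect_equal(sum(prof$rel_abund), 1, tolerance = 1e-9)
  expect_equal(unname(prof$rel_abund["GH13"]), 2 / 3)
  empty <- glycobiome_profile(asn[0, ])
  rec <- recommend_substrates(empty)
  expect_equal(rec$notice, "no GH evidence")
  expect_equal(nrow(rec$ranking), 0L)
})

test_that("the default rule map realizes the four-glycan logic", {
  mk_prof <- function(fams, labs) {
    glycobiome_profile(data.frame(
      gene_id = paste0("g", seq_along(fams)), gh_family = fams,
      subfamily_label = labs, identity = 100, coverage = 1))
  }
  # pullulanase-only dark matter -> pullulan alone
  rec <- recommend_substrates(mk_prof("GH13", "pullulanase"))
  expect_equal(rec$ranking$substrate, "pullulan")
  # endo-xylanase without beta-xylosidase does not fire the xylan rule
  rec <- recommend_substrates(mk_prof("GH10", "xylanase"))
  expect_equal(nrow(rec$ranking), 0L)
  rec <- recommend_substrates(mk_prof(c("GH11", "GH3"),
                                      c("xylanase", "beta-xylosidase")))
  expect_equal(rec$ranking$substrate, "xylan")
  # families matching no rule recommend nothing
  rec <- recommend_substrates(mk_prof("GH99", "unknown"))
  expect_equal(nrow(rec$ranking), 0L)
  # all four substrates from a full repertoire, each with supporting genes
  rec <- recommend_substrates(mk_prof(
    c("GH13", "GH13", "GH10", "GH43", "GH53"),
    c("pullulanase", "amylase", "xylanase", "beta-xylosidase",
      "galactanase")))
  expect_setequal(rec$ranking$substrate,
                  c("pullulan", "starch", "xylan", "arabinogalactan"))
  expect_true(all(nzchar(rec$ranking$genes)))
})

test_that("recommendations are scale-invariant in gene counts", {
  asn <- data.frame(gene_id = paste0("g", 1:4),
                    gh_family = c("GH13", "GH10", "GH43", "GH53"),
                    subfamily_label = c("pullulanase", "xylanase",
                                        "beta-xylosidase", "galactanase"),
                    identity = 100, coverage = 1)
  r1 <- recommend_substrates(glycobiome_profile(asn))
  asn3 <- do.call(rbind, replicate(3, asn, simplify = FALSE))
  asn3$gene_id <- paste0("g", seq_len(nrow(asn3)))
  r3 <- recommend_substrates(glycobiome_profile(asn3))
  expect_equal(r1$ranking$substrate, r3$ranking$substrate)
  expect_equal(r1$ranking$score, r3$ranking$score, tolerance = 1e-12)
})

test_that("substrate maps round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(default_substrate_map(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- read_substrate_map(path)
  expect_equal(m$substrate, default_substrate_map()$substrate)
})
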