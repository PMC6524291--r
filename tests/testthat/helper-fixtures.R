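# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code under fixed seeds; no data files are read.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) assign(key, builder(), envir = .fx)
  .fx[[key]]
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste0("M", paste(sample(AA20, n - 1, replace = TRUE), collapse = ""))
}

mutate_protein <- function(p, rate) {
  a <- strsplit(p, "")[[1]]
  i <- which(runif(length(a)) < rate)
  i <- i[i > 1]                      # keep the initiator M
  if (length(i)) a[i] <- sample(AA20, length(i), replace = TRUE)
  paste(a, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small two-genus reference panel: three Bifidobacterium-like genomes
# derived from one ancestor (ORF-preserving divergence) plus one unrelated
# Lactobacillus-like genome
test_panel <- function() {
  memo("panel", function() {
    anc <- simulate_genome(60000, seed = 100, id = "anc")
    bifA <- mutate_genome(anc, 0.05, seed = 101, preserve_orfs = TRUE)
    bifA$id <- "bifA"
    bifB <- mutate_genome(anc, 0.10, seed = 102, preserve_orfs = TRUE)
    bifB$id <- "bifB"
    bifC <- mutate_genome(anc, 0.16, seed = 103, preserve_orfs = TRUE)
    bifC$id <- "bifC"
    lacD <- simulate_genome(60000, seed = 104, id = "lacD")
    meta <- data.frame(
      genome_id = c("bifA", "bifB", "bifC", "lacD"),
      genus = c("Bifidobacterium", "Bifidobacterium", "Bifidobacterium",
                "Lactobacillus"),
      species = c("bif_alpha", "bif_beta", "bif_gamma", "lac_delta"),
      strain = c("A1", "B1", "C1", "D1"), stringsAsFactors = FALSE)
    list(panel = build_panel(list(bifA = bifA, bifB = bifB, bifC = bifC,
                                  lacD = lacD), meta),
         genomes = list(anc = anc, bifA = bifA, bifB = bifB, bifC = bifC,
                        lacD = lacD),
         meta = meta)
  })
}

# GH exemplar proteins shipped with the package, keyed by id
gh_refs <- function() {
  memo("gh", function() {
    p <- system.file("extdata", "gh_reference_synthetic.faa",
                     package = "metadark")
    Biostrings::readAAStringSet(p)
  })
}

gh_implant_set <- function() {
  gh <- gh_refs()
  ids <- seq_ids(gh)
  want <- c(grep("^GH13_pullulanase", ids, value = TRUE)[1],
            grep("^GH13_amylase", ids, value = TRUE)[1],
            grep("^GH10_xylanase", ids, value = TRUE)[1],
            grep("^GH43_beta-xylosidase", ids, value = TRUE)[1],
            grep("^GH53_galactanase", ids, value = TRUE)[1])
  setNames(as.character(gh)[match(want, ids)], want)
}

make_its_refs <- function(n = 8, len = 300) {
  seqs <- vapply(seq_len(n), function(i) random_dna(len), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("its_%02d species=Species_%02d", seq_len(n),
                      seq_len(n))
  x
}

mutate_dna <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  i <- which(runif(length(b)) < rate)
  for (k in i) b[k] <- sample(setdiff(c("A", "C", "G", "T"), b[k]), 1)
  paste(b, collapse = "")
}

# a mobile-element cassette contig: reverse-translated marker genes joined
# by short random spacers (gene content is entirely mobile markers)
mobile_cassette <- function(markers, seed) {
  set.seed(seed)
  parts <- character(0)
  for (j in seq_along(markers)) {
    parts <- c(parts, random_dna(sample(150:350, 1)), "TAA",
               reverse_translate(as.character(markers[[j]]),
                                 seed = seed + j))
  }
  paste(c(parts, random_dna(200)), collapse = "")
}

# independent least-squares oracle over all 15 unrooted 5-taxon topologies:
# fits OLS branch lengths per topology from edge-crossing indicators and
# returns the minimum-SSE tree
ls_best_5taxon <- function(D) {
  taxa <- rownames(D)
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  pair_idx <- t(utils::combn(5, 2))
  d <- D[pair_idx]
  best <- NULL
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]        # [[ reattaches tip labels on a multiPhylo
    sets <- edge_tip_sets(tr)
    X <- sapply(seq_along(sets), function(e)
      as.integer(xor(taxa[pair_idx[, 1]] %in% sets[[e]],
                     taxa[pair_idx[, 2]] %in% sets[[e]])))
    fit <- stats::lm.fit(X, d)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse) best <- list(tree = tr, sse = sse)
  }
  best$tree
}

# tip labels below each edge of a phylo (oracle-local reimplementation)
edge_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po)))
    sets[[po[r, 1]]] <- c(sets[[po[r, 1]]], sets[[po[r, 2]]])
  lapply(seq_len(nrow(phy$edge)), function(r) sets[[phy$edge[r, 2]]])
}

# random unrooted tree with positive branch lengths and its additive
# distance matrix, taxa in sorted label order
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}
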