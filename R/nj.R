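# Neighbor joining (canonical Saitou-Nei agglomeration) on core-genome
# distances, deterministic tie-breaking, outgroup rooting, and gene-
# resampling bootstrap supports on internal edges.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined, ties broken by the smallest pair of taxon
#' indices in the current ordering. The final unrooted tree is rooted on
#' the outgroup branch. Negative branch lengths arising from
#' non-additivity are clamped to zero with the deficit moved to the
#' sibling branch, preserving path lengths.
#'
#' NJ is exact on additive matrices: it recovers the generating topology
#' and branch lengths.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param taxa Taxon labels (default `rownames(D)`).
#' @param outgroup Optional taxon to root on; when NULL an unrooted tree
#'   (basal trifurcation) is returned.
#' @return An [ape] `phylo` object.
#' @export
nj_tree <- function(D, taxa = rownames(D), outgroup = NULL) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(is.nan(D)))
    stop("distance matrix contains NA/NaN", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(D)
  stopifnot(n >= 3)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  stopifnot(length(taxa) == n)
  if (!is.null(outgroup) && !outgroup %in% taxa)
    stop("outgroup '", outgroup, "' not among taxa", call. = FALSE)

  # nodes: recursive lists; leaves carry $tip
  nodes <- lapply(taxa, function(t) list(tip = t))
  act <- seq_len(n)          # active node ids into `nodes`
  M <- D
  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(M)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * M[i, j] - r[i] - r[j]
      if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
    }
    i <- best$i; j <- best$j
    li <- M[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- M[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newd <- (M[i, -c(i, j)] + M[j, -c(i, j)] - M[i, j]) / 2
    nodes[[length(nodes) + 1L]] <- list(
      children = list(nodes[[act[i]]], nodes[[act[j]]]),
      blens = c(li, lj))
    keep <- setdiff(seq_len(m), c(i, j))
    M2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      M2[seq_along(keep), seq_along(keep)] <- M[keep, keep, drop = FALSE]
      M2[m - 1, seq_along(keep)] <- M2[seq_along(keep), m - 1] <- newd
    }
    M <- M2
    act <- c(act[keep], length(nodes))
  }
  # final 3-star: closed-form three-point lengths
  d12 <- M[1, 2]; d13 <- M[1, 3]; d23 <- M[2, 3]
  l <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
         (d13 + d23 - d12) / 2)
  l[l < 0] <- 0
  root <- list(children = lapply(act, function(a) nodes[[a]]), blens = l)

  phy <- .to_phylo(root, taxa)
  if (!is.null(outgroup))
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  phy
}

# convert the recursive node structure into an ape phylo object
.to_phylo <- function(root, taxa) {
  ntip <- length(taxa)
  edges <- list()
  lens <- numeric(0)
  n_internal <- 0L
  count_internal <- function(nd) {
    if (!is.null(nd$tip)) return(invisible())
    n_internal <<- n_internal + 1L
    for (ch in nd$children) count_internal(ch)
  }
  count_internal(root)
  next_internal <- ntip
  assign_edges <- function(nd) {
    if (!is.null(nd$tip)) return(match(nd$tip, taxa))
    next_internal <<- next_internal + 1L
    me <- next_internal
    for (k in seq_along(nd$children)) {
      child_id <- assign_edges(nd$children[[k]])
      edges[[length(edges) + 1L]] <<- c(me, child_id)
      lens[length(lens) + 1L] <<- nd$blens[k]
    }
    me
  }
  assign_edges(root)
  phy <- structure(list(edge = do.call(rbind, edges),
                        edge.length = lens,
                        tip.label = taxa,
                        Nnode = n_internal),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# non-trivial bipartitions of a tree as canonical keys: for each internal
# edge, the tip set on the side NOT containing the alphabetically first
# taxon, sorted and collapsed. Invariant to taxon input order and rooting.
tree_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  tips <- phy$tip.label
  anchor <- sort(tips)[1]
  ntip <- length(tips)
  desc <- .edge_tipsets(phy)
  keys <- character(0)
  for (k in seq_along(desc)) {
    side <- desc[[k]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# tip label sets below each edge (list parallel to phy$edge rows)
.edge_tipsets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  # postorder accumulation
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    par <- po[r, 1]; ch <- po[r, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(r) sets[[phy$edge[r, 2]]])
}

#' Gene-resampling bootstrap supports for the core-genome NJ tree
#'
#' Core genes are resampled with replacement; for each replicate the
#' length-weighted distance matrix and NJ tree are recomputed, and the
#' support of an internal edge of the full-data tree is the percentage of
#' replicates whose tree contains the same bipartition. Supports are
#' attached as internal node labels (ape convention); the run is
#' reproducible under a fixed seed.
#'
#' @param pd A `core_pdistances` object (see [core_gene_pdistances()]).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param outgroup Taxon to root the reported tree on.
#' @return List of class `nj_bootstrap`: `tree` (rooted phylo with
#'   node.label supports), `supports` (named numeric by bipartition key),
#'   `n_reps`.
#' @export
bootstrap_supports <- function(pd, n_reps = 1000L, seed = 1L,
                               outgroup = NULL) {
  stopifnot(inherits(pd, "core_pdistances"))
  D0 <- core_distances(pd)
  tree <- nj_tree(D0, taxa = pd$taxa, outgroup = outgroup)
  ng <- length(pd$genes)
  if (ng < 2 || n_reps == 0) {
    warning(if (ng < 2) "fewer than 2 core genes: supports undefined"
            else "n_reps = 0: tree reported without supports",
            call. = FALSE)
    return(structure(list(tree = tree, supports = numeric(0),
                          n_reps = 0L), class = "nj_bootstrap"))
  }
  keys <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(ng, ng, replace = TRUE)
      Db <- core_distances(pd, gene_idx = idx)
      tb <- nj_tree(Db, taxa = pd$taxa)
      kb <- tree_bipartitions(tb)
      hit <- keys %in% kb
      hits[hit] <- hits[hit] + 1
    }
  })
  supports <- 100 * hits / n_reps
  tree <- .label_supports(tree, supports)
  structure(list(tree = tree, supports = supports,
                 n_reps = as.integer(n_reps)),
            class = "nj_bootstrap")
}

# write bipartition supports onto the rooted tree's internal node labels
.label_supports <- function(phy, supports) {
  tips <- phy$tip.label
  anchor <- sort(tips)[1]
  ntip <- length(tips)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tips[i]
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po)))
    sets[[po[r, 1]]] <- c(sets[[po[r, 1]]], sets[[po[r, 2]]])
  labs <- character(phy$Nnode)
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    side <- sets[[v]]
    if (length(side) <= 1 || length(side) >= ntip - 1) { labs[v - ntip] <- ""; next }
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    labs[v - ntip] <- if (key %in% names(supports))
      sprintf("%g", supports[[key]]) else ""
  }
  phy$node.label <- labs
  phy
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat(sprintf("<nj_bootstrap> %d tips, %d replicates\n",
              length(x$tree$tip.label), x$n_reps))
  if (length(x$supports)) {
    cat("  internal-edge supports (%):",
        paste(sprintf("%.0f", sort(unname(x$supports), decreasing = TRUE)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a tree as Newick with supports as internal node labels
#'
#' @param x A `phylo` or `nj_bootstrap` object.
#' @param path Output path.
#' @export
write_newick <- function(x, path) {
  phy <- if (inherits(x, "nj_bootstrap")) x$tree else x
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a distance matrix as PHYLIP-style square TSV
#'
#' @param D Distance matrix.
#' @param path Output path.
#' @export
write_distance_matrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i],
                       sprintf("%.10g", D[i, ])), collapse = "\t"), con)
  invisible(path)
}
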