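# Pangenome construction: all-vs-all protein similarity graph across
# genomes, connected-component ortholog clusters, core-genome extraction
# with paralog exclusion, and length-weighted core-genome p-distances that
# feed the neighbor-joining phylogeny.

#' Cluster proteins into orthologous groups across genomes
#'
#' Builds a similarity graph over all proteins of all genomes (edges where
#' a pair aligns at or above the identity threshold with bidirectional
#' coverage) after a shared-5-mer prefilter, and takes connected
#' components as clusters. Cluster ids are deterministic: components are
#' ordered by their sorted member list.
#'
#' @param proteomes Named list (genome id -> AAStringSet or named
#'   character vector). At least 2 genomes; a genome with zero proteins is
#'   an error because the core genome would be undefined.
#' @param min_identity Percent identity for an edge (default 50).
#' @param min_cov Minimum aligned fraction of BOTH sequences (default 0.5).
#' @return Object of class `ortholog_clusters`: `membership` (data.frame
#'   cluster_id, genome_id, gene_id), `n_genomes`, `n_clusters`.
#' @export
cluster_orthologs <- function(proteomes, min_identity = 50, min_cov = 0.5) {
  stopifnot(length(proteomes) >= 2)
  sizes <- vapply(proteomes, length, integer(1))
  if (any(sizes == 0))
    stop("genome(s) with zero proteins: ",
         paste(names(proteomes)[sizes == 0], collapse = ", "),
         "; the core genome cannot be defined", call. = FALSE)
  seqs <- unlist(lapply(proteomes, as.character), use.names = FALSE)
  gids <- rep(names(proteomes), sizes)
  gene <- unlist(lapply(seq_along(proteomes), function(i) {
    nm <- names(proteomes[[i]])
    if (is.null(nm)) nm <- sprintf("%s|p%04d", names(proteomes)[i],
                                   seq_len(sizes[i]))
    sub("\\s.*$", "", nm)
  }), use.names = FALSE)
  n <- length(seqs)

  # candidate pairs: share >= 2 distinct 5-mers
  ktab <- aa_kmer_table(seqs)
  pairs <- ktab[ktab, on = "kmer", allow.cartesian = TRUE][sidx < i.sidx]
  if (nrow(pairs)) {
    cnt <- pairs[, .N, by = .(sidx, i.sidx)]
    cand <- cnt[N >= 2L]
  } else {
    cand <- data.table(sidx = integer(0), i.sidx = integer(0))
  }
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(cand)) {
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      a <- cand$sidx[r]; b <- cand$i.sidx[r]
      pa <- align_pair(AAString(seqs[a]), AAString(seqs[b]), mode = "local",
                       kind = "protein")
      if (pa$identity < min_identity) next
      la <- nchar(seqs[a]); lb <- nchar(seqs[b])
      aligned_a <- pa$query_coverage * la
      if (aligned_a / la >= min_cov && aligned_a / lb >= min_cov)
        keep[r] <- TRUE
    }
    edges <- cbind(cand$sidx[keep], cand$i.sidx[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  # deterministic ids: order components by sorted member keys
  keys <- paste(gids, gene, sep = "/")
  by_comp <- split(seq_len(n), comp)
  ord <- order(vapply(by_comp, function(ix)
    paste(sort(keys[ix]), collapse = ";"), character(1)))
  membership <- rbindlist(lapply(seq_along(ord), function(k) {
    ix <- by_comp[[ord[k]]]
    data.table(cluster_id = sprintf("COG%05d", k), genome_id = gids[ix],
               gene_id = gene[ix])
  }))
  membership <- as.data.frame(membership)
  stopifnot(nrow(membership) == n)   # partition covers every gene once
  structure(list(membership = membership, n_genomes = length(proteomes),
                 n_clusters = length(by_comp)),
            class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat(sprintf("<ortholog_clusters> %d clusters over %d genomes (%d genes)\n",
              x$n_clusters, x$n_genomes, nrow(x$membership)))
  invisible(x)
}

#' Core and single-copy core clusters
#'
#' Core clusters are present in every genome; single-copy core clusters
#' additionally have exactly one member per genome. The difference counts
#' paralogous core clusters, which are excluded from the phylogeny.
#'
#' @param clusters An `ortholog_clusters`.
#' @param n_genomes Number of genomes (defaults to the value recorded in
#'   `clusters`).
#' @return List: `core` (cluster ids), `single_copy_core` (cluster ids),
#'   `n_core`, `n_single_copy`, `n_paralogous_core`.
#' @export
core_single_copy <- function(clusters, n_genomes = clusters$n_genomes) {
  m <- as.data.table(clusters$membership)
  per <- m[, .(n_genomes_present = length(unique(genome_id)),
               n_members = .N), by = cluster_id]
  core <- per$cluster_id[per$n_genomes_present == n_genomes]
  sc <- per$cluster_id[per$n_genomes_present == n_genomes &
                       per$n_members == n_genomes]
  if (!length(core))
    warning("empty core: no cluster is present in all genomes",
            call. = FALSE)
  list(core = core, single_copy_core = sc,
       n_core = length(core), n_single_copy = length(sc),
       n_paralogous_core = length(core) - length(sc))
}

#' Per-gene p-distance matrices for the single-copy core
#'
#' For each single-copy core gene, global pairwise protein alignments give
#' a p-distance (1 - identity/100) between every pair of genomes. The
#' per-gene matrices and gene lengths are kept separate so that the
#' length-weighted combination (and any gene resampling for bootstrap) is
#' a cheap reweighting.
#'
#' @param clusters An `ortholog_clusters`.
#' @param proteomes The named proteome list used for clustering.
#' @param single_copy Cluster ids (default: computed via
#'   [core_single_copy()]).
#' @return List of class `core_pdistances`: `p` (array taxa x taxa x
#'   genes), `len` (mean protein length per gene), `taxa`, `genes`.
#' @export
core_gene_pdistances <- function(clusters, proteomes, single_copy = NULL) {
  if (is.null(single_copy))
    single_copy <- core_single_copy(clusters)$single_copy_core
  stopifnot(length(single_copy) >= 1, length(proteomes) >= 3)
  taxa <- names(proteomes)
  nt <- length(taxa)
  seqs_of <- lapply(proteomes, function(p) {
    s <- as_named_chr(p)
    if (is.null(names(s)))
      names(s) <- sprintf("p%04d", seq_along(s))
    names(s) <- sub("\\s.*$", "", names(s))
    s
  })
  m <- clusters$membership
  P <- array(NA_real_, dim = c(nt, nt, length(single_copy)),
             dimnames = list(taxa, taxa, single_copy))
  len <- numeric(length(single_copy))
  for (k in seq_along(single_copy)) {
    sub <- m[m$cluster_id == single_copy[k], ]
    sub <- sub[match(taxa, sub$genome_id), ]
    gs <- vapply(seq_len(nt), function(i) {
      seqs_of[[sub$genome_id[i]]][[sub$gene_id[i]]]
    }, character(1))
    len[k] <- mean(nchar(gs))
    pm <- matrix(0, nt, nt)
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      pa <- align_pair(AAString(gs[i]), AAString(gs[j]), mode = "global",
                       kind = "protein")
      pm[i, j] <- pm[j, i] <- 1 - pa$identity / 100
    }
    P[, , k] <- pm
  }
  structure(list(p = P, len = len, taxa = taxa, genes = single_copy),
            class = "core_pdistances")
}

#' Length-weighted core-genome distance matrix
#'
#' `D[i,j] = sum_g len_g * p_g(i,j) / sum_g len_g`, the distance implied
#' by concatenating the core gene alignments and averaging per-site
#' differences.
#'
#' @param pd A `core_pdistances` object, or (`clusters`, `proteomes`) to
#'   compute one.
#' @param proteomes Optional; see above.
#' @param gene_idx Optional gene indices (with repeats) — used by the
#'   bootstrap to resample genes.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
core_distances <- function(pd, proteomes = NULL, gene_idx = NULL) {
  if (!inherits(pd, "core_pdistances")) {
    stopifnot(!is.null(proteomes))
    pd <- core_gene_pdistances(pd, proteomes)
  }
  idx <- if (is.null(gene_idx)) seq_along(pd$len) else gene_idx
  w <- pd$len[idx]
  num <- 0
  for (t in seq_along(idx)) num <- num + w[t] * pd$p[, , idx[t]]
  D <- num / sum(w)
  dimnames(D) <- list(pd$taxa, pd$taxa)
  D
}
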