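# Reference panel: the labeled genome/protein/ITS/GH/mobile-marker
# databases that binning, the novelty screen, glycobiome profiling and ANI
# compare against. Genomes are supplied as FASTA plus a taxonomy TSV
# (genome_id, genus, species, strain); proteomes are auto-predicted by the
# six-frame ORF caller when not supplied.

#' Build a reference panel
#'
#' @param genomes Either a named list of DNAStringSet objects (one per
#'   genome, programmatic use) or a named character vector of FASTA paths,
#'   names being genome ids.
#' @param metadata A data.frame with columns `genome_id`, `genus`,
#'   `species`, `strain`, or the path of a tab-separated file with those
#'   columns.
#' @param proteins Optional named list of AAStringSet proteomes; genomes
#'   without one get a proteome from [find_orfs()].
#' @param its Optional DNAStringSet (or FASTA path) of ITS reference
#'   sequences, one per species; headers should carry `species=` tokens or
#'   default to the record id.
#' @param gh_reference Optional AAStringSet (or FASTA path) of GH family
#'   exemplars with `family=` and `label=` header tokens. Defaults to the
#'   small synthetic exemplar set shipped with the package.
#' @param mobile_markers Optional AAStringSet (or FASTA path) of mobile
#'   element (phage/plasmid) marker proteins. Defaults to the shipped
#'   synthetic set.
#' @param min_aa Minimum ORF length for auto-predicted proteomes.
#' @return An object of class `reference_panel`.
#' @export
build_panel <- function(genomes, metadata, proteins = NULL, its = NULL,
                        gh_reference = NULL, mobile_markers = NULL,
                        min_aa = 80L) {
  if (is.character(metadata)) {
    metadata <- read.delim(metadata, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("genome_id", "genus", "species", "strain")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$genome_id))
    stop("duplicate genome_id in metadata: ",
         paste(unique(metadata$genome_id[duplicated(metadata$genome_id)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(metadata$genus)))
    stop("every taxonomy row must name a non-empty genus", call. = FALSE)

  if (is.character(genomes)) {
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
      stop("genome FASTA paths must be named by genome_id", call. = FALSE)
    genomes <- lapply(genomes, read_fasta, kind = "nucleotide")
  }
  genomes <- lapply(genomes, function(g) {
    if (inherits(g, "synthetic_genome")) {
      x <- DNAStringSet(g$seq); names(x) <- g$id; x
    } else if (is.character(g)) {
      x <- DNAStringSet(vapply(g, normalize_dna, character(1)))
      if (is.null(names(x))) names(x) <- paste0("rec", seq_along(x))
      x
    } else g
  })
  gids <- names(genomes)
  orphans <- setdiff(gids, metadata$genome_id)
  if (length(orphans))
    stop("genomes absent from metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(metadata$genome_id, gids)
  if (length(missing))
    stop("metadata rows without a genome FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)

  if (is.null(proteins)) proteins <- list()
  for (g in gids) {
    if (is.null(proteins[[g]])) {
      calls <- do.call(rbind, lapply(seq_along(genomes[[g]]), function(i)
        find_orfs(genomes[[g]][i], min_aa = min_aa,
                  contig_id = seq_ids(genomes[[g]])[i],
                  nonoverlapping = TRUE)))
      aa <- AAStringSet(if (is.null(calls)) character(0) else calls$protein)
      if (length(aa))
        names(aa) <- sprintf("%s|orf%04d", g, seq_len(length(aa)))
      proteins[[g]] <- aa
    }
  }

  read_aa <- function(x) if (is.character(x) && length(x) == 1 && file.exists(x))
    readAAStringSet(x) else x
  if (is.null(gh_reference)) {
    p <- system.file("extdata", "gh_reference_synthetic.faa",
                     package = "metadark")
    if (nzchar(p)) gh_reference <- readAAStringSet(p)
  } else gh_reference <- read_aa(gh_reference)
  if (is.null(mobile_markers)) {
    p <- system.file("extdata", "mobile_markers_synthetic.faa",
                     package = "metadark")
    if (nzchar(p)) mobile_markers <- readAAStringSet(p)
  } else mobile_markers <- read_aa(mobile_markers)
  if (is.character(its) && length(its) == 1 && file.exists(its))
    its <- read_fasta(its, kind = "nucleotide")

  structure(list(genomes = genomes,
                 taxonomy = metadata[, need],
                 proteins = proteins,
                 its = its,
                 gh_reference = gh_reference,
                 mobile_markers = mobile_markers,
                 cache = new.env(parent = emptyenv())),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  np <- sum(vapply(x$proteins, length, integer(1)))
  cat(sprintf("<reference_panel> %d genomes, %d genera, %d proteins%s%s\n",
              length(x$genomes), length(unique(x$taxonomy$genus)), np,
              if (!is.null(x$its)) sprintf(", %d ITS refs", length(x$its)) else "",
              if (!is.null(x$gh_reference))
                sprintf(", %d GH refs", length(x$gh_reference)) else ""))
  invisible(x)
}

# genus / species of a genome id
panel_genus <- function(panel, genome_id) {
  panel$taxonomy$genus[match(genome_id, panel$taxonomy$genome_id)]
}
panel_species <- function(panel, genome_id) {
  panel$taxonomy$species[match(genome_id, panel$taxonomy$genome_id)]
}

# flat view of all panel proteins + cached 5-mer table
panel_protein_table <- function(panel) {
  if (!is.null(panel$cache$prot)) return(panel$cache$prot)
  seqs <- unlist(lapply(panel$proteins, as.character), use.names = FALSE)
  ids <- unlist(lapply(panel$proteins, names), use.names = FALSE)
  gid <- rep(names(panel$proteins),
             vapply(panel$proteins, length, integer(1)))
  res <- list(seq = seqs, id = ids, genome = gid,
              kmers = aa_kmer_table(seqs))
  assign("prot", res, envir = panel$cache)
  res
}

# cached nucleotide k-mer index + concatenated sequence of a genome
# (records joined by a 20-N spacer so no k-mer spans two records)
panel_genome_index <- function(panel, genome_id, k = 15L) {
  key <- paste0("gidx_", genome_id, "_", k)
  if (!is.null(panel$cache[[key]])) return(panel$cache[[key]])
  chr <- paste(as.character(panel$genomes[[genome_id]]),
               collapse = strrep("N", 20L))
  res <- list(chr = chr, index = nt_index(chr, k = k))
  assign(key, res, envir = panel$cache)
  res
}

#' Best panel hit per query protein
#'
#' For each query protein, reports the single highest-scoring panel protein
#' passing both thresholds (or no row). A 5-mer prefilter (at least 2
#' shared 5-mers) restricts alignment to plausible candidates; ties are
#' broken by higher identity, then lexicographically smallest genome id.
#'
#' @param query_proteins AAStringSet or named character vector.
#' @param panel A `reference_panel`.
#' @param min_identity Minimum percent identity (default 30).
#' @param min_cov Minimum query coverage fraction (default 0.5).
#' @param exhaustive Skip the k-mer prefilter and align against every
#'   panel protein (used for validating the prefilter).
#' @return data.frame: query_id, genome_id, subject_id, identity,
#'   coverage, score. Queries without a passing hit are absent.
#' @export
best_hits <- function(query_proteins, panel, min_identity = 30,
                      min_cov = 0.5, exhaustive = FALSE) {
  pt <- panel_protein_table(panel)
  qseq <- as_named_chr(query_proteins)
  qids <- if (!is.null(names(qseq))) sub("\\s.*$", "", names(qseq))
          else paste0("q", seq_along(qseq))
  rows <- vector("list", length(qseq))
  for (i in seq_along(qseq)) {
    cand <- if (exhaustive) seq_along(pt$seq)
            else aa_prefilter(qseq[i], pt$kmers)
    if (!length(cand)) next
    best <- NULL
    for (j in cand) {
      pa <- align_pair(AAString(qseq[i]), AAString(pt$seq[j]),
                       mode = "local", kind = "protein")
      if (pa$identity < min_identity || pa$query_coverage < min_cov) next
      rec <- list(query_id = qids[i], genome_id = pt$genome[j],
                  subject_id = pt$id[j], identity = pa$identity,
                  coverage = pa$query_coverage, score = pa$score)
      if (is.null(best) ||
          rec$score > best$score ||
          (rec$score == best$score && rec$identity > best$identity) ||
          (rec$score == best$score && rec$identity == best$identity &&
           rec$genome_id < best$genome_id)) {
        best <- rec
      }
    }
    if (!is.null(best)) rows[[i]] <- as.data.frame(best)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), genome_id = character(0),
                      subject_id = character(0), identity = numeric(0),
                      coverage = numeric(0), score = numeric(0))
  stopifnot(all(out$identity >= min_identity), all(out$coverage >= min_cov))
  rownames(out) <- NULL
  out
}

#' Persist a reference panel to a directory
#'
#' Writes per-genome FASTA, proteome FASTA, the taxonomy TSV, any ITS/GH/
#' mobile sets, and a JSON manifest. No binary formats are used.
#'
#' @param panel A `reference_panel`.
#' @param dir Output directory (created if absent).
#' @export
save_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(panel$genomes))
    write_fasta(panel$genomes[[g]], file.path(dir, paste0(g, ".fna")))
  for (g in names(panel$proteins))
    if (length(panel$proteins[[g]]))
      write_fasta(panel$proteins[[g]], file.path(dir, paste0(g, ".faa")))
  write.table(panel$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(panel$its)) write_fasta(panel$its, file.path(dir, "its.fna"))
  if (!is.null(panel$gh_reference))
    write_fasta(panel$gh_reference, file.path(dir, "gh_reference.faa"))
  if (!is.null(panel$mobile_markers))
    write_fasta(panel$mobile_markers, file.path(dir, "mobile_markers.faa"))
  manifest <- list(format = "metadark_panel/1",
                   genomes = names(panel$genomes),
                   has_its = !is.null(panel$its),
                   has_gh = !is.null(panel$gh_reference),
                   has_mobile = !is.null(panel$mobile_markers))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a reference panel saved by [save_panel()]
#'
#' @param dir Panel directory.
#' @return A `reference_panel`.
#' @export
load_panel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  genomes <- lapply(man$genomes, function(g)
    read_fasta(file.path(dir, paste0(g, ".fna")), kind = "nucleotide"))
  names(genomes) <- man$genomes
  proteins <- lapply(man$genomes, function(g) {
    p <- file.path(dir, paste0(g, ".faa"))
    if (file.exists(p)) readAAStringSet(p) else AAStringSet(character(0))
  })
  names(proteins) <- man$genomes
  build_panel(genomes, file.path(dir, "taxonomy.tsv"), proteins = proteins,
              its = if (isTRUE(man$has_its))
                read_fasta(file.path(dir, "its.fna"), "nucleotide") else NULL,
              gh_reference = if (isTRUE(man$has_gh))
                readAAStringSet(file.path(dir, "gh_reference.faa")) else NULL,
              mobile_markers = if (isTRUE(man$has_mobile))
                readAAStringSet(file.path(dir, "mobile_markers.faa")) else NULL)
}
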