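# Genus-level classification of contigs (or reads) by proteome best-hit
# voting, and bp-weighted relative-abundance profiling of the community.

#' Classify one sequence to genus by proteome voting
#'
#' Genes are called with [find_orfs()]; each gene's best panel hit maps to
#' the genus of its genome, and the winning genus is the one with the
#' highest summed alignment score. Records shorter than 300 nt, or records
#' in which no ORF reaches `min_aa`, are classified by direct nucleotide
#' comparison against the panel genomes instead (ORF calling is unreliable
#' there).
#'
#' @param contig A DNAString / single-record DNAStringSet / character.
#' @param panel A `reference_panel`.
#' @param min_aa Minimum ORF length for gene calling.
#' @param min_identity,min_cov Protein search thresholds (see
#'   [best_hits()]).
#' @param nt_min_identity Minimum percent identity for nucleotide-mode
#'   assignment of short or ORF-free records.
#' @param seq_id Id recorded in the output.
#' @return A one-row data.frame: `seq_id`, `genus` ("unclassified" when no
#'   gene or nucleotide evidence), `support` (fraction of hit-bearing genes
#'   voting for the winner), `n_genes`, `bp`.
#' @export
classify_contig <- function(contig, panel, min_aa = 80L, min_identity = 30,
                            min_cov = 0.5, nt_min_identity = 80,
                            seq_id = NULL) {
  if (is(contig, "XStringSet")) {
    if (is.null(seq_id)) seq_id <- id_or(contig, "contig")
    contig <- contig[[1]]
  }
  s <- normalize_dna(as.character(contig))
  if (is.null(seq_id)) seq_id <- "contig"
  bp <- nchar(s)
  unclassified <- data.frame(seq_id = seq_id, genus = "unclassified",
                             support = 0, n_genes = 0L, bp = bp,
                             stringsAsFactors = FALSE)
  calls <- if (bp >= 300L) find_orfs(s, min_aa = min_aa, contig_id = seq_id,
                                     nonoverlapping = TRUE)
           else data.frame()
  if (!nrow(calls)) {
    # nucleotide mode: seed-and-extend against each panel genome
    best_g <- NULL; best_sc <- 0
    for (g in names(panel$genomes)) {
      gi <- panel_genome_index(panel, g)
      fr <- map_fragments(s, gi$index, gi$chr)
      ok <- !is.na(fr$identity) & fr$identity >= nt_min_identity
      if (!any(ok)) next
      sc <- sum(fr$identity[ok] * fr$len[ok] * fr$coverage[ok])
      if (sc > best_sc) { best_sc <- sc; best_g <- g }
    }
    if (is.null(best_g)) return(unclassified)
    return(data.frame(seq_id = seq_id, genus = panel_genus(panel, best_g),
                      support = 1, n_genes = 0L, bp = bp,
                      stringsAsFactors = FALSE))
  }
  prot <- setNames(calls$protein,
                   sprintf("%s_g%03d", seq_id, seq_len(nrow(calls))))
  hits <- best_hits(prot, panel, min_identity = min_identity,
                    min_cov = min_cov)
  if (!nrow(hits)) return(unclassified)
  hits$genus <- panel_genus(panel, hits$genome_id)
  by_genus <- tapply(hits$score, hits$genus, sum)
  winner <- names(by_genus)[order(-by_genus, names(by_genus))][1]
  support <- sum(hits$genus == winner) / nrow(hits)
  data.frame(seq_id = seq_id, genus = winner, support = support,
             n_genes = nrow(calls), bp = bp, stringsAsFactors = FALSE)
}

#' Classify every record of a contig set
#'
#' @param contigs A DNAStringSet.
#' @param panel A `reference_panel`.
#' @param ... Passed to [classify_contig()].
#' @return data.frame of per-record assignments (one row per contig).
#' @export
classify_sample <- function(contigs, panel, ...) {
  ids <- seq_ids(contigs)
  out <- lapply(seq_along(contigs), function(i)
    classify_contig(contigs[[i]], panel, seq_id = ids[i], ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' bp-weighted genus abundance profile
#'
#' Fractions are weighted by record length and sum to 1 over all genera
#' including "unclassified". Genera below `min_fraction` are folded into
#' "other" by the print method only; the machine-readable fractions retain
#' every genus exactly.
#'
#' @param assignments data.frame from [classify_sample()].
#' @param min_fraction Reporting threshold (default 0.002, i.e. 0.2% of
#'   the assembled data).
#' @return Object of class `abundance_profile`: `fractions` (named,
#'   sums to 1), `total_bp`, `min_fraction_reported`.
#' @export
abundance_profile <- function(assignments, min_fraction = 0.002) {
  stopifnot(nrow(assignments) > 0)
  bp_by <- tapply(assignments$bp, assignments$genus, sum)
  total <- sum(assignments$bp)
  fr <- sort(bp_by / total, decreasing = TRUE)
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  structure(list(fractions = fr, total_bp = total,
                 min_fraction_reported = min_fraction),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %d genera over %d bp (reporting floor %.2f%%)\n",
              length(x$fractions), x$total_bp,
              100 * x$min_fraction_reported))
  show <- x$fractions[x$fractions >= x$min_fraction_reported]
  other <- sum(x$fractions[x$fractions < x$min_fraction_reported])
  for (g in names(show)) cat(sprintf("  %-24s %6.2f%%\n", g, 100 * show[g]))
  if (other > 0) cat(sprintf("  %-24s %6.2f%%\n", "other", 100 * other))
  invisible(x)
}

#' Write an abundance profile as JSON
#'
#' @param profile An `abundance_profile`.
#' @param path Output path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(list(fractions = as.list(profile$fractions),
                            total_bp = profile$total_bp,
                            min_fraction_reported = profile$min_fraction_reported),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
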