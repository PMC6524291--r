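# Novelty screen: per-contig decision among known_species, mobile_element,
# novel_candidate and too_short, combining three evidence levels against
# the reference panel — nucleotide fragment chains, proteome best-hit
# identities, and whole-sequence anchor coverage — plus a mobile-element
# marker test that automates the removal of phage/plasmid contigs.

#' Screening thresholds
#'
#' All cutoffs of the novelty screen in one place; every output header
#' echoes them for provenance. The defaults align the nucleotide "known"
#' identity with the 95% ANI species boundary.
#'
#' @param min_len Contigs of length <= `min_len` are `too_short`
#'   (default 5000; the retained set is strictly "> 5000 bp").
#' @param nt_known_identity Percent nucleotide identity at or above which
#'   a contig region counts as matching a known genome (default 95).
#' @param nt_known_cov Fraction of the contig that must align at
#'   `nt_known_identity` for the nucleotide test (default 0.75).
#' @param prot_known_identity Mean percent best-hit protein identity to a
#'   single genome that marks a contig as known (default 96).
#' @param wga_known_cov Fraction of the contig that whole-sequence anchor
#'   chains must cover at `nt_known_identity` (default 0.75).
#' @param mobile_gene_fraction Fraction of genes best-matching mobile
#'   markers at or above which a contig is a mobile element (default 0.5).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_len = 5000L, nt_known_identity = 95,
                              nt_known_cov = 0.75, prot_known_identity = 96,
                              wga_known_cov = 0.75,
                              mobile_gene_fraction = 0.5) {
  stopifnot(nt_known_identity > 0, nt_known_identity <= 100,
            prot_known_identity > 0, prot_known_identity <= 100,
            nt_known_cov > 0, nt_known_cov <= 1,
            wga_known_cov > 0, wga_known_cov <= 1,
            mobile_gene_fraction > 0, mobile_gene_fraction <= 1)
  structure(list(min_len = as.integer(min_len),
                 nt_known_identity = nt_known_identity,
                 nt_known_cov = nt_known_cov,
                 prot_known_identity = prot_known_identity,
                 wga_known_cov = wga_known_cov,
                 mobile_gene_fraction = mobile_gene_fraction),
            class = "screen_thresholds")
}

# best local alignment of one protein against the mobile-marker set,
# behind a shared-5-mer prefilter (mkmers: cached aa_kmer_table)
.mobile_best <- function(protein, markers, mkmers, min_identity = 30,
                         min_cov = 0.5) {
  best <- NULL
  for (j in aa_prefilter(protein, mkmers)) {
    pa <- align_pair(AAString(protein), markers[[j]], mode = "local",
                     kind = "protein")
    if (pa$identity < min_identity || pa$query_coverage < min_cov) next
    if (is.null(best) || pa$score > best$score)
      best <- list(score = pa$score, id = seq_ids(markers)[j])
  }
  best
}

#' Screen one contig for novelty
#'
#' Evaluation order: (1) length filter; (2) mobile-element test — the
#' fraction of genes whose best mobile-marker hit outscores their best
#' panel hit; (3) "known" tests against each panel genome at nucleotide,
#' protein, and whole-sequence level; (4) otherwise `novel_candidate`.
#'
#' @param contig DNAString / single-record DNAStringSet / character.
#' @param panel A `reference_panel`.
#' @param thresholds A [screen_thresholds()] object.
#' @param min_aa Minimum ORF length for gene calling.
#' @param contig_id Id recorded in the verdict.
#' @return A list of class `contig_verdict`: `contig_id`, `status`,
#'   `matched_species` (or NA), `bp`, and an `evidence` list.
#' @export
screen_contig <- function(contig, panel, thresholds = screen_thresholds(),
                          min_aa = 80L, contig_id = NULL) {
  if (is(contig, "XStringSet")) {
    if (is.null(contig_id)) contig_id <- id_or(contig, "contig")
    contig <- contig[[1]]
  }
  if (is.null(contig_id)) contig_id <- "contig"
  s <- normalize_dna(as.character(contig))
  bp <- nchar(s)
  th <- thresholds
  verdict <- function(status, matched = NA_character_, evidence = list()) {
    structure(list(contig_id = contig_id, status = status,
                   matched_species = matched, bp = bp,
                   evidence = evidence, thresholds = th),
              class = "contig_verdict")
  }
  if (bp <= th$min_len) return(verdict("too_short"))

  calls <- find_orfs(s, min_aa = min_aa, contig_id = contig_id,
                     nonoverlapping = TRUE)
  n_genes <- nrow(calls)
  hits <- if (n_genes) {
    prot <- setNames(calls$protein,
                     sprintf("%s_g%03d", contig_id, seq_len(n_genes)))
    best_hits(prot, panel)
  } else data.frame()

  # (2) mobile-element test
  mobile_frac <- 0
  if (n_genes && !is.null(panel$mobile_markers) &&
      length(panel$mobile_markers)) {
    if (is.null(panel$cache$mobile_kmers))
      assign("mobile_kmers",
             aa_kmer_table(as.character(panel$mobile_markers)),
             envir = panel$cache)
    mkmers <- panel$cache$mobile_kmers
    n_mobile <- 0L
    for (i in seq_len(n_genes)) {
      qid <- sprintf("%s_g%03d", contig_id, i)
      mb <- .mobile_best(calls$protein[i], panel$mobile_markers, mkmers)
      if (is.null(mb)) next
      psc <- if (nrow(hits)) hits$score[match(qid, hits$query_id)] else NA
      if (is.na(psc) || mb$score > psc) n_mobile <- n_mobile + 1L
    }
    mobile_frac <- n_mobile / n_genes
  }
  if (mobile_frac >= th$mobile_gene_fraction)
    return(verdict("mobile_element",
                   evidence = list(mobile_fraction = mobile_frac,
                                   n_genes = n_genes)))

  # (3) known-species tests per genome
  nt_best <- list(identity = NA_real_, cov = 0, genome = NA_character_)
  wga_best <- list(cov = 0, genome = NA_character_)
  for (g in names(panel$genomes)) {
    gi <- panel_genome_index(panel, g)
    fr <- map_fragments(s, gi$index, gi$chr)
    ok <- !is.na(fr$identity) & fr$identity >= th$nt_known_identity
    if (!any(ok)) next
    cov <- sum(fr$len[ok] * fr$coverage[ok]) / bp
    mid <- sum(fr$identity[ok] * fr$len[ok] * fr$coverage[ok]) /
      sum(fr$len[ok] * fr$coverage[ok])
    if (cov > nt_best$cov)
      nt_best <- list(identity = mid, cov = cov, genome = g)
    if (cov > wga_best$cov) wga_best <- list(cov = cov, genome = g)
  }
  prot_best <- list(identity = NA_real_, frac = 0, genome = NA_character_)
  if (nrow(hits)) {
    for (g in unique(hits$genome_id)) {
      sub <- hits[hits$genome_id == g, ]
      frac <- nrow(sub) / n_genes
      mid <- mean(sub$identity)
      if (frac >= 0.5 && (is.na(prot_best$identity) || mid > prot_best$identity))
        prot_best <- list(identity = mid, frac = frac, genome = g)
    }
  }
  evidence <- list(nt_best_identity = nt_best$identity,
                   nt_best_cov = nt_best$cov, nt_best_genome = nt_best$genome,
                   prot_mean_identity = prot_best$identity,
                   prot_gene_fraction = prot_best$frac,
                   prot_best_genome = prot_best$genome,
                   wga_cov = wga_best$cov, wga_genome = wga_best$genome,
                   mobile_fraction = mobile_frac, n_genes = n_genes)
  pass_nt <- !is.na(nt_best$identity) &&
    nt_best$identity >= th$nt_known_identity && nt_best$cov >= th$nt_known_cov
  pass_prot <- !is.na(prot_best$identity) &&
    prot_best$identity >= th$prot_known_identity
  pass_wga <- wga_best$cov >= th$wga_known_cov
  if (pass_nt || pass_prot || pass_wga) {
    g <- if (pass_nt) nt_best$genome
         else if (pass_prot) prot_best$genome else wga_best$genome
    return(verdict("known_species", matched = panel_species(panel, g),
                   evidence = evidence))
  }
  if (n_genes == 0 && nt_best$cov == 0)
    evidence$flags <- "no_evidence"
  verdict("novel_candidate", evidence = evidence)
}

#' @export
print.contig_verdict <- function(x, ...) {
  cat(sprintf("<contig_verdict> %s: %s (%d bp)%s\n", x$contig_id, x$status,
              x$bp, if (!is.na(x$matched_species))
                paste0(" -> ", x$matched_species) else ""))
  invisible(x)
}

#' Screen a whole contig set
#'
#' Runs [screen_contig()] on every record and aggregates counts and summed
#' bp per status (the quantities behind a known-vs-novel bp breakdown of a
#' sample). Putative novel contigs can be written to a dedicated FASTA for
#' glycobiome analysis; contigs with a borderline mobile-gene fraction
#' (0.3-0.5) are listed for manual review rather than auto-decided.
#'
#' @param contigs DNAStringSet.
#' @param panel A `reference_panel`.
#' @param thresholds A [screen_thresholds()] object.
#' @param novel_fasta Optional path: novel_candidate contigs written here.
#' @param ... Passed to [screen_contig()].
#' @return Object of class `screen_report`: `verdicts` (data.frame),
#'   `summary` (status, n, bp), `review` (borderline contig ids),
#'   `thresholds`.
#' @export
screen_sample <- function(contigs, panel, thresholds = screen_thresholds(),
                          novel_fasta = NULL, ...) {
  ids <- seq_ids(contigs)
  vs <- lapply(seq_along(contigs), function(i)
    screen_contig(contigs[[i]], panel, thresholds, contig_id = ids[i], ...))
  verdicts <- data.frame(
    contig_id = vapply(vs, `[[`, character(1), "contig_id"),
    status = vapply(vs, `[[`, character(1), "status"),
    matched_species = vapply(vs, `[[`, character(1), "matched_species"),
    bp = vapply(vs, `[[`, numeric(1), "bp"),
    mobile_fraction = vapply(vs, function(v)
      if (!is.null(v$evidence$mobile_fraction))
        v$evidence$mobile_fraction else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  lev <- c("known_species", "novel_candidate", "mobile_element", "too_short")
  summ <- data.frame(status = lev,
                     n = as.integer(table(factor(verdicts$status, lev))),
                     bp = as.numeric(tapply(verdicts$bp,
                                            factor(verdicts$status, lev),
                                            sum, default = 0)))
  summ$bp[is.na(summ$bp)] <- 0
  review <- verdicts$contig_id[!is.na(verdicts$mobile_fraction) &
                               verdicts$mobile_fraction >= 0.3 &
                               verdicts$mobile_fraction <
                                 thresholds$mobile_gene_fraction]
  if (!is.null(novel_fasta)) {
    novel <- contigs[verdicts$status == "novel_candidate"]
    write_fasta(novel, novel_fasta)
  }
  structure(list(verdicts = verdicts, summary = summ, review = review,
                 thresholds = thresholds, details = vs),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-16s %4d contigs  %12.0f bp\n", x$summary$status[i],
                x$summary$n[i], x$summary$bp[i]))
  if (length(x$review))
    cat("  review (borderline mobile):", paste(x$review, collapse = ", "), "\n")
  invisible(x)
}

#' Write a screen report (TSV verdicts + JSON aggregate)
#'
#' Both files carry the thresholds in a header comment for provenance.
#'
#' @param report A `screen_report`.
#' @param tsv,json Output paths (either may be NULL).
#' @export
write_screen_report <- function(report, tsv = NULL, json = NULL) {
  hdr <- paste0("# metadark novelty screen; thresholds: ",
                paste(sprintf("%s=%s", names(unclass(report$thresholds)),
                              unlist(report$thresholds)), collapse = " "))
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines(hdr, con)
    suppressWarnings(write.table(report$verdicts, con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    close(con)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(thresholds = unclass(report$thresholds),
                              summary = report$summary,
                              review = report$review),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
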