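# Glycobiome profiling: assign predicted proteins to glycosyl-hydrolase
# (GH) families by best hit against a GH reference set, summarize the
# family repertoire, and convert it into ranked carbon-source
# recommendations for selective cultivation.

# parse "family=GH13 label=pullulanase" style tokens from FASTA headers
.gh_meta <- function(headers) {
  fam <- sub(".*family=([^ ]+).*", "\\1", headers)
  fam[!grepl("family=", headers)] <- NA
  lab <- sub(".*label=([^ ]+).*", "\\1", headers)
  lab[!grepl("label=", headers)] <- ""
  # fall back to id prefix "GH13_pullulanase_1"
  ids <- sub("\\s.*$", "", headers)
  guess <- strsplit(ids, "_")
  fam[is.na(fam)] <- vapply(guess[is.na(fam)], `[`, character(1), 1)
  need <- !nzchar(lab)
  lab[need] <- vapply(guess[need], function(x)
    if (length(x) >= 2) x[2] else "", character(1))
  data.frame(id = ids, family = fam, label = lab, stringsAsFactors = FALSE)
}

#' Assign proteins to GH families
#'
#' Each query protein is aligned against the GH reference set; the best
#' hit passing the identity and coverage thresholds assigns the family and
#' subfamily label of the reference record.
#'
#' @param proteins AAStringSet or named character vector of amino-acid
#'   sequences.
#' @param gh_reference AAStringSet of labeled GH exemplars (headers carry
#'   `family=` / `label=` tokens, or `GHnn_label_*` ids).
#' @param min_identity Minimum percent identity (default 40; GH families
#'   are conserved across genera at roughly this level).
#' @param min_cov Minimum query coverage (default 0.7).
#' @return data.frame: gene_id, gh_family, subfamily_label, identity,
#'   coverage.
#' @export
assign_gh <- function(proteins, gh_reference, min_identity = 40,
                      min_cov = 0.7) {
  stopifnot(length(gh_reference) > 0)
  meta <- .gh_meta(names(gh_reference))
  refs <- as.character(gh_reference)
  ktab <- aa_kmer_table(refs)
  qseq <- as_named_chr(proteins)
  qids <- if (!is.null(names(qseq))) sub("\\s.*$", "", names(qseq))
          else paste0("q", seq_along(qseq))
  rows <- list()
  for (i in seq_along(qseq)) {
    cand <- aa_prefilter(qseq[i], ktab)
    best <- NULL
    for (j in cand) {
      pa <- align_pair(AAString(qseq[i]), AAString(refs[j]), mode = "local",
                       kind = "protein")
      if (pa$identity < min_identity || pa$query_coverage < min_cov) next
      if (is.null(best) || pa$score > best$score)
        best <- list(j = j, identity = pa$identity,
                     coverage = pa$query_coverage, score = pa$score)
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = qids[i], gh_family = meta$family[best$j],
        subfamily_label = meta$label[best$j], identity = best$identity,
        coverage = best$coverage, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), gh_family = character(0),
               subfamily_label = character(0), identity = numeric(0),
               coverage = numeric(0))
  rownames(out) <- NULL
  out
}

#' Summarize GH assignments into a glycobiome profile
#'
#' @param assignments data.frame from [assign_gh()].
#' @return Object of class `glycobiome_profile`: `counts` and `rel_abund`
#'   per family (fractions sum to 1 over assigned genes), `n_genes_total`,
#'   and the assignment table for auditability.
#' @export
glycobiome_profile <- function(assignments) {
  if (!nrow(assignments)) {
    return(structure(list(counts = integer(0), rel_abund = numeric(0),
                          n_genes_total = 0L, assignments = assignments),
                     class = "glycobiome_profile"))
  }
  cnt <- sort(table(assignments$gh_family), decreasing = TRUE)
  rel <- as.numeric(cnt) / sum(cnt)
  names(rel) <- names(cnt)
  stopifnot(abs(sum(rel) - 1) < 1e-9)
  structure(list(counts = as.integer(cnt), rel_abund = rel,
                 n_genes_total = nrow(assignments),
                 assignments = assignments),
            class = "glycobiome_profile")
}

#' @export
print.glycobiome_profile <- function(x, ...) {
  cat(sprintf("<glycobiome_profile> %d GH genes in %d families\n",
              x$n_genes_total, length(x$rel_abund)))
  for (f in names(x$rel_abund))
    cat(sprintf("  %-8s %5.1f%%\n", f, 100 * x$rel_abund[f]))
  invisible(x)
}

#' Default substrate rule map
#'
#' Each rule is a conjunction of alternative-sets over GH families
#' (optionally restricted to a subfamily label as `FAM:label`): the rule
#' fires when every conjunct is satisfied by at least one assigned gene.
#' The default map encodes pullulanase-bearing GH13 to pullulan, amylase
#' GH13 to starch, endo-xylanase (GH10/GH11) plus beta-xylosidase
#' (GH43 or GH3) to xylan, and GH53 to arabinogalactan.
#'
#' @return data.frame with columns `pattern`, `substrate`, `weight`.
#' @export
default_substrate_map <- function() {
  data.frame(
    pattern = c("GH13:pullulanase",
                "GH13:amylase",
                "GH10|GH11 & GH43|GH3:beta-xylosidase",
                "GH53"),
    substrate = c("pullulan", "starch", "xylan", "arabinogalactan"),
    weight = 1.0,
    stringsAsFactors = FALSE)
}

#' Read a substrate rule map from TSV
#'
#' @param path TSV with columns pattern, substrate, weight.
#' @return data.frame usable by [recommend_substrates()].
#' @export
read_substrate_map <- function(path) {
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "substrate", "weight") %in% names(m)))
  m
}

# does any assignment satisfy one term ("GH13" or "GH13:pullulanase")?
.term_genes <- function(term, assignments) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  ok <- assignments$gh_family == parts[1]
  if (length(parts) > 1)
    ok <- ok & grepl(parts[2], assignments$subfamily_label, fixed = TRUE)
  assignments$gene_id[ok]
}

#' Rank candidate carbon sources from a glycobiome profile
#'
#' A rule fires when its GH pattern is present among the assignments; the
#' substrate score is the summed `weight x relative abundance` of the
#' supporting families. Recommendations are ranked by descending score,
#' ties broken by substrate name, and each lists its supporting gene ids.
#'
#' @param profile A `glycobiome_profile`.
#' @param map Rule table (default [default_substrate_map()]).
#' @param top_k Return at most this many substrates (default all).
#' @return Object of class `substrate_recommendation`: data.frame
#'   `ranking` (substrate, score, supporting genes) and `notice` when no
#'   GH evidence exists.
#' @export
recommend_substrates <- function(profile, map = default_substrate_map(),
                                 top_k = Inf) {
  stopifnot(inherits(profile, "glycobiome_profile"))
  if (profile$n_genes_total == 0) {
    return(structure(list(ranking = data.frame(substrate = character(0),
                                               score = numeric(0),
                                               genes = character(0)),
                          notice = "no GH evidence"),
                     class = "substrate_recommendation"))
  }
  asn <- profile$assignments
  rows <- list()
  for (r in seq_len(nrow(map))) {
    conjuncts <- trimws(strsplit(map$pattern[r], "&", fixed = TRUE)[[1]])
    genes <- character(0)
    fams <- character(0)
    fired <- TRUE
    for (cj in conjuncts) {
      terms <- trimws(strsplit(cj, "|", fixed = TRUE)[[1]])
      gset <- unique(unlist(lapply(terms, .term_genes, assignments = asn)))
      if (!length(gset)) { fired <- FALSE; break }
      genes <- union(genes, gset)
      fams <- union(fams, sub(":.*$", "", terms))
    }
    if (!fired) next
    support <- sum(profile$rel_abund[intersect(fams, names(profile$rel_abund))])
    rows[[length(rows) + 1L]] <- data.frame(
      substrate = map$substrate[r], score = map$weight[r] * support,
      genes = paste(genes, collapse = ","), stringsAsFactors = FALSE)
  }
  rk <- if (length(rows)) do.call(rbind, rows) else
    data.frame(substrate = character(0), score = numeric(0),
               genes = character(0))
  if (nrow(rk)) {
    rk <- rk[order(-rk$score, rk$substrate), , drop = FALSE]
    stopifnot(all(nzchar(rk$genes)))   # every recommendation is auditable
    if (is.finite(top_k)) rk <- head(rk, top_k)
    rownames(rk) <- NULL
  }
  structure(list(ranking = rk, notice = NULL),
            class = "substrate_recommendation")
}

#' @export
print.substrate_recommendation <- function(x, ...) {
  if (!is.null(x$notice)) {
    cat("<substrate_recommendation>", x$notice, "\n")
    return(invisible(x))
  }
  cat("<substrate_recommendation>\n")
  for (i in seq_len(nrow(x$ranking)))
    cat(sprintf("  %d. %-16s score %.3f\n", i, x$ranking$substrate[i],
                x$ranking$score[i]))
  invisible(x)
}
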