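# ITS-based isolate triage: assign an isolate's internal transcribed
# spacer sequence to a known species, or flag it as putatively novel when
# its best reference identity falls below the species threshold.

#' Classify an ITS sequence against a reference ITS database
#'
#' The query is globally aligned against every reference ITS; the best hit
#' by identity decides the verdict: `assigned` when identity and coverage
#' clear the species thresholds, `putative_novel` when the best identity
#' falls short, `no_hit` when nothing aligns.
#'
#' @param its_seq Character / DNAString / single-record DNAStringSet.
#' @param its_refs DNAStringSet of reference ITS sequences; headers may
#'   carry `species=` tokens, otherwise the record id names the species.
#' @param species_identity Percent identity for a species-level assignment
#'   (default 98).
#' @param min_cov Minimum query coverage (default 0.9).
#' @param isolate_id Id recorded in the call.
#' @return One-row data.frame: isolate_id, best_species, identity,
#'   coverage, verdict.
#' @export
classify_its <- function(its_seq, its_refs, species_identity = 98,
                         min_cov = 0.9, isolate_id = NULL) {
  stopifnot(length(its_refs) > 0)
  if (is(its_seq, "XStringSet")) {
    if (is.null(isolate_id)) isolate_id <- id_or(its_seq, "isolate")
    its_seq <- its_seq[[1]]
  }
  if (is.null(isolate_id)) isolate_id <- "isolate"
  s <- normalize_dna(as.character(its_seq))
  if (nchar(s) < 50)
    stop("ITS query shorter than 50 nt: too short to classify", call. = FALSE)
  hdr <- names(its_refs)
  sp <- ifelse(grepl("species=", hdr),
               sub(".*species=([^ ]+).*", "\\1", hdr),
               sub("\\s.*$", "", hdr))
  best <- NULL
  for (j in seq_along(its_refs)) {
    pa <- align_pair(DNAString(s), its_refs[[j]], mode = "global",
                     kind = "nucleotide")
    if (is.null(best) || pa$identity > best$identity)
      best <- list(identity = pa$identity, coverage = pa$query_coverage,
                   species = sp[j])
  }
  verdict <- if (is.null(best) || best$identity <= 0) "no_hit"
             else if (best$identity >= species_identity &&
                      best$coverage >= min_cov) "assigned"
             else "putative_novel"
  data.frame(isolate_id = isolate_id,
             best_species = if (verdict == "no_hit") NA_character_
                            else best$species,
             identity = if (is.null(best)) NA_real_ else best$identity,
             coverage = if (is.null(best)) NA_real_ else best$coverage,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Classify a batch of isolate ITS sequences
#'
#' @param its_seqs DNAStringSet of isolate ITS sequences.
#' @param its_refs Reference ITS DNAStringSet.
#' @param ... Passed to [classify_its()].
#' @return data.frame with one row per isolate.
#' @export
classify_its_batch <- function(its_seqs, its_refs, ...) {
  ids <- seq_ids(its_seqs)
  out <- lapply(seq_along(its_seqs), function(i)
    classify_its(its_seqs[[i]], its_refs, isolate_id = ids[i], ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
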