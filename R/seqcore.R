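# Sequence primitives: FASTA I/O, normalization, translation, six-frame ORF
# calling and affine-gap pairwise alignment. Everything downstream (binning,
# novelty screen, glycobiome, ANI, pangenome) is built on these.

#' Normalize a nucleotide sequence
#'
#' Folds case, converts RNA U to T, and verifies the result contains only
#' the characters A, C, G, T, N. Ambiguity codes other than N are not part
#' of the toolkit's alphabet.
#'
#' @param x Character scalar (a nucleotide sequence).
#' @return Normalized uppercase character scalar.
#' @export
normalize_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide character '%s' at position %d",
                 substr(x, bad, bad), bad), call. = FALSE)
  }
  x
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @param kind Either "nucleotide" or "protein".
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; names
#'   hold the full FASTA headers (use [seq_ids()] for the id token).
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (kind == "nucleotide") {
    x <- Biostrings::readBStringSet(path)
    seqs <- vapply(as.character(x), normalize_dna, character(1), USE.NAMES = FALSE)
    out <- DNAStringSet(seqs)
    names(out) <- names(x)
  } else {
    out <- readAAStringSet(path)
  }
  ids <- seq_ids(out)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param x An XStringSet (names become headers).
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Sequence ids (first whitespace-delimited token of each FASTA header)
#'
#' @param x An XStringSet.
#' @return Character vector of ids.
#' @export
seq_ids <- function(x) {
  n <- names(x)
  if (is.null(n)) stop("sequences have no names", call. = FALSE)
  sub("\\s.*$", "", n)
}

#' Translate a nucleotide sequence
#'
#' Codon-by-codon translation under a chosen genetic code. Stops are
#' rendered as `*`, codons containing N as `X`, and a trailing partial
#' codon is ignored.
#'
#' @param dna Character scalar or [Biostrings::DNAString].
#' @param table NCBI genetic-code id; default "11" (bacterial).
#' @return Character scalar amino-acid sequence.
#' @export
translate_dna <- function(dna, table = "11") {
  s <- normalize_dna(as.character(dna))
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon", call. = FALSE)
  s <- substr(s, 1L, n - (n %% 3L))
  aa <- translate(DNAString(s), genetic.code = getGeneticCode(as.character(table)),
                  if.fuzzy.codon = "X", no.init.codon = TRUE)
  as.character(aa)
}

#' Find open reading frames in all six frames
#'
#' Calls maximal stop-to-stop ORFs that begin at an ATG/GTG/TTG start codon
#' and end at a stop codon, on both strands. Coordinates are 0-based
#' half-open on the forward strand and include the terminal stop codon, so
#' the protein length is `(end - start)/3 - 1`.
#'
#' @param contig A [Biostrings::DNAString], single-element DNAStringSet, or
#'   character scalar.
#' @param min_aa Minimum protein length in residues (default 80; must be
#'   at least 30).
#' @param contig_id Id recorded in the output; defaults to the sequence
#'   name or "contig".
#' @param nonoverlapping Resolve overlapping calls greedily (longest ORF
#'   wins; up to 30 nt overlap tolerated), as gene-content statistics
#'   expect one gene per locus. Default FALSE: report every ORF.
#' @return A data.frame of gene calls: `contig_id`, `start`, `end`,
#'   `strand`, `protein`.
#' @export
find_orfs <- function(contig, min_aa = 80L, contig_id = NULL,
                      nonoverlapping = FALSE) {
  stopifnot(min_aa >= 30L)
  if (is(contig, "XStringSet")) {
    if (is.null(contig_id)) contig_id <- id_or(contig, "contig")
    contig <- contig[[1]]
  }
  if (is.null(contig_id)) contig_id <- "contig"
  s <- normalize_dna(as.character(contig))
  n <- nchar(s)
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (n < (min_aa + 1L) * 3L) return(empty)

  starts_ok <- c("ATG", "GTG", "TTG")
  calls <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else
      as.character(reverseComplement(DNAString(s)))
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < min_aa + 1L) next
      sub <- substr(ss, frame + 1L, frame + 3L * ncod)
      aa <- strsplit(as.character(
        translate(DNAString(sub), genetic.code = getGeneticCode("11"),
                  if.fuzzy.codon = "X", no.init.codon = TRUE)), "")[[1]]
      stops <- which(aa == "*")
      if (!length(stops)) next
      codons <- substring(sub, seq(1L, by = 3L, length.out = ncod),
                          seq(3L, by = 3L, length.out = ncod))
      prev <- 0L
      for (k in stops) {
        seg <- if (k - prev >= min_aa + 1L) (prev + 1L):(k - 1L) else integer(0)
        if (length(seg)) {
          hit <- seg[codons[seg] %in% starts_ok]
          if (length(hit)) {
            i <- hit[1L]
            if (k - i >= min_aa) {
              st <- frame + (i - 1L) * 3L   # 0-based on current strand
              en <- frame + k * 3L
              if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
              calls[[length(calls) + 1L]] <- list(
                contig_id = contig_id, start = st, end = en, strand = strand,
                protein = paste(aa[i:(k - 1L)], collapse = ""))
            }
          }
        }
        prev <- k
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, lapply(calls, as.data.frame, stringsAsFactors = FALSE))
  if (nonoverlapping) out <- filter_overlapping_orfs(out)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy longest-first resolution of overlapping ORF calls; overlaps up to
# max_overlap nt (shared operon boundaries) are tolerated
filter_overlapping_orfs <- function(calls, max_overlap = 30L) {
  if (nrow(calls) <= 1) return(calls)
  ord <- order(-(calls$end - calls$start), calls$start, calls$strand)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      if (ov > max_overlap) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  calls[sort(kept), , drop = FALSE]
}

#' Export gene calls as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive convention of GFF3; features are written as `CDS`.
#'
#' @param calls Gene-call data.frame from [find_orfs()].
#' @param path Output path.
#' @export
write_gff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(calls)) {
    lines <- sprintf("%s\tmetadark\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     calls$contig_id, calls$start + 1L, calls$end,
                     calls$strand,
                     sprintf("%s_orf%04d", calls$contig_id, seq_len(nrow(calls))))
    writeLines(lines, con)
  }
  invisible(path)
}

# substitution matrix over ACGTN: N never matches nor mismatches
.nt_submat <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- 0; m[, "N"] <- 0
  m
})

#' Pairwise alignment with affine gaps
#'
#' Aligns two sequences of the same kind. Nucleotides use match +1 /
#' mismatch -1 / gap open -5 / gap extend -2 (N is neutral: columns with N
#' are excluded from the identity denominator); proteins use BLOSUM62 with
#' gap open -11 / gap extend -1. Identity is computed over aligned columns,
#' coverage as the fraction of the query consumed by the alignment.
#'
#' @param query,subject Character scalars, XString, or single-element
#'   XStringSet objects of the same kind.
#' @param mode "local" or "global".
#' @param kind "nucleotide" or "protein"; guessed from the object class
#'   when the inputs are Biostrings objects.
#' @return A list of class `pairwise_alignment` with fields `query_id`,
#'   `subject_id`, `mode`, `identity` (percent), `query_coverage`
#'   (fraction), `score`.
#' @export
align_pair <- function(query, subject, mode = c("local", "global"),
                       kind = NULL) {
  mode <- match.arg(mode)
  kind_of <- function(x) {
    if (is(x, "AAString") || is(x, "AAStringSet")) "protein"
    else if (is(x, "DNAString") || is(x, "DNAStringSet")) "nucleotide"
    else NA_character_
  }
  kq <- kind_of(query); ks <- kind_of(subject)
  if (!is.na(kq) && !is.na(ks) && kq != ks) {
    stop("query and subject are of different kinds (", kq, " vs ", ks, ")",
         call. = FALSE)
  }
  if (is.null(kind)) kind <- if (!is.na(kq)) kq else "nucleotide"
  qid <- id_or(query, "query")
  sid <- id_or(subject, "subject")
  as_one <- function(x, kind) {
    if (is(x, "XStringSet")) x <- x[[1]]
    if (kind == "nucleotide") DNAString(normalize_dna(as.character(x)))
    else AAString(as.character(x))
  }
  q <- as_one(query, kind); s <- as_one(subject, kind)
  type <- if (mode == "global") "global" else "local"
  pa <- if (kind == "nucleotide") {
    pairwiseAlignment(q, s, type = type, substitutionMatrix = .nt_submat,
                      gapOpening = 5, gapExtension = 2)
  } else {
    pairwiseAlignment(q, s, type = type, substitutionMatrix = "BLOSUM62",
                      gapOpening = 11, gapExtension = 1)
  }
  qlen <- length(q)
  has_n <- kind == "nucleotide" &&
    (grepl("N", as.character(q), fixed = TRUE) ||
     grepl("N", as.character(s), fixed = TRUE))
  if (!has_n) {
    # column counts from C-level accessors (extracting aligned strings is
    # an order of magnitude slower)
    ni <- Biostrings::nindel(pa)
    ins_w <- unname(Biostrings::insertion(ni)[, "WidthSum"])
    del_w <- unname(Biostrings::deletion(ni)[, "WidthSum"])
    nm <- Biostrings::nmatch(pa)
    cols <- nm + Biostrings::nmismatch(pa) + ins_w + del_w
    ident <- if (cols) 100 * nm / cols else 0
    qcov <- if (qlen) (nm + Biostrings::nmismatch(pa) + ins_w) / qlen else 0
  } else {
    ap <- strsplit(as.character(alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(alignedSubject(pa)), "")[[1]]
    keep <- !(ap == "-" & as_ == "-") & ap != "N" & as_ != "N"
    denom <- sum(keep)
    ident <- if (denom) 100 * sum(ap == as_ & ap != "-" & keep) / denom else 0
    qcov <- if (qlen) sum(ap != "-") / qlen else 0
  }
  structure(list(query_id = qid, subject_id = sid, mode = mode,
                 identity = ident, query_coverage = qcov,
                 score = score(pa)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s (%s): identity %.2f%%, coverage %.3f, score %.1f\n",
              x$query_id, x$subject_id, x$mode, x$identity,
              x$query_coverage, x$score))
  invisible(x)
}
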