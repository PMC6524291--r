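# Deterministic synthetic-community generator. Produces reference-panel
# genomes with known ORF coordinates, derived "novel species" genomes at
# controlled substitution rates, gene implants (GH, mobile markers),
# assembly-like contig fragmentation, and spike-in titration series. Every
# generator is seed-deterministic and writes a truth log sufficient to
# score the downstream modules without external data.

.codon_sets <- local({
  gc11 <- Biostrings::getGeneticCode("11")
  split(names(gc11), unname(gc11))
})

#' Simulate a bacterial genome with known gene coordinates
#'
#' Generates an i.i.d. background at the target GC content and implants
#' non-overlapping ORFs (ATG...stop, 300-1500 nt) covering at least the
#' requested fraction of the genome, each preceded by an in-frame stop so
#' that ORF callers recover the exact start. After construction, intergenic
#' bases are minimally adjusted so the realized GC matches the target.
#'
#' @param length Genome length in nt (>= 5000).
#' @param gc Target GC fraction, in (0.2, 0.8).
#' @param seed Integer seed; identical inputs give byte-identical genomes.
#' @param orf_cov Minimum fraction of the genome covered by implanted ORFs.
#' @param id Sequence id for the generated record.
#' @return A list of class `synthetic_genome`: `seq` (character), `id`,
#'   `truth_orfs` (data.frame with 0-based half-open `start`, `end`,
#'   `strand`), `gc`, `seed`.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L, orf_cov = 0.6,
                            id = "synthetic_genome") {
  stopifnot(length >= 5000)
  if (gc <= 0.2 || gc >= 0.8) stop("gc must lie in (0.2, 0.8)", call. = FALSE)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(probs), length, replace = TRUE, prob = probs)
    # carve ORFs into the background: guard stop, start codon, non-stop
    # codons, terminal stop
    orfs <- list()
    pos <- 1L + sample(60:240, 1L)
    orf_bp <- 0L
    while (TRUE) {
      ncod <- sample(100:500, 1L)          # 300-1500 nt incl. stop
      glen <- 3L * ncod
      if (pos + glen + 3L > length - 60L) break
      strand <- sample(c("+", "-"), 1L)
      gene <- .random_cds(ncod, probs)
      block <- c("T", "A", "A", gene)      # in-frame guard precedes start
      if (strand == "-") block <- rev(.COMP[block])
      bases[pos:(pos + glen + 2L)] <- block
      if (strand == "+") {
        start0 <- pos + 2L                 # 0-based start of ATG
        end0 <- pos + 2L + glen
      } else {
        start0 <- pos - 1L
        end0 <- pos - 1L + glen
      }
      orfs[[length(orfs) + 1L]] <- list(start = start0, end = end0,
                                        strand = strand)
      orf_bp <- orf_bp + glen
      pos <- pos + glen + 3L
      gap <- if (orf_bp < orf_cov * length) sample(80:420, 1L)
             else sample(200:900, 1L)
      pos <- pos + gap
    }
    truth <- do.call(rbind, lapply(orfs, as.data.frame))
    # adjust intergenic bases so realized GC hits the target
    in_orf <- rep(FALSE, length)
    for (i in seq_len(nrow(truth)))
      in_orf[(truth$start[i] - 2L):(truth$end[i] + 3L)] <- TRUE
    in_orf <- in_orf[seq_len(length)]
    want_gc <- round(gc * length)
    have_gc <- sum(bases %in% c("G", "C"))
    delta <- want_gc - have_gc
    if (delta > 0) {
      cand <- which(!in_orf & bases %in% c("A", "T"))
      flip <- sample(cand, min(delta, base::length(cand)))
      bases[flip] <- ifelse(bases[flip] == "A", "G", "C")
    } else if (delta < 0) {
      cand <- which(!in_orf & bases %in% c("G", "C"))
      flip <- sample(cand, min(-delta, base::length(cand)))
      bases[flip] <- ifelse(bases[flip] == "G", "A", "T")
    }
    structure(list(seq = paste(bases, collapse = ""), id = id,
                   truth_orfs = truth, gc = gc, seed = as.integer(seed)),
              class = "synthetic_genome")
  })
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# random CDS of ncod codons: ATG + (ncod-2) non-stop codons + TAA,
# codon bases drawn at the genome's base composition (stops rejected)
.random_cds <- function(ncod, probs) {
  body_n <- ncod - 2L
  draw <- function(m) sample(names(probs), m, replace = TRUE, prob = probs)
  n_needed <- 3L * body_n
  out <- character(0)
  while (length(out) < n_needed) {
    b <- draw(ceiling(1.1 * (n_needed - length(out)) / 3) * 3)
    cod <- matrix(b, nrow = 3)
    codstr <- paste0(cod[1, ], cod[2, ], cod[3, ])
    ok <- !(codstr %in% c("TAA", "TAG", "TGA"))
    out <- c(out, as.vector(cod[, ok, drop = FALSE]))
  }
  c("A", "T", "G", out[seq_len(n_needed)], "T", "A", "A")
}

#' Mutate a genome at a controlled per-site substitution rate
#'
#' Each site is substituted independently with probability `sub_rate`,
#' drawing uniformly among the three alternative bases, so the expected
#' nucleotide identity to the parent is `100 * (1 - sub_rate)`. Optional
#' small indels can be layered on top.
#'
#' @param genome A `synthetic_genome`, character scalar, or DNAString.
#' @param sub_rate Per-site substitution probability in [0, 0.3].
#' @param seed Integer seed.
#' @param indel_rate Optional per-site rate of 1-3 nt insertions/deletions.
#' @param preserve_orfs Emulate purifying selection on the truth ORFs:
#'   start/stop codons and the flanking in-frame guard stops are never
#'   mutated, and a substitution that would introduce an in-frame stop
#'   inside an ORF is redirected to another alternative base. Gene content
#'   then survives divergence (the realized identity is marginally above
#'   `100*(1-sub_rate)` because ~1% of sites are protected). Requires a
#'   `synthetic_genome` with a truth log.
#' @return A list of class `synthetic_genome` (truth_orfs dropped when
#'   indels shift coordinates) with `n_substitutions` recording the
#'   realized substitution count.
#' @export
mutate_genome <- function(genome, sub_rate, seed = 1L, indel_rate = 0,
                          preserve_orfs = FALSE) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.3)
  s <- if (inherits(genome, "synthetic_genome")) genome$seq
       else as.character(genome)
  id <- if (inherits(genome, "synthetic_genome")) genome$id else "genome"
  truth <- if (inherits(genome, "synthetic_genome")) genome$truth_orfs
           else NULL
  if (preserve_orfs && is.null(truth))
    stop("preserve_orfs requires a synthetic_genome with a truth log",
         call. = FALSE)
  with_seed(seed, {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    protected <- rep(FALSE, n)
    if (preserve_orfs && nrow(truth)) {
      for (r in seq_len(nrow(truth))) {
        s0 <- truth$start[r]; e0 <- truth$end[r]
        ends <- c((s0 - 2L):(s0 + 3L), (e0 - 2L):(e0 + 3L))
        ends <- ends[ends >= 1L & ends <= n]
        protected[ends] <- TRUE
      }
    }
    hit <- which(runif(n) < sub_rate & !protected)
    if (length(hit)) {
      alt <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
      b[hit] <- alt
    }
    if (preserve_orfs && length(hit) && nrow(truth))
      b <- .fix_orf_stops(b, truth, hit)
    nsub <- length(hit)
    if (indel_rate > 0) {
      sites <- which(runif(n) < indel_rate)
      if (length(sites)) {
        pieces <- character(0)
        prev <- 1L
        for (p in sites) {
          if (runif(1) < 0.5) {             # insertion after p
            ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                                replace = TRUE), collapse = "")
            pieces <- c(pieces, paste(b[prev:p], collapse = ""), ins)
            prev <- p + 1L
          } else {                          # deletion of 1-3 nt at p
            dl <- sample(1:3, 1L)
            if (p > prev) pieces <- c(pieces, paste(b[prev:(p - 1L)], collapse = ""))
            prev <- min(p + dl, n + 1L)
          }
        }
        if (prev <= n) pieces <- c(pieces, paste(b[prev:n], collapse = ""))
        b <- strsplit(paste(pieces, collapse = ""), "")[[1]]
      }
    }
    structure(list(seq = paste(b, collapse = ""),
                   id = paste0(id, "_mut"),
                   truth_orfs = if (indel_rate == 0 &&
                                    inherits(genome, "synthetic_genome"))
                     genome$truth_orfs else NULL,
                   n_substitutions = nsub, sub_rate = sub_rate,
                   seed = as.integer(seed)),
              class = "synthetic_genome")
  })
}

# redirect substitutions that created an in-frame stop inside a truth ORF
# to the first alternative base (in ACGT order) that avoids one
.fix_orf_stops <- function(b, truth, hit) {
  stops <- c("TAA", "TAG", "TGA")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(nrow(truth))) {
    s0 <- truth$start[r]; e0 <- truth$end[r]; strand <- truth$strand[r]
    inside <- hit[hit > s0 + 3L & hit <= e0 - 3L]   # 1-based body positions
    for (p in inside) {
      p0 <- p - 1L
      if (strand == "+") {
        cs <- s0 + 3L * ((p0 - s0) %/% 3L)           # codon 0-based start
        codon <- function() paste(b[(cs + 1L):(cs + 3L)], collapse = "")
      } else {
        cidx <- (e0 - 1L - p0) %/% 3L
        hi <- e0 - 3L * cidx                          # 1-based top of codon
        codon <- function() paste(comp[b[c(hi, hi - 1L, hi - 2L)]],
                                  collapse = "")
      }
      if (codon() %in% stops) {
        for (alt in c("A", "C", "G", "T")) {
          b[p] <- alt
          if (!codon() %in% stops) break
        }
      }
    }
  }
  b
}

#' Reverse-translate a protein with uniform synonymous codons
#'
#' @param protein Amino-acid string (no stops).
#' @param seed Integer seed.
#' @return Nucleotide string: ATG-initiated CDS ending in TAA (the
#'   protein's own first residue is encoded as ATG when it is M).
#' @export
reverse_translate <- function(protein, seed = 1L) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  stopifnot(!"*" %in% aa)
  with_seed(seed, {
    cods <- vapply(aa, function(a) {
      set <- .codon_sets[[a]]
      if (is.null(set)) stop("cannot reverse-translate residue '", a, "'",
                             call. = FALSE)
      set[sample.int(length(set), 1L)]
    }, character(1))
    if (aa[1] == "M") cods[1] <- "ATG"
    paste(c(if (aa[1] != "M") "ATG", cods, "TAA"), collapse = "")
  })
}

#' Implant protein-coding genes into a genome
#'
#' Each protein is reverse-translated and spliced into the genome at a
#' random intergenic site (never inside a truth ORF), preceded by an
#' in-frame stop. Existing truth coordinates are shifted accordingly and
#' the implants are appended to the truth log with their labels.
#'
#' @param genome A `synthetic_genome`.
#' @param proteins Named character vector of amino-acid sequences; names
#'   become implant labels in the truth log.
#' @param seed Integer seed.
#' @return The genome with `truth_implants` (data.frame: label, start, end,
#'   strand, 0-based half-open) and updated `truth_orfs`.
#' @export
implant_genes <- function(genome, proteins, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"), length(proteins) >= 1)
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    stop("proteins must be named (labels carried into the truth log)",
         call. = FALSE)
  with_seed(seed, {
    truth <- genome$truth_orfs
    n <- nchar(genome$seq)
    busy <- rep(FALSE, n)
    if (!is.null(truth) && nrow(truth))
      for (i in seq_len(nrow(truth)))
        busy[max(1L, truth$start[i] - 2L):min(n, truth$end[i] + 3L)] <- TRUE
    free <- which(!busy)
    if (length(free) < length(proteins))
      stop("genome too crowded to host implants", call. = FALSE)
    sites <- sort(sample(free, length(proteins)))
    inserts <- vapply(seq_along(proteins), function(i) {
      cds <- reverse_translate(proteins[[i]], seed = derive_seed(seed, names(proteins)[i]))
      paste0("TAA", cds)
    }, character(1))
    # splice in increasing site order, tracking cumulative shift
    pieces <- character(0)
    prev <- 1L
    shift <- 0L
    implants <- list()
    for (i in seq_along(sites)) {
      p <- sites[i]
      pieces <- c(pieces, substr(genome$seq, prev, p), inserts[i])
      start0 <- p + shift + 3L              # skip the TAA guard (0-based)
      implants[[i]] <- data.frame(label = names(proteins)[i],
                                  start = start0,
                                  end = start0 + nchar(inserts[i]) - 3L,
                                  strand = "+")
      shift <- shift + nchar(inserts[i])
      prev <- p + 1L
    }
    pieces <- c(pieces, substr(genome$seq, prev, n))
    newseq <- paste(pieces, collapse = "")
    if (!is.null(truth) && nrow(truth)) {
      shifts <- vapply(truth$start, function(s0)
        sum(nchar(inserts)[sites <= s0]), numeric(1))
      truth$start <- truth$start + as.integer(shifts)
      truth$end <- truth$end + as.integer(shifts)
    }
    out <- genome
    out$seq <- newseq
    out$truth_orfs <- truth
    out$truth_implants <- do.call(rbind, implants)
    out
  })
}

#' Fragment a genome into assembly-like contigs
#'
#' Draws random breakpoints until the realized N50 lies within 20% of the
#' target; total bp is conserved exactly and each contig's source interval
#' is recorded for truth-based scoring.
#'
#' @param genome A `synthetic_genome` or character scalar.
#' @param n50 Target N50 in nt (>= 2000).
#' @param seed Integer seed.
#' @param prefix Contig id prefix.
#' @return List: `contigs` (DNAStringSet), `truth` (data.frame: contig_id,
#'   source, src_start, src_end, 0-based half-open), `n50`.
#' @export
fragment_contigs <- function(genome, n50, seed = 1L, prefix = NULL) {
  stopifnot(n50 >= 2000)
  s <- if (inherits(genome, "synthetic_genome")) genome$seq
       else as.character(genome)
  gid <- if (inherits(genome, "synthetic_genome")) genome$id else "genome"
  if (is.null(prefix)) prefix <- gid
  n <- nchar(s)
  with_seed(seed, {
    mean_len <- n50 / 1.65                 # Poisson breakage heuristic
    for (try in 1:40) {
      lens <- integer(0)
      tot <- 0L
      while (tot < n) {
        l <- max(300L, ceiling(stats::rexp(1, 1 / mean_len)))
        lens <- c(lens, l)
        tot <- tot + l
      }
      lens[length(lens)] <- lens[length(lens)] - (tot - n)
      if (lens[length(lens)] < 300L && length(lens) > 1L) {
        lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
        lens <- lens[-length(lens)]
      }
      realized <- .n50(lens)
      if (abs(realized - n50) <= 0.2 * n50) break
      mean_len <- mean_len * n50 / realized
    }
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    contigs <- substring(s, starts, ends)
    ids <- sprintf("%s_ctg%04d", prefix, seq_along(contigs))
    dss <- DNAStringSet(contigs)
    names(dss) <- ids
    list(contigs = dss,
         truth = data.frame(contig_id = ids, source = gid,
                            src_start = starts - 1L, src_end = ends,
                            stringsAsFactors = FALSE),
         n50 = .n50(lens))
  })
}

.n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Simulate a metagenomic community as assembled contigs
#'
#' Realizes a community specification: each member contributes contigs at
#' its relative bp abundance, drawn from its own genome or from a genome
#' derived from a reference at a controlled substitution rate (a "novel
#' species" relative to the panel). Contigs carry the member id in the
#' truth log.
#'
#' @param members data.frame with columns `id`, `abundance` (fractions
#'   summing to 1), optional `source` (name in `genomes`), optional
#'   `sub_rate` (divergence applied to the source genome; 0 or NA means
#'   use it verbatim), optional `is_novel` (logical, truth label only).
#' @param genomes Named list of genomes (`synthetic_genome` or character)
#'   referenced by `members$source` (default: by `members$id`).
#' @param total_bp Approximate total community size in bp.
#' @param n50 Target contig N50.
#' @param seed Integer seed.
#' @return List: `contigs` (DNAStringSet), `truth` (data.frame contig_id,
#'   member, is_novel), `members`.
#' @export
simulate_community <- function(members, genomes, total_bp = 2e6,
                               n50 = 8000L, seed = 1L) {
  stopifnot(abs(sum(members$abundance) - 1) < 1e-6)
  if (is.null(members$source)) members$source <- members$id
  if (is.null(members$sub_rate)) members$sub_rate <- 0
  if (is.null(members$is_novel)) members$is_novel <- FALSE
  all_ctg <- NULL
  truth <- list()
  for (r in seq_len(nrow(members))) {
    src <- genomes[[members$source[r]]]
    if (is.null(src)) stop("unknown source genome: ", members$source[r],
                           call. = FALSE)
    sr <- members$sub_rate[r]
    g <- if (!is.na(sr) && sr > 0)
      mutate_genome(src, sr, seed = derive_seed(seed, paste0("mut_", members$id[r])))
    else src
    frag <- fragment_contigs(g, n50 = n50,
                             seed = derive_seed(seed, paste0("frag_", members$id[r])),
                             prefix = members$id[r])
    want <- round(members$abundance[r] * total_bp)
    w <- width(frag$contigs)
    ord <- with_seed(derive_seed(seed, paste0("pick_", members$id[r])),
                     sample.int(length(w)))
    k <- which(cumsum(w[ord]) >= want)[1]
    if (is.na(k)) k <- length(w)
    pick <- frag$contigs[ord[seq_len(k)]]
    excess <- sum(width(pick)) - want
    if (excess > 0 && width(pick)[k] - excess >= 2000)
      pick[k] <- subseq(pick[k], 1L, width(pick)[k] - excess)
    truth[[r]] <- data.frame(contig_id = seq_ids(pick),
                             member = members$id[r],
                             is_novel = members$is_novel[r],
                             stringsAsFactors = FALSE)
    all_ctg <- if (is.null(all_ctg)) pick else c(all_ctg, pick)
  }
  list(contigs = all_ctg, truth = do.call(rbind, truth), members = members)
}

#' Build a spike-in titration series
#'
#' Mixes contigs of a target genome into a background contig set at each
#' requested bp fraction of the combined dataset. The target genome is
#' fragmented once; for each fraction a prefix of its contigs is taken and
#' the last contig trimmed so the spiked bp matches the requested fraction
#' as closely as contig granularity allows (never below 300 nt).
#'
#' @param background A DNAStringSet of background contigs.
#' @param target_genome A `synthetic_genome` or character scalar.
#' @param fractions Strictly decreasing bp fractions, e.g.
#'   `c(0.1, 0.01, 0.001, 1e-4)`.
#' @param seed Integer seed.
#' @param target_n50 N50 used when fragmenting the target genome.
#' @return A list with one element per fraction: `contigs` (background +
#'   spike), `fraction` (requested), `realized` (achieved bp fraction),
#'   `spike_ids`.
#' @export
spike_in_titration <- function(background, target_genome, fractions,
                               seed = 1L, target_n50 = 3000L) {
  stopifnot(all(diff(fractions) < 0), all(fractions > 0), all(fractions < 1))
  bg_bp <- sum(width(background))
  frag <- fragment_contigs(target_genome, n50 = target_n50,
                           seed = derive_seed(seed, "spike"),
                           prefix = "spike")
  tl <- width(frag$contigs)
  lapply(fractions, function(f) {
    want <- max(300, round(f / (1 - f) * bg_bp))
    k <- which(cumsum(tl) >= want)[1]
    if (is.na(k)) k <- length(tl)
    pick <- frag$contigs[seq_len(k)]
    excess <- sum(width(pick)) - want
    if (excess > 0 && width(pick)[k] - excess >= 300) {
      pick[k] <- subseq(pick[k], 1L, width(pick)[k] - excess)
    }
    ids <- paste0(seq_ids(pick), sprintf("_f%g", f))
    names(pick) <- ids
    all <- c(background, pick)
    list(contigs = all, fraction = f,
         realized = sum(width(pick)) / sum(width(all)),
         spike_ids = ids)
  })
}
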