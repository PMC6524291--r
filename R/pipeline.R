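# End-to-end orchestration: discovery (bin -> filter to target genus ->
# novelty screen -> glycobiome -> substrate recommendation) and
# confirmation (ITS triage, ANI vs the panel with the species boundary,
# and core-genome NJ placement of isolates). Reports are deterministic
# JSON; per-stage TSV/FASTA artifacts are written alongside.

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline plus the seed. Unknown
#' keys are rejected so silent typos cannot change an analysis.
#'
#' @param target_genus Genus whose dark matter is being mined.
#' @param seed Integer seed for all stochastic steps.
#' @param min_aa Minimum ORF length (residues).
#' @param min_identity,min_cov Protein search thresholds.
#' @param thresholds A [screen_thresholds()] object.
#' @param gh_min_identity,gh_min_cov GH assignment thresholds.
#' @param min_fraction Abundance reporting floor.
#' @param its_species_identity,its_min_cov ITS assignment thresholds.
#' @param ani_fragment_len ANI fragment length (nt).
#' @param boot_reps Bootstrap replicates for the confirmation tree.
#' @param ... Rejected: any unknown key is an error.
#' @return List of class `run_config`.
#' @export
run_config <- function(target_genus = "Bifidobacterium", seed = 1L,
                       min_aa = 80L, min_identity = 30, min_cov = 0.5,
                       thresholds = screen_thresholds(),
                       gh_min_identity = 40, gh_min_cov = 0.7,
                       min_fraction = 0.002,
                       its_species_identity = 98, its_min_cov = 0.9,
                       ani_fragment_len = 1020L, boot_reps = 100L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config keys: ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  structure(list(target_genus = target_genus, seed = as.integer(seed),
                 min_aa = as.integer(min_aa), min_identity = min_identity,
                 min_cov = min_cov, thresholds = thresholds,
                 gh_min_identity = gh_min_identity, gh_min_cov = gh_min_cov,
                 min_fraction = min_fraction,
                 its_species_identity = its_species_identity,
                 its_min_cov = its_min_cov,
                 ani_fragment_len = as.integer(ani_fragment_len),
                 boot_reps = as.integer(boot_reps)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Threshold keys under `thresholds:` feed [screen_thresholds()]; all
#' other keys feed [run_config()]. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- if (!is.null(y$thresholds)) do.call(screen_thresholds, y$thresholds)
        else screen_thresholds()
  y$thresholds <- NULL
  do.call(run_config, c(y, list(thresholds = th)))
}

.config_hash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  x <- paste(names(flat), flat, sep = "=", collapse = ";")
  # small deterministic polynomial hash; provenance only
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 268435399
  sprintf("%07x", h)
}

#' Discovery pipeline: bin, screen, profile the glycobiome, recommend
#' substrates
#'
#' Classifies every contig to genus, restricts to the configured target
#' genus, runs the novelty screen, profiles GH families on the putative
#' novel ("dark matter") contigs, and ranks candidate carbon sources for
#' selective cultivation. When the target genus falls below the abundance
#' reporting floor the report flags insufficient dark matter and suggests
#' a spike-in titration analysis instead.
#'
#' @param contigs DNAStringSet of assembled contigs (non-empty).
#' @param panel A `reference_panel`.
#' @param config A [run_config()].
#' @param outdir Optional directory for per-stage TSV/FASTA/JSON
#'   artifacts.
#' @return List of class `discovery_report`.
#' @export
run_discovery <- function(contigs, panel, config = run_config(),
                          outdir = NULL) {
  if (length(contigs) == 0)
    stop("empty contig set: nothing to analyze", call. = FALSE)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  assignments <- stage("binning", classify_sample(
    contigs, panel, min_aa = config$min_aa,
    min_identity = config$min_identity, min_cov = config$min_cov))
  profile <- stage("binning", abundance_profile(
    assignments, min_fraction = config$min_fraction))
  target_frac <- unname(profile$fractions[config$target_genus])
  if (is.na(target_frac)) target_frac <- 0

  target_ids <- assignments$seq_id[assignments$genus == config$target_genus]
  target_contigs <- contigs[seq_ids(contigs) %in% target_ids]
  low_abundance <- target_frac < config$min_fraction

  screen <- if (length(target_contigs)) {
    stage("novelty_screen", screen_sample(
      target_contigs, panel, config$thresholds,
      novel_fasta = if (!is.null(outdir))
        file.path(outdir, "novel_candidates.fasta") else NULL,
      min_aa = config$min_aa))
  } else NULL

  gh_profile <- NULL; substrates <- NULL
  if (!is.null(screen)) {
    novel_ids <- screen$verdicts$contig_id[
      screen$verdicts$status == "novel_candidate"]
    novel_contigs <- target_contigs[seq_ids(target_contigs) %in% novel_ids]
    if (length(novel_contigs)) {
      calls <- stage("glycobiome", do.call(rbind, lapply(
        seq_along(novel_contigs), function(i)
          find_orfs(novel_contigs[[i]], min_aa = config$min_aa,
                    contig_id = seq_ids(novel_contigs)[i],
                    nonoverlapping = TRUE))))
      if (!is.null(calls) && nrow(calls)) {
        prot <- setNames(calls$protein,
                         sprintf("%s_g%03d", calls$contig_id,
                                 seq_len(nrow(calls))))
        gh <- stage("glycobiome", assign_gh(
          prot, panel$gh_reference,
          min_identity = config$gh_min_identity,
          min_cov = config$gh_min_cov))
        gh_profile <- glycobiome_profile(gh)
        substrates <- recommend_substrates(gh_profile)
      }
    }
  }

  report <- structure(list(
    tool = "metadark", version = as.character(packageVersion("metadark")),
    config_hash = .config_hash(config), seed = config$seed,
    target_genus = config$target_genus,
    abundance = as.list(profile$fractions),
    target_fraction = target_frac,
    low_abundance = low_abundance,
    note = if (low_abundance)
      "target genus below reporting floor: insufficient dark matter; consider a spike-in titration analysis" else NULL,
    screen_summary = if (!is.null(screen)) screen$summary else NULL,
    gh_rel_abund = if (!is.null(gh_profile))
      as.list(gh_profile$rel_abund) else NULL,
    substrates = if (!is.null(substrates)) substrates$ranking else NULL,
    assignments = assignments,
    screen = screen, gh_profile = gh_profile), class = "discovery_report")

  if (!is.null(outdir)) {
    write.table(assignments, file.path(outdir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_profile_json(profile, file.path(outdir, "abundance.json"))
    if (!is.null(screen))
      write_screen_report(screen,
                          tsv = file.path(outdir, "verdicts.tsv"),
                          json = file.path(outdir, "screen.json"))
    write_discovery_json(report, file.path(outdir, "discovery.json"))
  }
  report
}

#' Serialize a discovery report as canonical JSON
#'
#' Deterministic given the same inputs, config and seed: no timestamps.
#'
#' @param report A `discovery_report`.
#' @param path Output path.
#' @export
write_discovery_json <- function(report, path) {
  out <- report[c("tool", "version", "config_hash", "seed", "target_genus",
                  "abundance", "target_fraction", "low_abundance", "note",
                  "screen_summary", "gh_rel_abund", "substrates")]
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("<discovery_report> target %s: %.3f%% of assembled bp%s\n",
              x$target_genus, 100 * x$target_fraction,
              if (isTRUE(x$low_abundance)) " (below reporting floor)" else ""))
  if (!is.null(x$screen_summary)) {
    for (i in seq_len(nrow(x$screen_summary)))
      cat(sprintf("  %-16s %4d contigs %12.0f bp\n",
                  x$screen_summary$status[i], x$screen_summary$n[i],
                  x$screen_summary$bp[i]))
  }
  if (!is.null(x$substrates) && nrow(x$substrates))
    cat("  recommended substrates:",
        paste(x$substrates$substrate, collapse = ", "), "\n")
  invisible(x)
}

#' Confirmation pipeline: ITS triage, ANI boundary calls, NJ placement
#'
#' For each isolate genome: optional ITS verdict, the nearest panel genome
#' by reciprocal ANI with the species-boundary call, and a core-genome NJ
#' tree of panel + isolates with bootstrap supports.
#'
#' @param isolates Named list of isolate genomes (any form accepted by
#'   [compute_ani()]).
#' @param panel A `reference_panel`.
#' @param config A [run_config()].
#' @param isolate_its Optional DNAStringSet of isolate ITS sequences named
#'   by isolate id.
#' @param outgroup Optional genome id used to root the tree.
#' @param outdir Optional artifact directory.
#' @return List of class `confirmation_report`.
#' @export
run_confirmation <- function(isolates, panel, config = run_config(),
                             isolate_its = NULL, outgroup = NULL,
                             outdir = NULL) {
  stopifnot(length(isolates) >= 1, !is.null(names(isolates)))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  its_calls <- NULL
  if (!is.null(isolate_its) && !is.null(panel$its))
    its_calls <- classify_its_batch(isolate_its, panel$its,
                                    species_identity = config$its_species_identity,
                                    min_cov = config$its_min_cov)
  ani_rows <- list()
  for (iso in names(isolates)) {
    best <- NULL
    for (g in names(panel$genomes)) {
      r <- compute_ani(isolates[[iso]], panel$genomes[[g]],
                       fragment_len = config$ani_fragment_len,
                       query_id = iso, subject_id = g)
      v <- if (r$no_homology) NA_real_ else r$reciprocal_ani
      if (is.null(best) || (!is.na(v) && (is.na(best$ani) || v > best$ani)))
        best <- list(genome = g, ani = v)
    }
    ani_rows[[iso]] <- data.frame(
      isolate = iso, nearest_genome = best$genome,
      nearest_species = panel_species(panel, best$genome),
      reciprocal_ani = best$ani,
      boundary_call = species_boundary(
        if (is.na(best$ani)) NA_real_ else best$ani),
      stringsAsFactors = FALSE)
  }
  ani_table <- do.call(rbind, ani_rows)
  rownames(ani_table) <- NULL

  # placement tree over panel + isolates
  proteomes <- panel$proteins
  for (iso in names(isolates)) {
    g <- isolates[[iso]]
    s <- if (inherits(g, "synthetic_genome")) g$seq else
      paste(as.character(g), collapse = "")
    calls <- find_orfs(s, min_aa = config$min_aa, contig_id = iso,
                       nonoverlapping = TRUE)
    aa <- AAStringSet(calls$protein)
    if (length(aa)) names(aa) <- sprintf("%s|orf%04d", iso, seq_len(length(aa)))
    proteomes[[iso]] <- aa
  }
  tree <- NULL; boot <- NULL; core <- NULL
  if (length(proteomes) >= 3) {
    clusters <- cluster_orthologs(proteomes)
    core <- core_single_copy(clusters)
    if (core$n_single_copy >= 1) {
      pd <- core_gene_pdistances(clusters, proteomes,
                                 single_copy = core$single_copy_core)
      boot <- bootstrap_supports(pd, n_reps = config$boot_reps,
                                 seed = config$seed, outgroup = outgroup)
      tree <- boot$tree
    }
  }
  report <- structure(list(
    tool = "metadark", version = as.character(packageVersion("metadark")),
    config_hash = .config_hash(config), seed = config$seed,
    its = its_calls, ani = ani_table,
    core = if (!is.null(core))
      core[c("n_core", "n_single_copy", "n_paralogous_core")] else NULL,
    newick = if (!is.null(tree)) ape::write.tree(tree) else NULL,
    bootstrap = boot), class = "confirmation_report")
  if (!is.null(outdir)) {
    if (!is.null(its_calls))
      write.table(its_calls, file.path(outdir, "its_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ani_table, file.path(outdir, "ani.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(tree)) write_newick(tree, file.path(outdir, "tree.nwk"))
    write_confirmation_json(report, file.path(outdir, "confirmation.json"))
  }
  report
}

#' Serialize a confirmation report as canonical JSON
#'
#' @param report A `confirmation_report`.
#' @param path Output path.
#' @export
write_confirmation_json <- function(report, path) {
  out <- report[c("tool", "version", "config_hash", "seed", "its", "ani",
                  "core", "newick")]
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.confirmation_report <- function(x, ...) {
  cat("<confirmation_report>\n")
  for (i in seq_len(nrow(x$ani)))
    cat(sprintf("  %s: nearest %s (ANI %.2f%%) -> %s\n",
                x$ani$isolate[i], x$ani$nearest_species[i],
                x$ani$reciprocal_ani[i], x$ani$boundary_call[i]))
  if (!is.null(x$newick)) cat("  tree:", x$newick, "\n")
  invisible(x)
}
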