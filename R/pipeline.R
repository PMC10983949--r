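# End-to-end orchestration: conservation -> transcript construction ->
# structure gating, with per-stage TSV outputs and a machine-readable JSON
# summary. The pipeline itself is deterministic (all randomness lives in the
# fixture generator), so re-running on unchanged inputs reproduces identical
# outputs byte for byte.

#' Pipeline configuration
#'
#' @param source_genome,source_annotation Source genome FASTA and GTF.
#' @param uorf_table uORF definition TSV (see [read_uorf_table()]).
#' @param targets Named list of `list(genome=, annotation=)` paths for the
#'   target genomes.
#' @param junction_bed Coverage-backed junction BED (optional).
#' @param scored_junctions Scored candidate junction TSV (optional).
#' @param plddt_dir Directory of per-protein pLDDT profiles (optional; the
#'   structure stage is skipped without it).
#' @param out_dir Output directory.
#' @param min_avg_junction_score Mean donor/acceptor score threshold for
#'   predicted junctions (default 0.9).
#' @param min_cds_ratio CDS length-ratio filter threshold (default 0.9).
#' @param plddt_band Half-width of the pLDDT "no change" band (default 1).
#' @param locus_distance_bp Displacement threshold for the conservation
#'   exception (default 1000).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(source_genome, source_annotation, uorf_table,
                            targets, junction_bed = NULL,
                            scored_junctions = NULL, plddt_dir = NULL,
                            out_dir = "uorfconnect_out",
                            min_avg_junction_score = 0.9,
                            min_cds_ratio = 0.9, plddt_band = 1.0,
                            locus_distance_bp = 1000) {
  cfg <- list(
    source_genome = source_genome, source_annotation = source_annotation,
    uorf_table = uorf_table, targets = targets,
    junction_bed = junction_bed, scored_junctions = scored_junctions,
    plddt_dir = plddt_dir, out_dir = out_dir,
    min_avg_junction_score = min_avg_junction_score,
    min_cds_ratio = min_cds_ratio, plddt_band = plddt_band,
    locus_distance_bp = locus_distance_bp
  )
  if (any(c(cfg$min_avg_junction_score, cfg$min_cds_ratio, cfg$plddt_band,
            cfg$locus_distance_bp) <= 0)) {
    abort("pipeline thresholds must be positive")
  }
  for (p in c(source_genome, source_annotation, uorf_table)) {
    if (!file.exists(p)) abort(sprintf("input file does not exist: %s", p))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration for a generated fixture directory
#' @param fixture A `uorf_fixture` object or fixture directory path.
#' @param out_dir Output directory.
#' @param ... Threshold overrides passed to [pipeline_config()].
#' @export
fixture_pipeline_config <- function(fixture, out_dir = file.path(tempdir(), "uorfconnect_out"), ...) {
  dir <- if (inherits(fixture, "uorf_fixture")) fixture$dir else fixture
  tnames <- list.dirs(file.path(dir, "targets"), recursive = FALSE)
  targets <- setNames(
    purrr::map(tnames, ~ list(genome = file.path(.x, "genome.fa"),
                              annotation = file.path(.x, "annotation.gtf"))),
    basename(tnames)
  )
  pipeline_config(
    source_genome = file.path(dir, "source", "genome.fa"),
    source_annotation = file.path(dir, "source", "annotation.gtf"),
    uorf_table = file.path(dir, "uorfs.tsv"),
    targets = targets,
    junction_bed = file.path(dir, "junctions.bed"),
    scored_junctions = file.path(dir, "scored_junctions.tsv"),
    plddt_dir = file.path(dir, "plddt"),
    out_dir = out_dir, ...
  )
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full uORF-connected-transcript pipeline
#'
#' Stages: (1) conservation assessment of every uORF in every target genome;
#' (2) construction of uORF-connected transcripts from coverage-backed and
#' score-predicted junctions, with the three validity filters; (3) average
#' pLDDT gating of passing transcripts against their references. Writes
#' per-stage TSVs, the retained-transcript GTF and protein FASTA, and a JSON
#' report of all counts.
#'
#' @param config A [pipeline_config()] (or [fixture_pipeline_config()]).
#' @return A `uorf_pipeline_result` with the stage objects and the report.
#' @export
run_uorf_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome_fasta(config$source_genome)
  annot <- read_annotation(config$source_annotation)
  uorfs <- hydrate_uorfs(read_uorf_table(config$uorf_table), genome)
  stage_msg("load", "%d uORFs, %d chromosomes, %d target genomes",
            nrow(uorfs), length(genome), length(config$targets))

  conservation <- assess_conservation(
    uorfs, config$targets,
    locus_distance_bp = config$locus_distance_bp
  )
  write_conservation_tsvs(conservation, config$out_dir)
  stage_msg("conserve", "%d/%d uORFs conserved in all targets",
            glance(conservation)$n_conserved_all, nrow(uorfs))

  cov_jx <- if (!is.null(config$junction_bed) && file.exists(config$junction_bed)) {
    load_junctions(config$junction_bed, uorfs, annot, genome)
  } else {
    tibble(chrom = character(), donor = integer(), acceptor = integer(),
           strand = character(), coverage = integer(), uorf_id = character(),
           provenance = character(), donor_score = double(), acceptor_score = double())
  }
  pred_jx <- NULL
  if (!is.null(config$scored_junctions) && file.exists(config$scored_junctions)) {
    scorer <- scorer_from_table(read_scored_junctions(config$scored_junctions))
    pred_jx <- purrr::map(seq_len(nrow(uorfs)), function(i) {
      u <- uorfs[i, ]
      donors <- scan_donor_candidates(u, genome)
      if (nrow(donors) == 0) return(NULL)
      pair_and_score(donors, annot, u$host_transcript_id, scorer,
                     known = cov_jx, min_avg_score = config$min_avg_junction_score)
    }) |> purrr::compact() |> bind_rows()
  }
  junctions <- bind_rows(
    select(cov_jx, "chrom", "donor", "acceptor", "strand", "coverage",
           "uorf_id", "provenance", "donor_score", "acceptor_score"),
    pred_jx
  )
  stage_msg("build", "%d coverage-backed + %d score-predicted junctions",
            nrow(cov_jx), if (is.null(pred_jx)) 0L else nrow(pred_jx))

  transcripts <- build_transcripts(uorfs, junctions, annot, genome,
                                   min_cds_ratio = config$min_cds_ratio)
  stage_msg("build", "%d candidates, %d passed the validity filters",
            nrow(transcripts$candidates), sum(transcripts$candidates$passed))

  structure <- NULL
  retained_ids <- transcripts$candidates$transcript_id[transcripts$candidates$passed]
  if (!is.null(config$plddt_dir) && dir.exists(config$plddt_dir) &&
      sum(transcripts$candidates$passed) > 0) {
    pairs <- transcripts$candidates |>
      filter(.data$passed) |>
      mutate(novel_id = .data$transcript_id,
             reference_id = .data$reference_transcript_id) |>
      select("novel_id", "reference_id", "uorf_id", "provenance")
    structure <- compare_structures(pairs, config$plddt_dir, band = config$plddt_band)
    readr::write_tsv(structure$comparisons,
                     file.path(config$out_dir, "structure_comparisons.tsv"))
    retained_ids <- structure$comparisons$novel_id[structure$comparisons$verdict != "eliminated"]
    stage_msg("evaluate", "%d/%d transcripts retained by the pLDDT gate",
              length(retained_ids), nrow(pairs))
  }
  write_transcript_outputs(transcripts, config$out_dir, ids = retained_ids)

  cov <- coverage_summary(transcripts, retained_ids)
  tally <- if (!is.null(structure)) tally_retention(structure$comparisons) else NULL
  cand <- transcripts$candidates
  retained <- cand[cand$transcript_id %in% retained_ids, ]
  all_key <- paste(sort(conservation$targets), collapse = ",")
  n_all <- conservation$intersections$subsets$n_uorfs[
    conservation$intersections$subsets$subset == all_key]
  report <- list(
    n_uorfs = nrow(uorfs),
    conservation = list(
      per_genome = conservation$intersections$per_genome,
      intersections = conservation$intersections$subsets,
      n_conserved_all_targets = if (length(n_all)) n_all else 0L
    ),
    transcripts = list(
      n_candidates = nrow(cand),
      n_candidates_coverage = sum(cand$provenance == "coverage_backed"),
      n_candidates_predicted = sum(cand$provenance == "score_predicted"),
      n_passed_filters = sum(cand$passed),
      n_retained = nrow(retained),
      n_retained_coverage = sum(retained$provenance == "coverage_backed"),
      n_retained_predicted = sum(retained$provenance == "score_predicted"),
      n_uorfs_retained_union = dplyr::n_distinct(retained$uorf_id)
    ),
    structure = if (!is.null(tally)) list(
      per_stream = tally$per_stream,
      n_retained_total = tally$n_retained_total,
      n_uorfs_union = tally$n_uorfs_union
    ),
    coverage = as.list(cov),
    thresholds = config[c("min_avg_junction_score", "min_cds_ratio",
                          "plddt_band", "locus_distance_bp")]
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(config = config, conservation = conservation,
              transcripts = transcripts, structure = structure,
              retained_ids = retained_ids, report = report)
  class(out) <- "uorf_pipeline_result"
  out
}

#' @export
print.uorf_pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<uorf_pipeline_result>\n")
  cat(sprintf("  uORFs assessed:        %d\n", r$n_uorfs))
  cat(sprintf("  conserved in all:      %d\n", r$conservation$n_conserved_all_targets))
  cat(sprintf("  candidate transcripts: %d (%d coverage, %d predicted)\n",
              r$transcripts$n_candidates, r$transcripts$n_candidates_coverage,
              r$transcripts$n_candidates_predicted))
  cat(sprintf("  retained transcripts:  %d from %d distinct uORFs\n",
              r$transcripts$n_retained, r$transcripts$n_uorfs_retained_union))
  invisible(x)
}

#' @export
glance.uorf_pipeline_result <- function(x, ...) {
  r <- x$report
  tibble(
    n_uorfs = r$n_uorfs,
    n_conserved_all_targets = r$conservation$n_conserved_all_targets,
    n_candidates = r$transcripts$n_candidates,
    n_retained = r$transcripts$n_retained,
    n_uorfs_retained_union = r$transcripts$n_uorfs_retained_union,
    mean_coverage_retained = r$coverage$mean_coverage_retained,
    mean_coverage_all = r$coverage$mean_coverage_all
  )
}
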