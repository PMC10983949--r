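# Fixture bundles: seeded, self-contained input sets (source genome +
# annotation, mutated target genomes, uORF table, junction evidence, scored
# candidate junctions, pLDDT profiles) with a ground-truth record for every
# downstream stage. Truth is fixed by construction, never measured.

locus_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9176) %% 2147483647)
}

annot_from_record <- function(rec) {
  base <- tibble(chrom = rec$chrom, strand = rec$strand,
                 gene_id = rec$gene_id_annot, transcript_id = rec$tx_id)
  bind_rows(
    mutate(base, start = rec$gene_start, end = rec$gene_end, type = "gene",
           transcript_id = NA_character_),
    mutate(base, start = rec$gene_start, end = rec$gene_end, type = "transcript"),
    bind_cols(base[rep(1, nrow(rec$exons)), ], rec$exons) |> mutate(type = "exon"),
    bind_cols(base[rep(1, nrow(rec$cds)), ], rec$cds) |> mutate(type = "CDS")
  ) |> select("chrom", "start", "end", "strand", "type", "gene_id", "transcript_id")
}

#' Default locus templates cycling through the generator's layouts
#'
#' Deterministic variety used when no explicit templates are given: both
#' strands, all three uORF layouts, and (from the fourth locus on) a mix of
#' clean grafts, injected filter failures, sub-threshold length ratios,
#' predicted-junction evidence spanning the 0.9 score cut, and pLDDT deltas
#' spanning the +/-1 retention band.
#'
#' @param n Number of loci.
#' @return List of [locus_template()] objects.
#' @export
default_locus_templates <- function(n) {
  purrr::map(seq_len(n), function(i) {
    layout <- UORF_LAYOUTS[(i - 1L) %% 3L + 1L]
    kind <- (i - 1L) %% 8L
    locus_template(
      gene_id = sprintf("SYNG%04d", i),
      strand = if (i %% 2L == 0L) "-" else "+",
      uorf_layout = if (kind %in% c(3L, 4L)) "utr_contained" else layout,
      has_valid_donor = kind != 5L,
      inject_premature_stop = kind == 3L,
      inject_frameshift = kind == 4L,
      target_cds_ratio = if (kind == 6L) 0.6 else 1.0,
      evidence = if (kind == 5L) character(0)
        else if (kind == 2L) c("coverage", "predicted")
        else if (kind == 7L) "predicted" else "coverage",
      predicted_scores = if (kind == 7L && i %% 16L >= 8L) c(0.99, 0.79) else c(0.95, 0.93),
      junction_coverage = 40L + 17L * ((i - 1L) %% 10L),
      plddt_delta = c(2.0, 0.0, -1.5, 2.5, 1.1, 2.0, 2.0, -0.4)[kind + 1L]
    )
  })
}

#' Build one target-genome locus under a mutation mode
#'
#' Rebuilds the source locus from its template and seed, applies the mode on
#' the plus-strand layout, then orients the chromosome. `"perfect"` yields a
#' byte-identical chromosome; the other modes realise the rubric outcomes of
#' the conservation levels (synonymous-only change, non-synonymous change,
#' relocation beyond/within 1 kbp of the gene span, uORF deletion, move into
#' an intron, gene renaming).
#'
#' @param template A [locus_template()].
#' @param seed Integer seed that was used to build the source locus.
#' @param mode One of `r paste0('"', TARGET_MODES, '"', collapse = ", ")`.
#' @return A locus record (sequence, annotation intervals, truth fields).
#' @export
mutate_target <- function(template, seed, mode = "perfect") {
  mode <- match.arg(mode, TARGET_MODES)
  rec <- withr::with_seed(seed, build_locus_plus(template))
  rec <- withr::with_seed(locus_seed(seed, match(mode, TARGET_MODES)),
                          apply_target_mode(rec, mode))
  if (template$strand == "-") rec <- flip_record(rec)
  rec$mode <- mode
  rec$expected <- expected_assessment(mode, template$uorf_layout)
  rec
}

build_source_locus <- function(template, seed) {
  rec <- withr::with_seed(seed, build_locus_plus(template))
  if (template$strand == "-") rec <- flip_record(rec)
  rec
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes a source genome + GTF, one mutated genome + GTF per target, the
#' uORF table, coverage-backed junction BED, scored candidate junctions,
#' per-protein pLDDT profiles and a JSON truth file. All randomness is
#' derived from `seed`; the same seed reproduces byte-identical files.
#'
#' @param dir Output directory.
#' @param n_loci Number of loci (each on its own chromosome).
#' @param seed Integer seed.
#' @param templates Optional list of [locus_template()]s (defaults to
#'   [default_locus_templates()]).
#' @param target_modes Named list: target genome id -> vector of mutation
#'   modes (length 1 or `n_loci`). Default: four targets, all `"perfect"`.
#' @param min_avg_score,min_cds_ratio,plddt_band Thresholds the recorded
#'   truth assumes (the defaults match the analysis defaults).
#' @param plddt_base_mean Average pLDDT around which reference profiles are
#'   centred.
#' @return A `uorf_fixture` object with paths, tables, locus records and the
#'   truth record.
#' @export
simulate_uorf_fixture <- function(dir, n_loci = 1L, seed = 1L,
                                  templates = NULL, target_modes = NULL,
                                  min_avg_score = 0.9, min_cds_ratio = 0.9,
                                  plddt_band = 1.0, plddt_base_mean = 78) {
  if (n_loci < 1L) abort("n_loci must be at least 1")
  templates <- templates %||% default_locus_templates(n_loci)
  if (length(templates) != n_loci) abort("need one template per locus")
  purrr::walk(templates, validate_template)
  if (is.null(target_modes)) {
    target_modes <- setNames(rep(list("perfect"), 4L),
                             paste0("genome", LETTERS[1:4]))
  }
  target_modes <- purrr::map(target_modes, function(m) {
    if (length(m) == 1L) rep(m, n_loci) else m
  })
  stopifnot(all(lengths(target_modes) == n_loci))

  dir.create(file.path(dir, "source"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "plddt"), recursive = TRUE, showWarnings = FALSE)

  seeds <- purrr::map_int(seq_len(n_loci), ~ locus_seed(seed, .x))
  source_recs <- purrr::map2(templates, seeds, build_source_locus)

  # --- source genome + annotation + uORF table + junction evidence
  src_seqs <- setNames(purrr::map_chr(source_recs, "seq"),
                       purrr::map_chr(source_recs, "chrom"))
  src_annot <- bind_rows(purrr::map(source_recs, annot_from_record))
  write_genome_fasta(src_seqs, file.path(dir, "source", "genome.fa"))
  write_annotation_gtf(src_annot, file.path(dir, "source", "annotation.gtf"))

  uorfs <- purrr::imap(source_recs, function(rec, i) {
    tibble(
      uorf_id = sprintf("uorf_%04d", i), chrom = rec$chrom, strand = rec$strand,
      blocks = list(rec$uorf_blocks), host_transcript_id = rec$tx_id,
      gene_id = rec$gene_id, nt_sequence = rec$uorf_nt, aa_sequence = rec$uorf_aa
    )
  }) |> bind_rows()
  write_uorf_table(uorfs, file.path(dir, "uorfs.tsv"))

  junctions <- purrr::imap(source_recs, function(rec, i) {
    jx <- locus_junctions(rec)
    if (nrow(jx) > 0) jx$uorf_id <- sprintf("uorf_%04d", i)
    jx
  }) |> bind_rows()
  cov_jx <- junctions |> filter(.data$provenance == "coverage_backed")
  if (nrow(cov_jx) > 0) {
    cov_jx$name <- sprintf("jx_%03d", seq_len(nrow(cov_jx)))
  }
  write_junction_bed(cov_jx, file.path(dir, "junctions.bed"))
  pred_jx <- junctions |> filter(.data$provenance == "score_predicted")
  write_scored_junctions(pred_jx, file.path(dir, "scored_junctions.tsv"))

  # --- target genomes
  target_paths <- list()
  conservation_truth <- list()
  for (tname in names(target_modes)) {
    tdir <- file.path(dir, "targets", tname)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    modes <- target_modes[[tname]]
    trecs <- purrr::map(seq_len(n_loci), function(i) {
      mutate_target(templates[[i]], seeds[i], modes[i])
    })
    tseqs <- setNames(purrr::map_chr(trecs, "seq"), purrr::map_chr(trecs, "chrom"))
    tannot <- bind_rows(purrr::map(trecs, annot_from_record))
    write_genome_fasta(tseqs, file.path(tdir, "genome.fa"))
    write_annotation_gtf(tannot, file.path(tdir, "annotation.gtf"))
    target_paths[[tname]] <- list(genome = file.path(tdir, "genome.fa"),
                                  annotation = file.path(tdir, "annotation.gtf"))
    conservation_truth[[tname]] <- purrr::imap(trecs, function(rec, i) {
      tibble(uorf_id = sprintf("uorf_%04d", i), target_genome_id = tname,
             mode = rec$mode, score = rec$expected$score,
             conserved = rec$expected$conserved,
             displaced_gt_1kbp = rec$expected$displaced)
    }) |> bind_rows()
  }
  conservation_truth <- bind_rows(conservation_truth)

  # --- transcript-construction truth (candidates, filters, structure)
  cand_truth <- purrr::imap(source_recs, function(rec, i) {
    tpl <- rec$template
    jx <- locus_junctions(rec)
    if (nrow(jx) == 0) return(NULL)
    keep_pred <- function(j) {
      mean(c(j$donor_score, j$acceptor_score)) >= min_avg_score &&
        !any(jx$provenance == "coverage_backed" &
               jx$donor == j$donor & jx$acceptor == j$acceptor)
    }
    rows <- purrr::map(seq_len(nrow(jx)), function(r) {
      j <- jx[r, ]
      if (j$provenance == "score_predicted" && !keep_pred(j)) return(NULL)
      graft_len <- j$uorf_offset + rec$geom$cds_rest
      ref_len <- rec$geom$e1 + rec$geom$cds_rest
      frame_ok <- graft_len %% 3L == 0L
      ratio <- graft_len / ref_len
      premature <- tpl$inject_premature_stop
      passed <- !premature && frame_ok && ratio >= min_cds_ratio
      verdict <- if (!passed) NA_character_
        else if (tpl$plddt_delta > plddt_band) "retained_improved"
        else if (abs(tpl$plddt_delta) <= plddt_band) "retained_no_change"
        else "eliminated"
      tibble(
        uorf_id = sprintf("uorf_%04d", i), gene_id = rec$gene_id,
        reference_transcript_id = rec$tx_id, chrom = rec$chrom,
        donor = j$donor, acceptor = j$acceptor, strand = rec$strand,
        provenance = j$provenance, coverage = j$coverage,
        graft_len = graft_len, ref_cds_len = ref_len,
        premature_stop = premature, frame_multiple_of_3 = frame_ok,
        length_ratio = ratio, passed = passed,
        plddt_delta = tpl$plddt_delta, verdict = verdict,
        retained = passed && !is.na(verdict) && verdict != "eliminated"
      )
    })
    bind_rows(purrr::compact(rows))
  }) |> purrr::compact() |> bind_rows()

  if (nrow(cand_truth) > 0) {
    ord <- order(cand_truth$uorf_id, cand_truth$donor, cand_truth$acceptor,
                 cand_truth$reference_transcript_id)
    cand_truth <- cand_truth[ord, ]
    cand_truth$transcript_id <- sprintf("uorft_%04d", seq_len(nrow(cand_truth)))
    cand_truth <- select(cand_truth, "transcript_id", dplyr::everything())
  } else {
    cand_truth <- tibble(
      transcript_id = character(), uorf_id = character(), gene_id = character(),
      reference_transcript_id = character(), chrom = character(),
      donor = integer(), acceptor = integer(), strand = character(),
      provenance = character(), coverage = integer(), graft_len = integer(),
      ref_cds_len = integer(), premature_stop = logical(),
      frame_multiple_of_3 = logical(), length_ratio = double(),
      passed = logical(), plddt_delta = double(), verdict = character(),
      retained = logical()
    )
  }

  # --- pLDDT profiles: references and passing novel proteins
  pairs <- cand_truth |>
    filter(.data$passed) |>
    mutate(
      novel_id = .data$transcript_id,
      novel_len = .data$graft_len / 3L - 1L,
      reference_id = .data$reference_transcript_id,
      reference_len = .data$ref_cds_len / 3L - 1L,
      delta = .data$plddt_delta
    ) |>
    select("novel_id", "novel_len", "reference_id", "reference_len", "delta")
  emit_plddt_profiles(pairs, file.path(dir, "plddt"),
                      base_mean = plddt_base_mean, rng_seed = locus_seed(seed, 777L))

  truth <- list(
    seed = seed, n_loci = n_loci,
    thresholds = list(min_avg_score = min_avg_score,
                      min_cds_ratio = min_cds_ratio, plddt_band = plddt_band),
    conservation = conservation_truth,
    transcripts = cand_truth,
    retained_transcripts = cand_truth$transcript_id[cand_truth$retained],
    n_uorfs_retained_union = dplyr::n_distinct(cand_truth$uorf_id[cand_truth$retained])
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(
    dir = dir,
    paths = list(
      source_genome = file.path(dir, "source", "genome.fa"),
      source_annotation = file.path(dir, "source", "annotation.gtf"),
      uorf_table = file.path(dir, "uorfs.tsv"),
      junction_bed = file.path(dir, "junctions.bed"),
      scored_junctions = file.path(dir, "scored_junctions.tsv"),
      plddt_dir = file.path(dir, "plddt"),
      truth = file.path(dir, "truth.json"),
      targets = target_paths
    ),
    templates = templates, seeds = seeds,
    records = source_recs, uorfs = uorfs, junctions = junctions,
    truth = truth
  )
  class(out) <- "uorf_fixture"
  out
}

#' @export
print.uorf_fixture <- function(x, ...) {
  cat(sprintf("<uorf_fixture> %d loci, %d target genomes at '%s'\n",
              x$truth$n_loci, length(x$paths$targets), x$dir))
  invisible(x)
}

#' Emit per-residue pLDDT tables realising exact average deltas
#'
#' For each (novel, reference) pair, the reference profile is centred at
#' `base_mean` and the novel profile at `base_mean + delta`; after centring,
#' the realised difference of averages equals the requested delta to within
#' 1e-9. Residue values stay inside [0, 100]; a delta whose implied average
#' leaves that range is rejected.
#'
#' @param pairs Tibble with `novel_id`, `novel_len`, `reference_id`,
#'   `reference_len`, `delta`.
#' @param dir Output directory for `<protein_id>.tsv` tables (`NULL` to skip
#'   writing).
#' @param base_mean Reference average pLDDT.
#' @param rng_seed Seed for the per-residue noise.
#' @return Named list of numeric profiles.
#' @export
emit_plddt_profiles <- function(pairs, dir = NULL, base_mean = 78,
                                rng_seed = 1L) {
  make_profile <- function(n, target) {
    if (target < 0 || target > 100) {
      abort(sprintf("unreachable pLDDT delta: implied average %.2f outside [0, 100]", target))
    }
    half <- min(8, target, 100 - target)
    vals <- stats::runif(n, -half, half)
    vals <- vals - mean(vals) + target
    while (any(vals < 0 | vals > 100)) {
      half <- half / 2
      vals <- stats::runif(n, -half, half)
      vals <- vals - mean(vals) + target
    }
    vals
  }
  profiles <- withr::with_seed(rng_seed, {
    out <- list()
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      if (is.null(out[[p$reference_id]])) {
        out[[p$reference_id]] <- make_profile(p$reference_len, base_mean)
      }
      ref_avg <- mean(out[[p$reference_id]])
      out[[p$novel_id]] <- make_profile(p$novel_len, ref_avg + p$delta)
      realized <- mean(out[[p$novel_id]]) - ref_avg
      stopifnot(abs(realized - p$delta) < 1e-9)
    }
    out
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(profiles, function(v, id) {
      readr::write_tsv(tibble(residue_index = seq_along(v), plddt = v),
                       file.path(dir, paste0(id, ".tsv")))
    })
  }
  invisible(profiles)
}
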