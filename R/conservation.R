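# Cross-genome conservation scoring of uORFs on the additive 0-7 rubric:
# sequence match (weight 4, with a protein-level fallback for mismatched
# full-length hits), 5'UTR containment (weight 2) and gene locus match
# (weight 1). Each uORF is assessed in genomic and transcriptomic space and
# the higher-scoring assessment wins; a score >= 4 counts as conserved
# unless the best sequence match lies more than `locus_distance_bp` away
# from the source gene's annotated span.

strip_version <- function(x) sub("\\.\\d+$", "", x)

# Precomputed per-target structures shared across uORFs: transcript models,
# spliced transcript sequences and gene spans.
target_cache <- function(genome, annot) {
  models <- transcript_models(annot)
  tx_seqs <- if (is.null(genome)) NULL else purrr::map_chr(models, function(m) {
    spliced_seq(genome, m$chrom, m$exons, m$strand)
  })
  list(models = models, tx_seqs = tx_seqs, genes = gene_spans(annot))
}

#' Additive conservation rubric score
#'
#' @param sequence_match,utr_containment,locus_match Logical criterion flags
#'   (weights 4, 2 and 1).
#' @return Integer score 0-7.
#' @export
rubric_score <- function(sequence_match, utr_containment, locus_match) {
  as.integer(4L * as.logical(sequence_match) +
               2L * as.logical(utr_containment) +
               1L * as.logical(locus_match))
}

# Per-transcript structures derived from an annotation table.
transcript_models <- function(annot) {
  tx_ids <- unique(stats::na.omit(annot$transcript_id[annot$type %in% c("exon", "CDS")]))
  purrr::map(setNames(tx_ids, tx_ids), function(tx) {
    rows <- annot[!is.na(annot$transcript_id) & annot$transcript_id == tx, ]
    exons <- rows[rows$type == "exon", c("start", "end")] |> arrange(.data$start)
    cds <- rows[rows$type == "CDS", c("start", "end")] |> arrange(.data$start)
    strand <- rows$strand[1]
    lens <- exons$end - exons$start
    # length of exonic sequence upstream of the CDS start, transcript coords
    cds_off <- NA_integer_
    if (nrow(cds) > 0) {
      if (strand == "+") {
        cstart <- min(cds$start)
        cds_off <- sum(pmax(0L, pmin(exons$end, cstart) - exons$start))
      } else {
        cend <- max(cds$end)
        cds_off <- sum(pmax(0L, exons$end - pmax(exons$start, cend)))
      }
    }
    utr <- NULL
    if (nrow(cds) > 0) {
      if (strand == "+") {
        cstart <- min(cds$start)
        utr <- exons |> filter(.data$start < cstart) |>
          mutate(end = pmin(.data$end, cstart))
      } else {
        cend <- max(cds$end)
        utr <- exons |> filter(.data$end > cend) |>
          mutate(start = pmax(.data$start, cend))
      }
      utr <- utr[utr$end > utr$start, ]
    }
    list(
      transcript_id = tx, gene_id = rows$gene_id[1], chrom = rows$chrom[1],
      strand = strand, exons = exons, cds = cds, coding = nrow(cds) > 0,
      cds_start_offset = cds_off, utr5 = utr,
      span = c(min(exons$start), max(exons$end))
    )
  })
}

gene_spans <- function(annot) {
  rows <- annot[annot$type == "gene", ]
  tibble(chrom = rows$chrom, start = rows$start, end = rows$end,
         gene_id = strip_version(rows$gene_id))
}

interval_gap <- function(s1, e1, s2, e2) {
  if (e1 > s2 && e2 > s1) return(0)
  max(s2 - e1, s1 - e2)
}

#' All-frame protein-identity fallback for a mismatched full-length hit
#'
#' Checks whether any of the six frame translations (three forward, three on
#' the reverse complement) of the matched target subsequence equals the
#' query's encoded protein exactly.
#'
#' @param uorf_aa Amino-acid sequence of the query uORF (stop rendered `*`).
#' @param hit_nt Nucleotide sequence of the full-length target hit.
#' @return `TRUE` iff some frame translation matches.
#' @export
protein_fallback <- function(uorf_aa, hit_nt) {
  for (s in c(hit_nt, revcomp(hit_nt))) {
    for (off in 0:2) {
      if (translate_frame(s, off) == uorf_aa) return(TRUE)
    }
  }
  FALSE
}

match_in_sequence <- function(pattern, subject, max_mismatch) {
  hits <- list()
  pat_f <- Biostrings::DNAString(pattern)
  subj <- Biostrings::DNAString(subject)
  for (str in c("+", "-")) {
    pat <- if (str == "+") pat_f else Biostrings::reverseComplement(pat_f)
    mp <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    if (length(mp) == 0) next
    seqs <- as.character(mp)
    n_mis <- vapply(seqs, function(s) hamming(s, as.character(pat)), integer(1))
    hits[[str]] <- tibble(
      start = Biostrings::start(mp) - 1L, end = Biostrings::end(mp),
      strand = str, n_mismatches = as.integer(n_mis), hit_nt_sense = NA_character_
    ) |>
      mutate(hit_nt_sense = if (str == "+") seqs else vapply(seqs, revcomp, character(1)))
  }
  bind_rows(hits)
}

#' Find genomic and transcriptomic matches of a uORF in a target genome
#'
#' When no precomputed alignments are supplied the target is scanned
#' exhaustively with [Biostrings::matchPattern()] on both strands, allowing
#' up to `max_mismatch` substitutions so that protein-level fallback
#' candidates are recovered; the target transcriptome (spliced transcript
#' sequences derived from the annotation) is scanned the same way.
#'
#' @param uorf One-row uORF tibble with `nt_sequence`/`aa_sequence` (see
#'   [hydrate_uorfs()]).
#' @param genome Named character vector of target chromosome sequences.
#' @param annot Target annotation table.
#' @param alignments Optional tibble of precomputed hits ([read_paf()] /
#'   [read_sam()]); rows whose target name is a chromosome are treated as
#'   genomic, rows naming a transcript as transcriptomic.
#' @param max_mismatch Substitution allowance for the built-in scan;
#'   defaults to `max(3, ceiling(0.1 * query length))`.
#' @return Tibble of hits with `space`, location, `n_mismatches`,
#'   `full_length` and `protein_identical` columns.
#' @export
find_uorf_matches <- function(uorf, genome, annot, alignments = NULL,
                              max_mismatch = NULL, cache = NULL) {
  q <- uorf$nt_sequence
  qlen <- nchar(q)
  if (is.null(max_mismatch)) max_mismatch <- max(3L, ceiling(0.1 * qlen))
  if (is.null(cache)) cache <- target_cache(genome, annot)
  tx_seqs <- cache$tx_seqs

  if (!is.null(alignments)) {
    aln <- alignments[alignments$query == uorf$uorf_id & alignments$full_length, ]
    hits <- purrr::pmap(aln, function(...) {
      row <- list(...)
      space <- if (row$chrom %in% names(genome)) "genomic" else "transcriptomic"
      if (space == "transcriptomic" && !row$chrom %in% names(tx_seqs)) {
        abort(sprintf("alignment target '%s' is neither a chromosome nor a transcript", row$chrom))
      }
      subj <- if (space == "genomic") genome[[row$chrom]] else tx_seqs[[row$chrom]]
      nt <- substr0(subj, row$start, row$end)
      if (row$strand == "-") nt <- revcomp(nt)
      tibble(space = space, target = row$chrom, start = row$start, end = row$end,
             strand = row$strand, n_mismatches = row$n_mismatches,
             full_length = TRUE, hit_nt_sense = nt)
    })
    hits <- bind_rows(hits)
  } else {
    gen_hits <- purrr::imap(genome, function(s, nm) {
      h <- match_in_sequence(q, s, max_mismatch)
      if (nrow(h) == 0) return(NULL)
      mutate(h, space = "genomic", target = nm, full_length = TRUE)
    })
    tx_hits <- purrr::imap(tx_seqs, function(s, nm) {
      h <- match_in_sequence(q, s, max_mismatch)
      if (nrow(h) == 0) return(NULL)
      mutate(h, space = "transcriptomic", target = nm, full_length = TRUE)
    })
    hits <- bind_rows(purrr::compact(c(gen_hits, tx_hits)))
  }
  if (nrow(hits) == 0) {
    return(tibble(space = character(), target = character(), start = integer(),
                  end = integer(), strand = character(), n_mismatches = integer(),
                  full_length = logical(), protein_identical = logical()))
  }
  hits$protein_identical <- purrr::pmap_lgl(
    hits[, c("n_mismatches", "full_length", "hit_nt_sense")],
    function(n_mismatches, full_length, hit_nt_sense) {
      if (!full_length || n_mismatches == 0L) return(NA)
      protein_fallback(uorf$aa_sequence, hit_nt_sense)
    }
  )
  hits |> select(-"hit_nt_sense") |> arrange(.data$space, .data$target, .data$start)
}

# Evaluate rubric flags for every hit and keep the best one.
score_hits <- function(uorf, hits, annot, locus_distance_bp = 1000, cache = NULL) {
  if (is.null(cache)) cache <- target_cache(NULL, annot)
  models <- cache$models
  genes <- cache$genes
  expected <- strip_version(uorf$gene_id)

  eval_hit <- function(h) {
    seq_match <- h$full_length && (h$n_mismatches == 0L || isTRUE(h$protein_identical))
    utr <- FALSE; utr_partial <- FALSE; locus <- FALSE; dist <- Inf
    if (h$space == "genomic") {
      for (m in models) {
        if (!m$coding || m$chrom != h$target || m$strand != h$strand) next
        if (is.null(m$utr5) || nrow(m$utr5) == 0) next
        contained <- any(m$utr5$start <= h$start & m$utr5$end >= h$end)
        overlaps <- any(m$utr5$start < h$end & m$utr5$end > h$start)
        utr <- utr || contained
        utr_partial <- utr_partial || (overlaps && !contained)
      }
      g_exp <- genes[genes$gene_id == expected & genes$chrom == h$target, ]
      locus <- nrow(g_exp) > 0 &&
        any(g_exp$start < h$end & g_exp$end > h$start)
      ref <- if (nrow(g_exp) > 0) g_exp else genes[genes$chrom == h$target, ]
      if (nrow(ref) > 0) {
        dist <- min(purrr::map2_dbl(ref$start, ref$end,
                                    ~ interval_gap(h$start, h$end, .x, .y)))
      }
    } else {
      m <- models[[h$target]]
      utr <- m$coding && h$strand == "+" && !is.na(m$cds_start_offset) &&
        h$end <= m$cds_start_offset
      utr_partial <- m$coding && h$strand == "+" && !utr &&
        !is.na(m$cds_start_offset) && h$start < m$cds_start_offset
      locus <- strip_version(m$gene_id) == expected
      g_exp <- genes[genes$gene_id == expected & genes$chrom == m$chrom, ]
      ref <- if (nrow(g_exp) > 0) g_exp else genes[genes$chrom == m$chrom, ]
      if (nrow(ref) > 0) {
        dist <- min(purrr::map2_dbl(ref$start, ref$end,
                                    ~ interval_gap(m$span[1], m$span[2], .x, .y)))
      }
    }
    tibble(sequence_match = seq_match, utr_containment = utr,
           utr_partial = utr_partial, locus_match = locus,
           score = rubric_score(seq_match, utr, locus),
           hit_distance = dist)
  }

  flags <- purrr::pmap(hits, function(...) eval_hit(list(...)))
  bind_rows(flags) |>
    mutate(space = hits$space, n_mismatches = hits$n_mismatches)
}

#' Score one uORF's conservation assessment in one target
#'
#' Reconciles genomic and transcriptomic hits: the highest-scoring hit wins
#' (ties resolve to genomic space, then fewer mismatches). An empty hit set
#' yields score 0.
#'
#' @inheritParams find_uorf_matches
#' @param hits Hit tibble from [find_uorf_matches()].
#' @param locus_distance_bp Displacement threshold for the "sequence match
#'   far from the source gene" exception (default 1000).
#' @return One-row assessment tibble.
#' @export
score_conservation <- function(uorf, hits, annot, locus_distance_bp = 1000,
                               cache = NULL) {
  empty <- tibble(
    uorf_id = uorf$uorf_id, sequence_match = FALSE, utr_containment = FALSE,
    utr_partial = FALSE, locus_match = FALSE, score = 0L,
    displaced_gt_1kbp = FALSE, conserved = FALSE, winning_space = "none"
  )
  if (nrow(hits) == 0) return(empty)
  flags <- score_hits(uorf, hits, annot, locus_distance_bp, cache = cache)
  ord <- order(-flags$score, flags$space != "genomic", flags$n_mismatches)
  best <- flags[ord[1], ]
  displaced <- best$sequence_match && best$hit_distance > locus_distance_bp
  tibble(
    uorf_id = uorf$uorf_id,
    sequence_match = best$sequence_match,
    utr_containment = best$utr_containment,
    utr_partial = best$utr_partial,
    locus_match = best$locus_match,
    score = best$score,
    displaced_gt_1kbp = displaced,
    conserved = best$score >= 4L && !displaced,
    winning_space = best$space
  )
}

#' Assess uORF conservation across target genomes
#'
#' Runs the full rubric for every uORF in every target genome and summarises
#' cross-genome intersections.
#'
#' @param uorfs Hydrated uORF tibble ([hydrate_uorfs()]).
#' @param targets Named list; each element a list with `genome` (named
#'   character vector or FASTA path) and `annotation` (annotation tibble or
#'   GTF path).
#' @param alignments Optional named list of precomputed alignment tibbles
#'   per target.
#' @param max_mismatch,locus_distance_bp See [find_uorf_matches()] and
#'   [score_conservation()].
#' @return A `uorf_conservation` object; `tidy()` returns the per-uORF,
#'   per-genome assessments, `glance()` the cross-genome summary.
#' @export
assess_conservation <- function(uorfs, targets, alignments = NULL,
                                max_mismatch = NULL, locus_distance_bp = 1000) {
  rows <- purrr::imap(targets, function(tgt, tname) {
    genome <- if (is.character(tgt$genome) && length(tgt$genome) == 1 &&
                  file.exists(tgt$genome)) read_genome_fasta(tgt$genome) else tgt$genome
    annot <- if (is.character(tgt$annotation)) read_annotation(tgt$annotation) else tgt$annotation
    aln <- if (!is.null(alignments)) alignments[[tname]] else NULL
    cache <- target_cache(genome, annot)
    purrr::map(seq_len(nrow(uorfs)), function(i) {
      u <- uorfs[i, ]
      hits <- find_uorf_matches(u, genome, annot, alignments = aln,
                                max_mismatch = max_mismatch, cache = cache)
      score_conservation(u, hits, annot, locus_distance_bp, cache = cache) |>
        mutate(target_genome_id = tname, .after = "uorf_id")
    }) |> bind_rows()
  })
  assessments <- bind_rows(rows) |> arrange(.data$uorf_id, .data$target_genome_id)
  out <- list(
    assessments = assessments,
    intersections = summarize_intersections(assessments),
    targets = names(targets),
    n_uorfs = nrow(uorfs)
  )
  class(out) <- "uorf_conservation"
  out
}

#' Cross-genome intersection counts of conserved uORFs
#'
#' @param assessments Assessment tibble with `uorf_id`, `target_genome_id`
#'   and `conserved` columns covering every uORF in every genome.
#' @return List with `per_genome` conserved totals and `subsets` counts of
#'   uORFs conserved in exactly each subset of genomes (subset counts sum to
#'   the number of uORFs; uORFs conserved nowhere fall in subset `"none"`).
#' @export
summarize_intersections <- function(assessments) {
  genomes <- sort(unique(assessments$target_genome_id))
  uorf_ids <- sort(unique(assessments$uorf_id))
  grid <- tidyr::expand_grid(uorf_id = uorf_ids, target_genome_id = genomes)
  missing <- anti_join(grid, assessments, by = c("uorf_id", "target_genome_id"))
  if (nrow(missing) > 0) {
    abort(sprintf("missing assessment for uORF '%s' in genome '%s'",
                  missing$uorf_id[1], missing$target_genome_id[1]))
  }
  per_genome <- assessments |>
    group_by(target_genome_id = .data$target_genome_id) |>
    summarise(n_conserved = sum(.data$conserved), .groups = "drop")
  subsets <- assessments |>
    filter(.data$conserved) |>
    group_by(uorf_id = .data$uorf_id) |>
    summarise(subset = paste(sort(.data$target_genome_id), collapse = ","),
              .groups = "drop")
  subsets <- tibble(uorf_id = uorf_ids) |>
    left_join(subsets, by = "uorf_id") |>
    mutate(subset = dplyr::coalesce(.data$subset, "none")) |>
    count(.data$subset, name = "n_uorfs") |>
    arrange(dplyr::desc(.data$n_uorfs))
  list(per_genome = per_genome, subsets = subsets)
}

#' @export
print.uorf_conservation <- function(x, ...) {
  cat(sprintf("<uorf_conservation> %d uORFs x %d genomes\n", x$n_uorfs, length(x$targets)))
  all_key <- paste(sort(x$targets), collapse = ",")
  n_all <- x$intersections$subsets$n_uorfs[x$intersections$subsets$subset == all_key]
  if (length(n_all) == 0) n_all <- 0L
  cat(sprintf("  conserved in all genomes: %d/%d\n", n_all, x$n_uorfs))
  invisible(x)
}

#' @export
tidy.uorf_conservation <- function(x, ...) x$assessments

#' @export
glance.uorf_conservation <- function(x, ...) {
  all_key <- paste(sort(x$targets), collapse = ",")
  n_all <- x$intersections$subsets$n_uorfs[x$intersections$subsets$subset == all_key]
  if (length(n_all) == 0) n_all <- 0L
  tibble(
    n_uorfs = x$n_uorfs, n_genomes = length(x$targets),
    n_conserved_all = as.integer(n_all),
    frac_conserved_all = n_all / x$n_uorfs,
    mean_score = mean(x$assessments$score)
  )
}

#' @export
autoplot.uorf_conservation <- function(object, ...) {
  ggplot2::ggplot(object$assessments,
                  ggplot2::aes(x = .data$target_genome_id, y = .data$uorf_id,
                               fill = factor(.data$score, levels = 0:7))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_viridis_d(name = "score", drop = FALSE) +
    ggplot2::labs(x = "target genome", y = "uORF",
                  title = "uORF conservation rubric scores") +
    ggplot2::theme_minimal()
}

#' Write per-uORF assessments and intersection counts as TSVs
#' @param x `uorf_conservation` object.
#' @param dir Output directory.
#' @export
write_conservation_tsvs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$assessments, file.path(dir, "conservation_assessments.tsv"))
  readr::write_tsv(x$intersections$subsets, file.path(dir, "conservation_intersections.tsv"))
  readr::write_tsv(x$intersections$per_genome, file.path(dir, "conservation_per_genome.tsv"))
  invisible(dir)
}
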