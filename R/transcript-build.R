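# Construction of uORF-connected transcripts: a splice donor inside a uORF
# is joined to an acceptor inside the downstream gene's CDS, the uORF prefix
# (start codon up to the donor) is concatenated with the reference coding
# sequence from the acceptor onward, and the graft passes through three
# validity filters: no premature stop codon, length a multiple of three, and
# CDS length >= 90% of the reference CDS.

# transcription-order vector of genomic positions covered by interval blocks
positions_in_order <- function(blocks, strand) {
  pos <- unlist(purrr::map2(blocks$start, blocks$end, ~ seq.int(.x, .y - 1L)))
  if (strand == "-") rev(pos) else pos
}

runs_to_blocks <- function(pos) {
  pos <- sort(pos)
  breaks <- which(diff(pos) != 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))] + 1L
  tibble(start = as.integer(starts), end = as.integer(ends))
}

junction_dinucleotides <- function(genome, chrom, donor, acceptor, strand) {
  s <- genome[[chrom]]
  if (strand == "+") {
    list(donor = substr0(s, donor, donor + 2L),
         acceptor = substr0(s, acceptor - 2L, acceptor))
  } else {
    list(donor = revcomp(substr0(s, acceptor - 2L, acceptor)),
         acceptor = revcomp(substr0(s, donor, donor + 2L)))
  }
}

# strand-aware biological endpoints of an intron record
donor_base <- function(j) if (j$strand == "+") j$donor else j$acceptor - 1L
acceptor_base <- function(j) if (j$strand == "+") j$acceptor else j$donor - 1L

#' Load coverage-backed splice junctions relevant to uORF grafting
#'
#' Reads junction evidence (BED6 + coverage, introns 0-based half-open) and
#' keeps only junctions whose donor lies inside some uORF's blocks and whose
#' acceptor falls within the CDS span of a protein-coding transcript of the
#' same gene. Junctions violating the GT-AG rule on the sense strand are
#' dropped with a warning.
#'
#' @param path Junction BED path (or an already-read junction tibble).
#' @param uorfs Hydrated uORF tibble.
#' @param annot Annotation table of the source genome.
#' @param genome Named character vector of source chromosome sequences.
#' @return Junction tibble tagged `coverage_backed`, one row per
#'   (junction, matching uORF) pair.
#' @export
load_junctions <- function(path, uorfs, annot, genome) {
  raw <- if (is.character(path)) read_junction_bed(path) else path
  if (nrow(raw) == 0) return(raw)
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    j <- raw[i, ]
    if (j$acceptor - j$donor < 4L) {
      warn(sprintf("junction %s:%d-%d dropped: intron shorter than 4 bases",
                   j$chrom, j$donor, j$acceptor))
      keep[i] <- FALSE
      next
    }
    di <- junction_dinucleotides(genome, j$chrom, j$donor, j$acceptor, j$strand)
    if (di$donor != "GT" || di$acceptor != "AG") {
      warn(sprintf("junction %s:%d-%d(%s) dropped: non-canonical %s..%s (GT-AG required)",
                   j$chrom, j$donor, j$acceptor, j$strand, di$donor, di$acceptor))
      keep[i] <- FALSE
    }
  }
  raw <- raw[keep, ]
  models <- transcript_models(annot)
  out <- list()
  for (i in seq_len(nrow(raw))) {
    j <- raw[i, ]
    d <- donor_base(j)
    a <- acceptor_base(j)
    for (k in seq_len(nrow(uorfs))) {
      u <- uorfs[k, ]
      if (u$chrom != j$chrom || u$strand != j$strand) next
      blocks <- u$blocks[[1]]
      if (!any(blocks$start <= d & d < blocks$end)) next
      ok <- FALSE
      for (m in models) {
        if (!m$coding || m$chrom != j$chrom || m$strand != j$strand) next
        if (strip_version(m$gene_id) != strip_version(u$gene_id)) next
        if (min(m$cds$start) <= a && a < max(m$cds$end)) { ok <- TRUE; break }
      }
      if (!ok) next
      out[[length(out) + 1L]] <- mutate(
        j, uorf_id = u$uorf_id, provenance = "coverage_backed",
        donor_score = NA_real_, acceptor_score = NA_real_
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), donor = integer(), acceptor = integer(),
                  strand = character(), coverage = integer(), uorf_id = character(),
                  provenance = character(), donor_score = double(),
                  acceptor_score = double()))
  }
  bind_rows(out)
}

#' Scan a uORF for candidate splice donors (GT dinucleotides)
#'
#' Every sense-strand GT whose first base lies after the start codon and
#' before the uORF's stop codon is reported; GTs split across two uORF
#' blocks are skipped since they are not genomically contiguous.
#'
#' @param uorf One-row hydrated uORF tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with the spliced `offset` of each donor (the would-be
#'   first intronic base) and its genomic position `donor_pos`.
#' @export
scan_donor_candidates <- function(uorf, genome) {
  nt <- uorf$nt_sequence
  len <- nchar(nt)
  blocks <- uorf$blocks[[1]]
  offs <- as.integer(stringr::str_locate_all(nt, "GT")[[1]][, 1]) - 1L
  offs <- offs[offs >= 3L & offs <= len - 5L]
  rows <- purrr::map(offs, function(o) {
    m <- splice_offset_to_genomic(blocks, uorf$strand, o, width = 2L)
    if (!m$contiguous) return(NULL)
    tibble(uorf_id = uorf$uorf_id, chrom = uorf$chrom, strand = uorf$strand,
           offset = o, donor_pos = m$pos[1])
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(uorf_id = character(), chrom = character(), strand = character(),
                  offset = integer(), donor_pos = integer())
  }
  out
}

#' Build a junction scorer from a precomputed score table
#'
#' The returned function fulfils the scorer contract used by
#' [pair_and_score()]: it takes a junction tibble and returns matching
#' `donor_score`/`acceptor_score` columns. Junctions absent from the table
#' score 0 on both ends.
#'
#' @param scores Tibble with `chrom`, `donor`, `acceptor`, `strand`,
#'   `donor_score`, `acceptor_score` (see [read_scored_junctions()]).
#' @return A scorer function.
#' @export
scorer_from_table <- function(scores) {
  function(junctions) {
    hit <- left_join(
      junctions[, c("chrom", "donor", "acceptor", "strand")],
      scores, by = c("chrom", "donor", "acceptor", "strand")
    )
    tibble(donor_score = dplyr::coalesce(hit$donor_score, 0),
           acceptor_score = dplyr::coalesce(hit$acceptor_score, 0))
  }
}

#' Pair donor candidates with annotated acceptors and score the junctions
#'
#' Acceptor sites are the starts (in transcription sense) of the reference
#' transcript's CDS exons 2..n. Each candidate junction is scored by the
#' supplied scorer; junctions with a mean donor/acceptor score of at least
#' `min_avg_score` are retained, excluding any junction already present in
#' the coverage-backed set.
#'
#' @param donors Donor tibble from [scan_donor_candidates()].
#' @param annot Annotation table.
#' @param reference_transcript_id Transcript whose annotated acceptors are
#'   used.
#' @param scorer Scorer function (see [scorer_from_table()]).
#' @param known Coverage-backed junction tibble to exclude (may be empty).
#' @param min_avg_score Retention threshold on the mean of donor and
#'   acceptor scores (default 0.9).
#' @return Junction tibble tagged `score_predicted`.
#' @export
pair_and_score <- function(donors, annot, reference_transcript_id, scorer,
                           known = NULL, min_avg_score = 0.9) {
  if (nrow(donors) == 0) {
    return(tibble(chrom = character(), donor = integer(), acceptor = integer(),
                  strand = character(), coverage = integer(), uorf_id = character(),
                  provenance = character(), donor_score = double(),
                  acceptor_score = double()))
  }
  m <- transcript_models(annot)[[reference_transcript_id]]
  if (is.null(m) || !m$coding) {
    abort(sprintf("reference transcript '%s' not found or non-coding", reference_transcript_id))
  }
  cds_tx <- if (m$strand == "-") m$cds[rev(seq_len(nrow(m$cds))), ] else m$cds
  if (nrow(cds_tx) < 2L) {
    return(tibble(chrom = character(), donor = integer(), acceptor = integer(),
                  strand = character(), coverage = integer(), uorf_id = character(),
                  provenance = character(), donor_score = double(),
                  acceptor_score = double()))
  }
  acc <- cds_tx[-1, ]
  cands <- tidyr::crossing(donors, acc_i = seq_len(nrow(acc))) |>
    mutate(
      donor = if_else(.data$strand == "+", .data$donor_pos,
                      acc$end[.data$acc_i]),
      acceptor = if_else(.data$strand == "+", acc$start[.data$acc_i],
                         .data$donor_pos + 1L)
    ) |>
    select("uorf_id", "chrom", "strand", "donor", "acceptor")
  sc <- scorer(cands)
  if (!all(c("donor_score", "acceptor_score") %in% names(sc)) ||
      nrow(sc) != nrow(cands)) {
    abort("scorer must return donor_score/acceptor_score for every junction")
  }
  if (any(sc$donor_score < 0 | sc$donor_score > 1 |
          sc$acceptor_score < 0 | sc$acceptor_score > 1, na.rm = TRUE)) {
    abort("scorer returned scores outside [0, 1]")
  }
  cands <- bind_cols(cands, sc) |>
    filter((.data$donor_score + .data$acceptor_score) / 2 >= min_avg_score) |>
    mutate(provenance = "score_predicted", coverage = NA_integer_)
  if (!is.null(known) && nrow(known) > 0) {
    cands <- anti_join(cands, known, by = c("chrom", "donor", "acceptor", "strand"))
  }
  distinct(cands, .data$chrom, .data$donor, .data$acceptor, .data$strand,
           .data$uorf_id, .keep_all = TRUE)
}

#' Graft a uORF onto a downstream reference transcript across a junction
#'
#' The grafted coding sequence is the uORF from its start codon up to (and
#' excluding) the donor's first intronic base, concatenated with the
#' reference coding sequence from the acceptor through the reference stop.
#'
#' @param uorf One-row hydrated uORF tibble.
#' @param junction One-row junction tibble (intron `donor`/`acceptor`,
#'   0-based half-open).
#' @param annot Annotation table.
#' @param genome Named character vector of chromosome sequences.
#' @param reference_transcript_id Reference (downstream) transcript.
#' @return A candidate list: grafted `cds_nt`, exon/CDS block structure of
#'   the novel transcript, and provenance fields (no validity verdicts yet).
#' @export
build_uorf_transcript <- function(uorf, junction, annot, genome,
                                  reference_transcript_id) {
  m <- transcript_models(annot)[[reference_transcript_id]]
  if (is.null(m)) abort(sprintf("reference transcript '%s' not in annotation", reference_transcript_id))
  blocks <- uorf$blocks[[1]]
  strand <- uorf$strand
  d <- donor_base(junction)
  a <- acceptor_base(junction)

  upos <- positions_in_order(blocks, strand)
  off <- match(d, upos) - 1L
  if (is.na(off)) abort(sprintf("donor base %d is not inside uORF '%s'", d, uorf$uorf_id))
  prefix_nt <- substr0(uorf$nt_sequence, 0L, off)
  prefix_blocks <- if (off > 0L) runs_to_blocks(upos[seq_len(off)]) else tibble(start = integer(), end = integer())

  cds_pos <- positions_in_order(m$cds, m$strand)
  cds_seq <- spliced_seq(genome, m$chrom, m$cds, m$strand)
  acc_off <- match(a, cds_pos) - 1L
  if (is.na(acc_off)) {
    if (a >= min(m$cds$start) && a < max(m$cds$end)) {
      abort(sprintf("acceptor base %d lies in an intron of reference '%s'",
                    a, reference_transcript_id))
    }
    abort(sprintf("acceptor base %d is outside the CDS span of reference '%s'",
                  a, reference_transcript_id))
  }
  downstream_nt <- substr0(cds_seq, acc_off, nchar(cds_seq))
  downstream_cds_blocks <- runs_to_blocks(cds_pos[seq.int(acc_off + 1L, length(cds_pos))])

  # full exon chain of the novel transcript: uORF prefix, then reference
  # exons from the acceptor through the reference 3' end
  expos <- positions_in_order(m$exons, m$strand)
  a_at <- match(a, expos)
  exon_blocks <- bind_rows(prefix_blocks,
                           runs_to_blocks(expos[seq.int(a_at, length(expos))])) |>
    arrange(.data$start)

  list(
    uorf_id = uorf$uorf_id,
    gene_id = uorf$gene_id,
    reference_transcript_id = reference_transcript_id,
    chrom = uorf$chrom, strand = strand,
    donor = junction$donor, acceptor = junction$acceptor,
    provenance = junction$provenance,
    coverage = junction$coverage,
    cds_nt = paste0(prefix_nt, downstream_nt),
    reference_cds_len = nchar(cds_seq),
    reference_protein = translate_nt(cds_seq),
    exon_blocks = exon_blocks,
    cds_blocks = bind_rows(prefix_blocks, downstream_cds_blocks) |> arrange(.data$start)
  )
}

#' Apply the three validity filters to a grafted transcript
#'
#' A construct is discarded when (1) it contains a premature in-frame stop
#' codon, (2) its length is not a multiple of three, or (3) its CDS is
#' shorter than `min_cds_ratio` (default 90%) of the reference CDS, both
#' lengths including their stop codons. Surviving constructs are translated;
#' non-ATG starts and proteins identical to the reference are flagged, not
#' dropped.
#'
#' @param cand Candidate list from [build_uorf_transcript()].
#' @param min_cds_ratio Minimum novel/reference CDS length ratio.
#' @return The candidate with verdict fields filled in.
#' @export
validate_transcript <- function(cand, min_cds_ratio = 0.9) {
  nt <- cand$cds_nt
  len <- nchar(nt)
  n_full <- len %/% 3L
  codons <- if (n_full > 0) substring(nt, 3L * (seq_len(n_full) - 1L) + 1L, 3L * seq_len(n_full)) else character(0)
  internal <- if (len %% 3L == 0L && n_full > 1L) codons[-n_full] else codons
  cand$premature_stop <- any(internal %in% STOP_CODONS)
  cand$frame_multiple_of_3 <- len %% 3L == 0L
  cand$length_ratio <- len / cand$reference_cds_len
  cand$passed <- !cand$premature_stop && cand$frame_multiple_of_3 &&
    cand$length_ratio >= min_cds_ratio
  first <- substr(nt, 1L, 3L)
  cand$non_aug_start <- first != "ATG"
  cand$start_residue <- if (first %in% c("ATA", "ATT", "ATC")) "I" else if (first == "ATG") "M" else "?"
  if (cand$passed) {
    cand$protein_aa <- translate_nt(nt)
    cand$identical_to_reference <- sub("\\*$", "", cand$protein_aa) ==
      sub("\\*$", "", cand$reference_protein)
  } else {
    cand$protein_aa <- NA_character_
    cand$identical_to_reference <- NA
  }
  cand
}

#' Construct and validate all uORF-connected transcripts
#'
#' For every junction and every protein-coding reference transcript at the
#' uORF's locus whose CDS contains the junction's acceptor, one candidate is
#' built and passed through the validity filters. Transcript identifiers
#' `uorft_NNNN` are assigned deterministically over the sorted
#' (uorf_id, donor, acceptor, reference) tuples.
#'
#' @param uorfs Hydrated uORF tibble.
#' @param junctions Combined junction tibble (coverage-backed and/or
#'   score-predicted), carrying `uorf_id` and `provenance`.
#' @param annot Annotation table.
#' @param genome Named character vector of chromosome sequences.
#' @param min_cds_ratio Length-ratio filter threshold (default 0.9).
#' @return A `uorf_transcript_set` object; `tidy()` gives the per-candidate
#'   filter report.
#' @export
build_transcripts <- function(uorfs, junctions, annot, genome,
                              min_cds_ratio = 0.9) {
  models <- transcript_models(annot)
  cands <- list()
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    u <- uorfs[uorfs$uorf_id == j$uorf_id, ]
    if (nrow(u) == 0) abort(sprintf("junction references unknown uORF '%s'", j$uorf_id))
    a <- acceptor_base(j)
    refs <- purrr::keep(models, function(m) {
      m$coding && m$chrom == j$chrom && m$strand == j$strand &&
        strip_version(m$gene_id) == strip_version(u$gene_id) &&
        min(m$cds$start) <= a && a < max(m$cds$end) &&
        !is.na(match(a, positions_in_order(m$cds, m$strand)))
    })
    for (ref in names(refs)) {
      cand <- build_uorf_transcript(u, j, annot, genome, ref)
      cands[[length(cands) + 1L]] <- validate_transcript(cand, min_cds_ratio)
    }
  }
  if (length(cands) == 0) {
    tb <- tibble(
      transcript_id = character(), uorf_id = character(), gene_id = character(),
      reference_transcript_id = character(), chrom = character(), strand = character(),
      donor = integer(), acceptor = integer(), provenance = character(),
      coverage = integer(), cds_nt = character(), protein_aa = character(),
      reference_cds_len = integer(), premature_stop = logical(),
      frame_multiple_of_3 = logical(), length_ratio = double(),
      non_aug_start = logical(), identical_to_reference = logical(),
      passed = logical()
    )
    out <- list(candidates = tb, structures = list(), min_cds_ratio = min_cds_ratio)
    class(out) <- "uorf_transcript_set"
    return(out)
  }
  tb <- purrr::map(cands, function(cc) {
    tibble(
      uorf_id = cc$uorf_id, gene_id = cc$gene_id,
      reference_transcript_id = cc$reference_transcript_id,
      chrom = cc$chrom, strand = cc$strand,
      donor = cc$donor, acceptor = cc$acceptor, provenance = cc$provenance,
      coverage = cc$coverage, cds_nt = cc$cds_nt, protein_aa = cc$protein_aa,
      reference_cds_len = cc$reference_cds_len,
      premature_stop = cc$premature_stop,
      frame_multiple_of_3 = cc$frame_multiple_of_3,
      length_ratio = cc$length_ratio,
      non_aug_start = cc$non_aug_start, start_residue = cc$start_residue,
      identical_to_reference = cc$identical_to_reference, passed = cc$passed
    )
  }) |> bind_rows()
  ord <- order(tb$uorf_id, tb$donor, tb$acceptor, tb$reference_transcript_id)
  tb <- tb[ord, ]
  tb$transcript_id <- sprintf("uorft_%04d", seq_len(nrow(tb)))
  tb <- select(tb, "transcript_id", dplyr::everything())
  structures <- setNames(cands[ord], tb$transcript_id)
  out <- list(candidates = tb, structures = structures, min_cds_ratio = min_cds_ratio)
  class(out) <- "uorf_transcript_set"
  out
}

#' Mean junction coverage, retained transcripts versus all constructions
#'
#' Means are taken over the coverage-backed junctions of (a) the retained
#' transcript set and (b) every transcript construction; empty sets yield
#' `NA` rather than zero.
#'
#' @param x `uorf_transcript_set` object.
#' @param retained_ids Transcript ids retained after downstream gating.
#' @return One-row tibble with `mean_coverage_retained` and
#'   `mean_coverage_all`.
#' @export
coverage_summary <- function(x, retained_ids = NULL) {
  tb <- x$candidates |> filter(.data$provenance == "coverage_backed")
  all_cov <- tb$coverage
  ret_cov <- if (is.null(retained_ids)) tb$coverage[tb$passed] else tb$coverage[tb$transcript_id %in% retained_ids]
  safe_mean <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  tibble(mean_coverage_retained = safe_mean(ret_cov),
         mean_coverage_all = safe_mean(all_cov))
}

#' @export
print.uorf_transcript_set <- function(x, ...) {
  tb <- x$candidates
  cat(sprintf("<uorf_transcript_set> %d candidates (%d passed) from %d uORFs\n",
              nrow(tb), sum(tb$passed), dplyr::n_distinct(tb$uorf_id)))
  invisible(x)
}

#' @export
tidy.uorf_transcript_set <- function(x, ...) {
  select(x$candidates, -"cds_nt")
}

#' @export
glance.uorf_transcript_set <- function(x, ...) {
  tb <- x$candidates
  tibble(
    n_candidates = nrow(tb),
    n_passed = sum(tb$passed),
    n_coverage_backed = sum(tb$provenance == "coverage_backed"),
    n_score_predicted = sum(tb$provenance == "score_predicted"),
    n_uorfs = dplyr::n_distinct(tb$uorf_id),
    n_non_aug = sum(tb$non_aug_start & tb$passed),
    n_identical_to_reference = sum(tb$identical_to_reference, na.rm = TRUE)
  )
}

#' @export
autoplot.uorf_transcript_set <- function(object, ...) {
  tb <- object$candidates |>
    mutate(outcome = dplyr::case_when(
      .data$passed ~ "passed",
      .data$premature_stop ~ "premature stop",
      !.data$frame_multiple_of_3 ~ "frameshift",
      TRUE ~ "too short"
    ))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$provenance, fill = .data$outcome)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "candidate transcripts",
                  title = "Validity-filter outcomes by evidence stream") +
    ggplot2::theme_minimal()
}

#' Write uORF-connected transcripts as GTF and protein FASTA
#'
#' @param x `uorf_transcript_set`.
#' @param dir Output directory.
#' @param ids Transcript ids to emit (default: all passing candidates).
#' @export
write_transcript_outputs <- function(x, dir, ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tb <- x$candidates
  if (is.null(ids)) ids <- tb$transcript_id[tb$passed]
  lines <- character(0)
  for (id in ids) {
    cc <- x$structures[[id]]
    row <- tb[tb$transcript_id == id, ]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; uorf_id "%s"; reference_transcript_id "%s"; provenance "%s";',
      cc$gene_id, id, cc$uorf_id, cc$reference_transcript_id, cc$provenance
    )
    span <- c(min(cc$exon_blocks$start), max(cc$exon_blocks$end))
    lines <- c(lines, sprintf("%s\tuorfconnect\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              cc$chrom, span[1] + 1L, span[2], cc$strand, attrs))
    for (k in seq_len(nrow(cc$exon_blocks))) {
      lines <- c(lines, sprintf("%s\tuorfconnect\texon\t%d\t%d\t.\t%s\t.\t%s",
                                cc$chrom, cc$exon_blocks$start[k] + 1L,
                                cc$exon_blocks$end[k], cc$strand, attrs))
    }
    fr <- gtf_frames(cc$cds_blocks$start, cc$cds_blocks$end, cc$strand)
    for (k in seq_len(nrow(cc$cds_blocks))) {
      lines <- c(lines, sprintf("%s\tuorfconnect\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                                cc$chrom, cc$cds_blocks$start[k] + 1L,
                                cc$cds_blocks$end[k], cc$strand, fr[k], attrs))
    }
  }
  readr::write_lines(lines, file.path(dir, "uorf_connected_transcripts.gtf"))
  prot <- tb[tb$transcript_id %in% ids & !is.na(tb$protein_aa), ]
  aa <- Biostrings::AAStringSet(setNames(sub("\\*$", "", prot$protein_aa),
                                         prot$transcript_id))
  Biostrings::writeXStringSet(aa, file.path(dir, "uorf_connected_proteins.faa"), width = 60L)
  readr::write_tsv(select(tb, -"cds_nt", -"protein_aa"),
                   file.path(dir, "transcript_filter_report.tsv"))
  invisible(dir)
}
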