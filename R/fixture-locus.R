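# Single-locus layout engine for the synthetic fixture generator.
#
# Each locus lives on its own small chromosome and carries one protein-coding
# gene whose 5'UTR hosts one uORF. The plus-strand layout is always built
# first; minus-strand loci are obtained by reverse-complementing the whole
# chromosome and flipping every recorded interval, so sense-strand assertions
# share one code path. All intervals are 0-based half-open.

UORF_LAYOUTS <- c("utr_contained", "spans_utr_exons", "overlaps_cds")
TARGET_MODES <- c(
  "perfect", "synonymous_only", "nonsynonymous", "relocate_gt_1kbp",
  "relocate_within_1kbp", "delete_uorf", "move_out_of_utr", "rename_gene"
)

FLANK5 <- 300L
FLANK3 <- 1500L   # long enough to host relocated uORF copies > 1 kbp away
PAD5 <- 40L       # UTR sequence upstream of the uORF
PAD3 <- 30L       # UTR sequence between uORF end and CDS start
UTR3 <- 40L
CDS_OVERLAP <- 7L # bases shared between uORF tail and CDS start in the
                  # overlaps_cds layout (engineered ...GCA TGC TGA tail)

#' Describe one synthetic locus
#'
#' A locus template fixes the ground truth for every downstream stage: the
#' uORF geometry, whether an engineered splice donor exists, which validity
#' filter (if any) a grafted transcript must fail, and the average-pLDDT
#' delta of the novel protein against its reference.
#'
#' @param gene_id,strand Gene identifier and strand of the locus.
#' @param uorf_length_nt uORF length in nucleotides; a multiple of 3 large
#'   enough to host a start and a stop codon.
#' @param n_utr_exons Number of 5'UTR exons (1, or 2 when the uORF spans two
#'   UTR exons).
#' @param uorf_layout `"utr_contained"` (uORF strictly inside the 5'UTR),
#'   `"spans_utr_exons"` (uORF split across two UTR exons), or
#'   `"overlaps_cds"` (uORF tail overlaps the annotated CDS start).
#' @param cds_exon_lengths_nt Optional explicit CDS exon lengths (the stop
#'   codon counts in the last exon); when `NULL` they are solved from
#'   `target_cds_ratio`.
#' @param has_valid_donor Engineer a GT splice donor inside the uORF (and
#'   emit junction evidence for it). When `FALSE` the uORF body is built
#'   from GT-free codons so the donor scan provably finds nothing.
#' @param inject_premature_stop Arrange the graft so the spliced novel CDS
#'   contains an in-frame stop while the uORF itself stays a valid ORF.
#' @param inject_frameshift Arrange the graft so the novel CDS length is not
#'   a multiple of 3.
#' @param target_cds_ratio Desired novel/reference CDS length ratio used to
#'   solve the donor placement and first CDS exon length (in `[0, 1.5]`).
#' @param evidence Evidence streams for the engineered junction(s): any of
#'   `"coverage"` (read-coverage-backed BED record) and `"predicted"`
#'   (scored candidate junction).
#' @param predicted_scores Donor/acceptor scores written for the predicted
#'   junction (mean >= 0.9 means it survives the score filter).
#' @param junction_coverage Read coverage recorded for the coverage-backed
#'   junction.
#' @param plddt_delta Average pLDDT difference (novel - reference) realised
#'   by the emitted per-residue profiles.
#' @return A `locus_template` list.
#' @export
locus_template <- function(gene_id = "SYNG0001",
                           strand = "+",
                           uorf_length_nt = 60L,
                           n_utr_exons = NULL,
                           uorf_layout = "utr_contained",
                           cds_exon_lengths_nt = NULL,
                           has_valid_donor = TRUE,
                           inject_premature_stop = FALSE,
                           inject_frameshift = FALSE,
                           target_cds_ratio = 1.0,
                           evidence = "coverage",
                           predicted_scores = c(0.95, 0.93),
                           junction_coverage = 100L,
                           plddt_delta = 2.0) {
  uorf_layout <- match.arg(uorf_layout, UORF_LAYOUTS)
  if (is.null(n_utr_exons)) {
    n_utr_exons <- if (uorf_layout == "spans_utr_exons") 2L else 1L
  }
  tpl <- list(
    gene_id = gene_id, strand = strand,
    uorf_length_nt = as.integer(uorf_length_nt),
    n_utr_exons = as.integer(n_utr_exons),
    uorf_layout = uorf_layout,
    cds_exon_lengths_nt = cds_exon_lengths_nt,
    has_valid_donor = isTRUE(has_valid_donor),
    inject_premature_stop = isTRUE(inject_premature_stop),
    inject_frameshift = isTRUE(inject_frameshift),
    target_cds_ratio = target_cds_ratio,
    evidence = evidence,
    predicted_scores = predicted_scores,
    junction_coverage = as.integer(junction_coverage),
    plddt_delta = plddt_delta
  )
  class(tpl) <- "locus_template"
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  len <- tpl$uorf_length_nt
  if (len < 6L) {
    abort(sprintf("impossible template for locus '%s': uorf_length %d cannot host start+stop",
                  tpl$gene_id, len))
  }
  if (len %% 3L != 0L) {
    abort(sprintf("impossible template for locus '%s': uorf_length %d is not a multiple of 3",
                  tpl$gene_id, len))
  }
  if (len < 30L) {
    abort(sprintf("impossible template for locus '%s': uorf_length %d is below the minimum of 30",
                  tpl$gene_id, len))
  }
  if (!tpl$strand %in% c("+", "-")) {
    abort(sprintf("locus '%s': strand must be '+' or '-'", tpl$gene_id))
  }
  if (!all(tpl$evidence %in% c("coverage", "predicted")) && length(tpl$evidence) > 0) {
    abort(sprintf("locus '%s': evidence must be a subset of {coverage, predicted}", tpl$gene_id))
  }
  if (tpl$uorf_layout == "spans_utr_exons" && tpl$n_utr_exons != 2L) {
    abort(sprintf("locus '%s': spans_utr_exons layout requires n_utr_exons = 2", tpl$gene_id))
  }
  if (tpl$target_cds_ratio < 0 || tpl$target_cds_ratio > 1.5) {
    abort(sprintf("locus '%s': target_cds_ratio must lie in [0, 1.5]", tpl$gene_id))
  }
  if (tpl$inject_premature_stop && tpl$inject_frameshift) {
    abort(sprintf("locus '%s': choose at most one injected defect", tpl$gene_id))
  }
  if (!is.null(tpl$cds_exon_lengths_nt) && sum(tpl$cds_exon_lengths_nt) %% 3L != 0L) {
    abort(sprintf("locus '%s': sum of cds_exon_lengths_nt must be a multiple of 3", tpl$gene_id))
  }
  invisible(tpl)
}

round_to_mult3 <- function(x) as.integer(round(x / 3)) * 3L

# Solve donor offset p and CDS exon geometry so that the grafted CDS
# (p uORF bases + CDS from exon 2 onwards) realises the requested outcome.
solve_geometry <- function(tpl) {
  len <- tpl$uorf_length_nt
  q_split <- if (tpl$uorf_layout == "spans_utr_exons") 9L else NA_integer_
  p_max <- if (tpl$uorf_layout == "overlaps_cds") len - 11L else len - 6L

  if (tpl$inject_premature_stop) {
    # p == 1 (mod 3): the junction codon is assembled from the engineered
    # 'T' before the donor GT plus the 'AA' at the start of CDS exon 2
    e1 <- 31L
    s2 <- 152L  # e1 + s2 multiple of 3
    p <- 13L
    if (p > p_max) abort(sprintf("locus '%s': uORF too short for a premature-stop graft", tpl$gene_id))
    return(list(p = p, e1 = e1, cds_rest = s2, q_split = q_split))
  }
  if (tpl$inject_frameshift) {
    e1 <- 33L
    s2 <- 150L
    p <- 13L  # p != e1 (mod 3) => graft length not a multiple of 3
    if (p > p_max) abort(sprintf("locus '%s': uORF too short for a frameshift graft", tpl$gene_id))
    return(list(p = p, e1 = e1, cds_rest = s2, q_split = q_split))
  }

  s2 <- 150L
  e1_min <- if (tpl$uorf_layout == "overlaps_cds") 9L else 6L
  if (!is.null(tpl$cds_exon_lengths_nt)) {
    e1 <- as.integer(tpl$cds_exon_lengths_nt[1])
    s2 <- as.integer(sum(tpl$cds_exon_lengths_nt[-1]))
    p_cands <- seq(6L, p_max, by = 1L)
    p_cands <- p_cands[p_cands %% 3L == e1 %% 3L]
    if (length(p_cands) == 0) abort(sprintf("locus '%s': no feasible donor placement", tpl$gene_id))
    p <- p_cands[which.min(abs((p_cands + s2) / (e1 + s2) - tpl$target_cds_ratio))]
    return(list(p = p, e1 = e1, cds_rest = s2, q_split = q_split,
                cds_exons = as.integer(tpl$cds_exon_lengths_nt)))
  }

  best <- NULL
  for (e1 in seq(e1_min, 600L, by = 3L)) {
    p_raw <- tpl$target_cds_ratio * (e1 + s2) - s2
    p <- round_to_mult3(p_raw)
    p <- max(6L, min(p, round_to_mult3(p_max - 2L)))
    if (p > p_max || p < 6L) next
    err <- abs((p + s2) / (e1 + s2) - tpl$target_cds_ratio)
    if (is.null(best) || err < best$err - 1e-12) {
      best <- list(p = p, e1 = e1, cds_rest = s2, q_split = q_split, err = err)
    }
  }
  if (is.null(best)) {
    abort(sprintf("impossible template for locus '%s': no CDS geometry achieves ratio %.2f",
                  tpl$gene_id, tpl$target_cds_ratio))
  }
  best$err <- NULL
  best
}

set_codon <- function(codons, base0, value) {
  stopifnot(base0 %% 3L == 0L)
  codons[base0 / 3L + 1L] <- value
  codons
}

# Build the uORF nucleotide sequence with all engineered features in place.
build_uorf_seq <- function(tpl, geom) {
  len <- tpl$uorf_length_nt
  n_cod <- len / 3L
  pool <- if (tpl$has_valid_donor) SAFE_CODONS else GT_FREE_CODONS
  codons <- sample(pool, n_cod, replace = TRUE)
  codons[1] <- "ATG"
  codons[2] <- "CTG"  # fixed mutation site for the synonymous/nonsynonymous modes
  codons[n_cod] <- "TAA"
  if (tpl$uorf_layout == "overlaps_cds") {
    # tail ...GCA TGC TGA: the last 7 bases double as the CDS start ATGCTGA
    codons[n_cod - 2L] <- "GCA"
    codons[n_cod - 1L] <- "TGC"
    codons[n_cod] <- "TGA"
  }
  if (tpl$has_valid_donor) {
    p <- geom$p
    if (tpl$inject_premature_stop || tpl$inject_frameshift) {
      codons <- set_codon(codons, p - 1L, "TGT")  # GT donor at p, 'T' ahead of it
    } else {
      codons <- set_codon(codons, p, "GTT")       # clean codon-boundary donor
      if ("predicted" %in% tpl$evidence && "coverage" %in% tpl$evidence) {
        codons <- set_codon(codons, p + 6L, "GTT")
      }
    }
  }
  paste(codons, collapse = "")
}

# Build the reference CDS (including its stop codon).
build_cds_seq <- function(tpl, geom, uorf_seq) {
  total <- geom$e1 + geom$cds_rest
  n_cod <- total / 3L
  codons <- sample(SAFE_CODONS, n_cod, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_cod] <- "TAA"
  if (tpl$uorf_layout == "overlaps_cds") {
    codons[2] <- "CTG"
    codons[3] <- "AAA"  # CDS starts ATG CTG AAA; first 7 bases == uORF tail
  }
  if (tpl$inject_premature_stop) {
    # reference codon spanning the exon1|exon2 boundary reads CAA;
    # the graft instead reads T + AA = premature TAA
    codons <- set_codon(codons, geom$e1 - 1L, "CAA")
  }
  paste(codons, collapse = "")
}

#' @export
print.locus_template <- function(x, ...) {
  cat(sprintf("<locus_template> %s (%s) uORF %d nt, layout %s\n",
              x$gene_id, x$strand, x$uorf_length_nt, x$uorf_layout))
  invisible(x)
}

# Assemble the plus-strand chromosome for one locus. Returns a locus record
# holding the sequence, annotation intervals, uORF blocks and graft truth.
build_locus_plus <- function(tpl) {
  geom <- solve_geometry(tpl)
  uorf_seq <- build_uorf_seq(tpl, geom)
  cds_seq <- build_cds_seq(tpl, geom, uorf_seq)
  len <- tpl$uorf_length_nt
  intron_len <- max(90L, len + 40L)

  cds_exons <- geom$cds_exons %||% c(geom$e1, geom$cds_rest)
  make_intron <- function() paste0("GT", random_dna(intron_len - 4L), "AG")

  chunks <- character(0)
  cursor <- 0L
  exons <- list()
  push <- function(s) {
    chunks[[length(chunks) + 1L]] <<- s
    start <- cursor
    cursor <<- cursor + nchar(s)
    c(start, cursor)
  }

  push(random_dna(FLANK5))
  uorf_blocks <- NULL
  if (tpl$uorf_layout == "spans_utr_exons") {
    q <- geom$q_split
    ex <- push(paste0(random_dna(PAD5), substr0(uorf_seq, 0L, q)))
    exons[[length(exons) + 1L]] <- ex
    b1 <- c(ex[2] - q, ex[2])
    push(make_intron())
    ex <- push(paste0(substr0(uorf_seq, q, len), random_dna(PAD3),
                      substr0(cds_seq, 0L, cds_exons[1])))
    exons[[length(exons) + 1L]] <- ex
    b2 <- c(ex[1], ex[1] + (len - q))
    uorf_blocks <- tibble(start = c(b1[1], b2[1]), end = c(b1[2], b2[2]))
    cds_first_start <- ex[2] - cds_exons[1]
  } else if (tpl$uorf_layout == "overlaps_cds") {
    ex <- push(paste0(random_dna(PAD5), substr0(uorf_seq, 0L, len - CDS_OVERLAP),
                      substr0(cds_seq, 0L, cds_exons[1])))
    exons[[length(exons) + 1L]] <- ex
    u_start <- ex[1] + PAD5
    uorf_blocks <- tibble(start = u_start, end = u_start + len)
    cds_first_start <- ex[1] + PAD5 + (len - CDS_OVERLAP)
    stopifnot(substr0(cds_seq, 0L, CDS_OVERLAP) ==
                substr0(uorf_seq, len - CDS_OVERLAP, len))
  } else {
    ex <- push(paste0(random_dna(PAD5), uorf_seq, random_dna(PAD3),
                      substr0(cds_seq, 0L, cds_exons[1])))
    exons[[length(exons) + 1L]] <- ex
    u_start <- ex[1] + PAD5
    uorf_blocks <- tibble(start = u_start, end = u_start + len)
    cds_first_start <- ex[2] - cds_exons[1]
  }

  cds <- list(c(cds_first_start, cds_first_start + cds_exons[1]))
  consumed <- cds_exons[1]
  for (i in seq_along(cds_exons)[-1]) {
    push(make_intron())
    piece <- substr0(cds_seq, consumed, consumed + cds_exons[i])
    consumed <- consumed + cds_exons[i]
    last <- i == length(cds_exons)
    ex <- push(paste0(piece, if (last) random_dna(UTR3) else ""))
    exons[[length(exons) + 1L]] <- ex
    cds[[length(cds) + 1L]] <- c(ex[1], ex[1] + cds_exons[i])
  }
  gene_end <- cursor
  push(random_dna(FLANK3))

  exons <- tibble(
    start = purrr::map_int(exons, ~ as.integer(.x[1])),
    end = purrr::map_int(exons, ~ as.integer(.x[2]))
  )
  cds <- tibble(
    start = purrr::map_int(cds, ~ as.integer(.x[1])),
    end = purrr::map_int(cds, ~ as.integer(.x[2]))
  )

  list(
    chrom = paste0("chr_", tpl$gene_id),
    seq = paste(chunks, collapse = ""),
    strand = "+",
    gene_id = tpl$gene_id,
    gene_id_annot = tpl$gene_id,
    tx_id = paste0(sub("^SYNG", "SYNT", tpl$gene_id), ".1"),
    exons = exons, cds = cds,
    gene_start = exons$start[1], gene_end = gene_end,
    uorf_blocks = uorf_blocks,
    uorf_nt = uorf_seq, uorf_aa = translate_nt(uorf_seq),
    cds_nt = cds_seq,
    geom = geom,
    template = tpl
  )
}

flip_record <- function(rec) {
  L <- nchar(rec$seq)
  flip_tbl <- function(tb) {
    tibble(start = L - tb$end, end = L - tb$start) |> arrange(.data$start)
  }
  rec$seq <- revcomp(rec$seq)
  rec$exons <- flip_tbl(rec$exons)
  rec$cds <- flip_tbl(rec$cds)
  rec$uorf_blocks <- flip_tbl(rec$uorf_blocks)
  new_start <- L - rec$gene_end
  rec$gene_end <- L - rec$gene_start
  rec$gene_start <- new_start
  rec$strand <- "-"
  rec
}

# Genomic coordinates of the engineered junctions, computed on the final
# orientation. Returns a tibble of junction records (intron interval
# [donor, acceptor) on the genome, sense interpreted through `strand`).
locus_junctions <- function(rec) {
  tpl <- rec$template
  if (!tpl$has_valid_donor || length(tpl$evidence) == 0) {
    return(tibble(
      chrom = character(), donor = integer(), acceptor = integer(),
      strand = character(), provenance = character(), coverage = integer(),
      donor_score = double(), acceptor_score = double(), uorf_offset = integer()
    ))
  }
  streams <- tpl$evidence
  offs <- c(coverage = rec$geom$p, predicted = rec$geom$p)
  if (all(c("coverage", "predicted") %in% streams) &&
      !tpl$inject_premature_stop && !tpl$inject_frameshift) {
    offs["predicted"] <- rec$geom$p + 6L
  }
  # acceptor = first exonic base of CDS exon 2 in transcription order
  cds_tx <- if (rec$strand == "+") rec$cds else rec$cds[rev(seq_len(nrow(rec$cds))), ]
  a_blk <- cds_tx[2, ]
  rows <- purrr::map(streams, function(st) {
    off <- offs[[st]]
    m <- splice_offset_to_genomic(rec$uorf_blocks, rec$strand, off, width = 2L)
    stopifnot(m$contiguous)
    if (rec$strand == "+") {
      donor <- m$pos[1]
      acceptor <- a_blk$start
    } else {
      donor <- a_blk$end
      acceptor <- m$pos[1] + 1L
    }
    tibble(
      chrom = rec$chrom, donor = as.integer(donor), acceptor = as.integer(acceptor),
      strand = rec$strand, provenance = if (st == "coverage") "coverage_backed" else "score_predicted",
      coverage = if (st == "coverage") tpl$junction_coverage else NA_integer_,
      donor_score = if (st == "predicted") tpl$predicted_scores[1] else NA_real_,
      acceptor_score = if (st == "predicted") tpl$predicted_scores[2] else NA_real_,
      uorf_offset = as.integer(off)
    )
  })
  bind_rows(rows)
}

# Apply a target-genome mutation mode to a plus-strand locus record.
apply_target_mode <- function(rec, mode) {
  mode <- match.arg(mode, TARGET_MODES)
  wipe_uorf <- function(r) {
    for (i in seq_len(nrow(r$uorf_blocks))) {
      w <- r$uorf_blocks$end[i] - r$uorf_blocks$start[i]
      substr0(r$seq, r$uorf_blocks$start[i]) <- random_dna(w)
    }
    r
  }
  place_copy <- function(r, gap) {
    at <- r$gene_end + gap
    if (at + nchar(r$uorf_nt) > nchar(r$seq) - 5L) {
      abort(sprintf("locus '%s': chromosome too short to relocate the uORF", r$gene_id))
    }
    substr0(r$seq, at) <- r$uorf_nt
    r
  }
  if (mode == "perfect") return(rec)
  if (mode == "rename_gene") {
    rec$gene_id_annot <- paste0(rec$gene_id, "X")
    return(rec)
  }
  if (mode == "synonymous_only") {
    # codon 2 of the uORF is always CTG (Leu); CTG -> CTT keeps the protein
    pos <- rec$uorf_blocks$start[1] + 5L
    substr0(rec$seq, pos) <- "T"
    return(rec)
  }
  if (mode == "nonsynonymous") {
    # CTG -> CCG swaps Leu for Pro
    pos <- rec$uorf_blocks$start[1] + 4L
    substr0(rec$seq, pos) <- "C"
    return(rec)
  }
  rec <- wipe_uorf(rec)
  if (mode == "delete_uorf") return(rec)
  if (mode == "relocate_gt_1kbp") return(place_copy(rec, 1200L))
  if (mode == "relocate_within_1kbp") return(place_copy(rec, 400L))
  if (mode == "move_out_of_utr") {
    # drop an exact copy inside the first CDS intron (keeps GT/AG edges)
    gaps_after <- rec$exons$start[-1]
    gaps_before <- rec$exons$end[-nrow(rec$exons)]
    # the intron immediately following the exon that carries the CDS start
    i <- which(gaps_before >= rec$cds$start[1])[1]
    if (is.na(i)) abort(sprintf("locus '%s': no intron available downstream of the CDS start", rec$gene_id))
    at <- gaps_before[i] + 20L
    if (at + nchar(rec$uorf_nt) > gaps_after[i] - 2L) {
      abort(sprintf("locus '%s': intron too short to host the relocated uORF", rec$gene_id))
    }
    substr0(rec$seq, at) <- rec$uorf_nt
    return(rec)
  }
  rec
}

# Expected conservation rubric outcome for a mode/layout combination; truth
# is fixed by construction, the assessments must reproduce it.
expected_assessment <- function(mode, layout) {
  in_utr <- layout != "overlaps_cds"
  row <- switch(mode,
    perfect              = list(seq = TRUE,  utr = in_utr, locus = TRUE,  displaced = FALSE),
    synonymous_only      = list(seq = TRUE,  utr = in_utr, locus = TRUE,  displaced = FALSE),
    nonsynonymous        = list(seq = FALSE, utr = in_utr, locus = TRUE,  displaced = FALSE),
    delete_uorf          = list(seq = FALSE, utr = FALSE,  locus = FALSE, displaced = FALSE),
    relocate_gt_1kbp     = list(seq = TRUE,  utr = FALSE,  locus = FALSE, displaced = TRUE),
    relocate_within_1kbp = list(seq = TRUE,  utr = FALSE,  locus = FALSE, displaced = FALSE),
    move_out_of_utr      = list(seq = TRUE,  utr = FALSE,  locus = TRUE,  displaced = FALSE),
    rename_gene          = list(seq = TRUE,  utr = in_utr, locus = FALSE, displaced = FALSE)
  )
  if (mode == "delete_uorf") {
    score <- 0L
  } else {
    score <- rubric_score(row$seq, row$utr, row$locus)
  }
  list(score = score, conserved = score >= 4L && !row$displaced,
       displaced = row$displaced)
}
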