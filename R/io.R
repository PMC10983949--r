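# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA (Biostrings), GTF (rtracklayer on the way in, hand-emitted lines on
# the way out for exact attribute control), junction BED6+coverage, the uORF
# table, scored-junction TSVs and PAF/SAM alignment adapters.
#
# Internal annotation tables are tibbles with columns
#   chrom, start, end (0-based half-open), strand, type, gene_id, transcript_id
# GTF is converted to/from 1-based inclusive at the boundary.

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_genome_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a GTF annotation into the internal annotation table
#'
#' @param path GTF file with gene/transcript/exon/CDS features carrying
#'   `gene_id`/`transcript_id` attributes.
#' @return Tibble with 0-based half-open `start`/`end` columns.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  tb <- as_tibble(as.data.frame(gr))
  tibble(
    chrom = as.character(tb$seqnames),
    start = as.integer(tb$start) - 1L,
    end = as.integer(tb$end),
    strand = as.character(tb$strand),
    type = as.character(tb$type),
    gene_id = as.character(tb$gene_id),
    transcript_id = if ("transcript_id" %in% names(tb)) as.character(tb$transcript_id) else NA_character_
  )
}

gtf_frames <- function(starts, ends, strand) {
  # phase of each CDS segment in transcription order
  lens <- ends - starts
  ord <- if (strand == "-") rev(seq_along(lens)) else seq_along(lens)
  cum <- c(0L, cumsum(lens[ord]))
  fr <- (3L - cum[-length(cum)] %% 3L) %% 3L
  out <- integer(length(lens))
  out[ord] <- fr
  out
}

#' Write the internal annotation table as GTF
#' @param annot Annotation tibble (0-based half-open).
#' @param path Output path.
#' @export
write_annotation_gtf <- function(annot, path) {
  lines <- character(0)
  for (g in unique(annot$gene_id)) {
    ga <- annot[annot$gene_id == g, ]
    grow <- ga[ga$type == "gene", ]
    fmt <- function(row, type, attrs, frame = ".") {
      sprintf("%s\tuorfconnect\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              row$chrom, type, row$start + 1L, row$end, row$strand, frame, attrs)
    }
    gattr <- sprintf('gene_id "%s"; gene_biotype "protein_coding";', g)
    lines <- c(lines, fmt(grow[1, ], "gene", gattr))
    for (tx in unique(stats::na.omit(ga$transcript_id))) {
      ta <- ga[!is.na(ga$transcript_id) & ga$transcript_id == tx, ]
      tattr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding";', g, tx)
      trow <- ta[ta$type == "transcript", ]
      lines <- c(lines, fmt(trow[1, ], "transcript", tattr))
      ex <- ta[ta$type == "exon", ] |> arrange(.data$start)
      ord <- if (trow$strand[1] == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
      for (k in seq_len(nrow(ex))) {
        eattr <- sprintf('%s exon_number "%d";', tattr, which(ord == k))
        lines <- c(lines, fmt(ex[k, ], "exon", eattr))
      }
      cds <- ta[ta$type == "CDS", ] |> arrange(.data$start)
      if (nrow(cds) > 0) {
        fr <- gtf_frames(cds$start, cds$end, trow$strand[1])
        for (k in seq_len(nrow(cds))) {
          lines <- c(lines, fmt(cds[k, ], "CDS", tattr, frame = as.character(fr[k])))
        }
      }
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write the uORF definition table
#'
#' Tab-separated with columns `uorf_id`, `chrom`, `strand`, `blocks`
#' (comma-separated `start-end` 0-based half-open intervals in genomic
#' order), `host_transcript_id`, `gene_id`.
#'
#' @param path TSV path.
#' @return Tibble, one row per uORF, with a `blocks` list-column of tibbles.
#' @export
read_uorf_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  needed <- c("uorf_id", "chrom", "strand", "blocks", "host_transcript_id", "gene_id")
  if (!all(needed %in% names(tb))) {
    abort(sprintf("uORF table '%s' is missing columns: %s", path,
                  paste(setdiff(needed, names(tb)), collapse = ", ")))
  }
  tb$blocks <- purrr::map(tb$blocks, parse_blocks)
  tb
}

parse_blocks <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts, "^(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) abort(sprintf("malformed blocks field '%s'", s))
  tb <- tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
  if (nrow(tb) > 2L) {
    abort(sprintf("uORFs with more than two blocks are not supported (got %d)", nrow(tb)))
  }
  if (any(tb$end <= tb$start) || is.unsorted(tb$start)) {
    abort(sprintf("blocks '%s' must be ordered, non-overlapping intervals", s))
  }
  tb
}

format_blocks <- function(blocks) {
  paste(sprintf("%d-%d", blocks$start, blocks$end), collapse = ",")
}

#' @rdname read_uorf_table
#' @param uorfs uORF tibble with a `blocks` list-column.
#' @export
write_uorf_table <- function(uorfs, path) {
  out <- uorfs
  out$blocks <- purrr::map_chr(uorfs$blocks, format_blocks)
  readr::write_tsv(out[, c("uorf_id", "chrom", "strand", "blocks",
                           "host_transcript_id", "gene_id")], path)
  invisible(path)
}

#' Attach spliced sequences and translations to a uORF table
#'
#' @param uorfs uORF tibble (see [read_uorf_table()]).
#' @param genome Named character vector of chromosome sequences.
#' @return The tibble with `nt_sequence` and `aa_sequence` columns added.
#' @export
hydrate_uorfs <- function(uorfs, genome) {
  uorfs$nt_sequence <- purrr::pmap_chr(
    list(uorfs$chrom, uorfs$blocks, uorfs$strand),
    function(chrom, blocks, strand) spliced_seq(genome, chrom, blocks, strand)
  )
  bad <- nchar(uorfs$nt_sequence) %% 3L != 0L
  if (any(bad)) {
    abort(sprintf("uORF '%s' has length %d, not a multiple of 3",
                  uorfs$uorf_id[bad][1], nchar(uorfs$nt_sequence[bad][1])))
  }
  uorfs$aa_sequence <- purrr::map_chr(uorfs$nt_sequence, translate_nt)
  uorfs
}

#' Read and write splice-junction evidence (BED6 + coverage)
#'
#' Junction records span the intron, 0-based half-open; column 7 carries the
#' summed read coverage supporting the junction.
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `donor` (intron start), `acceptor` (intron
#'   end), `strand`, `coverage`.
#' @export
read_junction_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 7L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      abort(sprintf("malformed junction BED line %d in '%s': %s", i, path, ln))
    }
    tibble(chrom = f[1], donor = as.integer(f[2]), acceptor = as.integer(f[3]),
           name = f[4], strand = f[6], coverage = as.integer(f[7]))
  })
  bind_rows(rows)
}

#' @rdname read_junction_bed
#' @param junctions Junction tibble.
#' @export
write_junction_bed <- function(junctions, path) {
  nm <- if ("name" %in% names(junctions)) junctions$name else
    sprintf("jx_%03d", seq_len(nrow(junctions)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d",
                   junctions$chrom, junctions$donor, junctions$acceptor,
                   nm, junctions$strand, junctions$coverage)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read and write scored candidate junctions
#'
#' Tab-separated with columns `chrom`, `donor` (0-based intron start),
#' `acceptor` (intron end), `strand`, `donor_score`, `acceptor_score`.
#' @param path TSV path.
#' @export
read_scored_junctions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", donor = "i", acceptor = "i", strand = "c",
    donor_score = "d", acceptor_score = "d"
  ))
}

#' @rdname read_scored_junctions
#' @param scores Scored-junction tibble.
#' @export
write_scored_junctions <- function(scores, path) {
  readr::write_tsv(scores[, c("chrom", "donor", "acceptor", "strand",
                              "donor_score", "acceptor_score")], path)
  invisible(path)
}

#' Parse minimap2-style PAF alignments into alignment hits
#'
#' Consumes precomputed alignments of uORF queries against a target genome
#' so that no aligner needs to run. Mismatch counts use the `NM:i` tag when
#' present, else `alignment block length - residue matches`.
#'
#' @param path PAF file.
#' @return Tibble of genomic-space hits (query name, target, interval,
#'   strand, mismatches, full-length flag).
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      abort(sprintf("unparsable PAF line %d in '%s': %s", i, path, ln))
    }
    num <- suppressWarnings(as.integer(f[c(2:4, 7:11)]))
    if (anyNA(num)) abort(sprintf("unparsable PAF line %d in '%s': %s", i, path, ln))
    nm <- stringr::str_match(ln, "NM:i:(\\d+)")[, 2]
    n_mis <- if (!is.na(nm)) as.integer(nm) else as.integer(f[11]) - as.integer(f[10])
    tibble(
      query = f[1], qlen = as.integer(f[2]), qstart = as.integer(f[3]),
      qend = as.integer(f[4]), strand = f[5], chrom = f[6],
      start = as.integer(f[8]), end = as.integer(f[9]),
      n_mismatches = n_mis,
      full_length = as.integer(f[3]) == 0L && as.integer(f[4]) == as.integer(f[2])
    )
  })
  bind_rows(rows)
}

#' Parse SAM text alignments into alignment hits
#'
#' Minimal adapter for single-end ungapped-or-simple CIGAR records; clipped
#' alignments are treated as not full-length.
#'
#' @param path SAM file.
#' @return Tibble of hits as in [read_paf()].
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[4])))) {
      abort(sprintf("unparsable SAM line %d in '%s': %s", i, path, ln))
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) return(NULL)
    cigar <- f[6]
    ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
    if (nrow(ops) == 0L) abort(sprintf("unparsable SAM line %d in '%s': %s", i, path, ln))
    widths <- as.integer(ops[, 2])
    types <- ops[, 3]
    ref_span <- sum(widths[types %in% c("M", "D", "N", "=", "X")])
    clipped <- any(types %in% c("S", "H"))
    qlen <- nchar(f[10])
    nm <- stringr::str_match(ln, "NM:i:(\\d+)")[, 2]
    tibble(
      query = f[1], qlen = qlen, qstart = 0L, qend = qlen,
      strand = if (bitwAnd(flag, 16L) == 16L) "-" else "+",
      chrom = f[3], start = as.integer(f[4]) - 1L,
      end = as.integer(f[4]) - 1L + ref_span,
      n_mismatches = if (!is.na(nm)) as.integer(nm) else 0L,
      full_length = !clipped && sum(widths[types %in% c("M", "=", "X", "I")]) == qlen
    )
  })
  bind_rows(purrr::compact(rows))
}
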