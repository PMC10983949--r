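# Low-level sequence helpers shared by the fixture generator and the
# analysis modules. All coordinates handled here are 0-based half-open;
# sequences are plain upper-case character scalars, with Biostrings doing
# the heavy lifting (translation, reverse complement, pattern matching).

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sense codons used for random ORF/CDS bodies; excludes stops so a random
# body can never terminate early in its own frame
SAFE_CODONS <- c(
  "GCT", "GCA", "GCC", "AAA", "AAG", "CCT", "CCA", "CTG", "CTC", "GAA",
  "GAC", "TTC", "ATC", "CAC", "AGA", "AGC", "ACA", "TGG", "TAC", "GGC"
)

# codons built only from A and C: a body drawn from these can never contain
# a GT dinucleotide, even across codon boundaries
GT_FREE_CODONS <- c("AAA", "AAC", "ACA", "ACC", "CAA", "CAC", "CCA", "CCC")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Stops are rendered as `*`. The input length must be a multiple of 3.
#'
#' @param nt Character scalar, sense-strand nucleotide sequence.
#' @return Character scalar amino-acid sequence.
#' @export
translate_nt <- function(nt) {
  if (nchar(nt) %% 3L != 0L) {
    abort(sprintf("cannot translate sequence of length %d (not a multiple of 3)", nchar(nt)))
  }
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
}

# translation of an arbitrary-phase window: trims the 3' remainder
translate_frame <- function(nt, offset = 0L) {
  sub <- substr(nt, offset + 1L, nchar(nt))
  keep <- nchar(sub) - nchar(sub) %% 3L
  if (keep < 3L) return("")
  translate_nt(substr(sub, 1L, keep))
}

substr0 <- function(x, start0, end0) {
  # 0-based half-open substring
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

`substr0<-` <- function(x, start0, value) {
  substr(x, start0 + 1L, start0 + nchar(value)) <- value
  x
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Extract a spliced sequence from a genome
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param blocks Tibble with `start`/`end` columns, 0-based half-open, in
#'   genomic order.
#' @param strand `"+"` or `"-"`; minus-strand results are
#'   reverse-complemented and blocks are stitched in transcription order.
#' @return Character scalar sense-strand sequence.
#' @export
spliced_seq <- function(seqs, chrom, blocks, strand = "+") {
  if (!chrom %in% names(seqs)) {
    abort(sprintf("sequence '%s' not present in genome", chrom))
  }
  pieces <- purrr::map2_chr(blocks$start, blocks$end, ~ substr0(seqs[[chrom]], .x, .y))
  out <- paste(pieces, collapse = "")
  if (strand == "-") out <- revcomp(out) else out
}

# Map an offset in the spliced (sense) sequence of a block set to its genomic
# position. Returns NA when the offset and offset+1 are not genomically
# adjacent (used to reject donors spanning a block boundary).
splice_offset_to_genomic <- function(blocks, strand, offset, width = 1L) {
  lens <- blocks$end - blocks$start
  total <- sum(lens)
  stopifnot(offset >= 0L, offset + width <= total)
  pos <- integer(width)
  for (k in seq_len(width)) {
    off <- offset + k - 1L
    if (strand == "+") {
      cum <- cumsum(lens)
      i <- which(off < cum)[1L]
      prev <- if (i == 1L) 0L else cum[i - 1L]
      pos[k] <- blocks$start[i] + (off - prev)
    } else {
      # transcription order is last block first on the minus strand
      lens_r <- rev(lens)
      cum <- cumsum(lens_r)
      i <- which(off < cum)[1L]
      prev <- if (i == 1L) 0L else cum[i - 1L]
      j <- nrow(blocks) + 1L - i
      pos[k] <- blocks$end[j] - 1L - (off - prev)
    }
  }
  contiguous <- if (width == 1L) TRUE else all(diff(pos) == (if (strand == "+") 1L else -1L))
  list(pos = pos, contiguous = contiguous)
}
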