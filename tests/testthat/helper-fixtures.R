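# Shared fixtures (memoised per session) and fully independent oracles.
# The oracles deliberately avoid the package's sequence machinery: they use
# their own FASTA/GTF parsing and raw base-R string surgery, so that
# equivalence tests compare two genuinely different routes.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, force(expr), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

fixture_dir <- function(name) file.path(tempdir(), "uorfconnect-tests", name)

# eight loci, one target genome exercising every mutation mode
mode_fixture <- function() {
  cached("mode_fixture", {
    modes <- c("perfect", "synonymous_only", "nonsynonymous", "delete_uorf",
               "relocate_gt_1kbp", "relocate_within_1kbp", "move_out_of_utr",
               "rename_gene")
    templates <- lapply(1:8, function(i) {
      locus_template(gene_id = sprintf("SYNG%04d", i),
                     strand = if (i %% 2 == 0) "-" else "+")
    })
    fx <- simulate_uorf_fixture(fixture_dir("modes"), n_loci = 8, seed = 42,
                                templates = templates,
                                target_modes = list(genomeA = modes))
    list(fx = fx, modes = modes)
  })
}

mixed_fixture <- function() {
  cached("mixed_fixture", {
    simulate_uorf_fixture(fixture_dir("mixed"), n_loci = 12, seed = 7)
  })
}

mixed_pipeline <- function() {
  cached("mixed_pipeline", {
    cfg <- fixture_pipeline_config(mixed_fixture(), out_dir = fixture_dir("mixed-out"))
    suppressMessages(run_uorf_pipeline(cfg))
  })
}

builder_inputs <- function() {
  cached("builder_inputs", {
    fx <- mixed_fixture()
    genome <- read_genome_fasta(fx$paths$source_genome)
    annot <- read_annotation(fx$paths$source_annotation)
    uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
    list(fx = fx, genome = genome, annot = annot, uorfs = uorfs)
  })
}

read_target <- function(fx, tname) {
  list(genome = read_genome_fasta(fx$paths$targets[[tname]]$genome),
       annotation = read_annotation(fx$paths$targets[[tname]]$annotation))
}

# ---------------------------------------------------------------------------
# independent oracle machinery (base R only)

oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[idx])
  bounds <- c(idx, length(lines) + 1L)
  out <- vapply(seq_along(idx), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, character(1))
  names(out) <- nm
  out
}

oracle_read_gtf <- function(path) {
  lines <- readLines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(f, function(x) {
    data.frame(
      chrom = x[1], type = x[3],
      start = as.integer(x[4]) - 1L, end = as.integer(x[5]),  # to 0-based
      strand = x[7],
      gene_id = sub('.*gene_id "([^"]+)".*', "\\1", x[9]),
      transcript_id = if (grepl("transcript_id", x[9]))
        sub('.*transcript_id "([^"]+)".*', "\\1", x[9]) else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_translate <- function(nt) {
  codes <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G"
  )
  n <- nchar(nt) %/% 3L
  paste(codes[substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))], collapse = "")
}

# every 0-based start of an exact full-length occurrence, one strand
oracle_exact_positions <- function(query, subject) {
  qn <- nchar(query); sn <- nchar(subject)
  if (sn < qn) return(integer(0))
  starts <- seq_len(sn - qn + 1L)
  hits <- starts[substring(subject, starts, starts + qn - 1L) == query]
  hits - 1L
}

# Independent splice-and-filter oracle working purely from emitted files.
# Returns one row per (uorf, junction) with the grafted CDS and the three
# filter verdicts, computed by raw string surgery.
oracle_graft_report <- function(fx, min_cds_ratio = 0.9) {
  genome <- oracle_read_fasta(fx$paths$source_genome)
  gtf <- oracle_read_gtf(fx$paths$source_annotation)
  uorfs <- read.delim(fx$paths$uorf_table, stringsAsFactors = FALSE)
  bed <- read.delim(fx$paths$junction_bed, header = FALSE,
                    col.names = c("chrom", "donor", "acceptor", "name",
                                  "score", "strand", "coverage"),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(bed))) {
    j <- bed[i, ]
    for (k in seq_len(nrow(uorfs))) {
      u <- uorfs[k, ]
      if (u$chrom != j$chrom || u$strand != j$strand) next
      blocks <- do.call(rbind, lapply(strsplit(u$blocks, ",")[[1]], function(b) {
        as.integer(strsplit(b, "-")[[1]])
      }))
      d <- if (j$strand == "+") j$donor else j$acceptor - 1L
      a <- if (j$strand == "+") j$acceptor else j$donor - 1L
      in_uorf <- any(blocks[, 1] <= d & d < blocks[, 2])
      if (!in_uorf) next
      # uORF positions in ascending genomic order
      upos <- unlist(apply(blocks, 1, function(b) seq.int(b[1], b[2] - 1L)))
      prefix_pos <- if (j$strand == "+") upos[upos < d] else upos[upos > d]
      cds_rows <- gtf[gtf$type == "CDS" & gtf$transcript_id == u$host_transcript_id, ]
      cpos <- unlist(mapply(seq.int, cds_rows$start, cds_rows$end - 1L, SIMPLIFY = FALSE))
      down_pos <- if (j$strand == "+") cpos[cpos >= a] else cpos[cpos <= a]
      take <- function(pos) {
        pos <- sort(pos)
        s <- paste(substring(genome[[u$chrom]], pos + 1L, pos + 1L), collapse = "")
        if (j$strand == "-") oracle_revcomp(s) else s
      }
      cds_nt <- paste0(take(prefix_pos), take(down_pos))
      ref_nt <- take(cpos)
      len <- nchar(cds_nt)
      n_full <- len %/% 3L
      codons <- substring(cds_nt, 3 * seq_len(n_full) - 2, 3 * seq_len(n_full))
      internal <- if (len %% 3L == 0L) codons[-n_full] else codons
      premature <- any(internal %in% c("TAA", "TAG", "TGA"))
      frame_ok <- len %% 3L == 0L
      ratio <- len / nchar(ref_nt)
      rows[[length(rows) + 1L]] <- data.frame(
        uorf_id = u$uorf_id, donor = j$donor, acceptor = j$acceptor,
        cds_nt = cds_nt, premature_stop = premature,
        frame_multiple_of_3 = frame_ok, length_ratio = ratio,
        passed = !premature && frame_ok && ratio >= min_cds_ratio,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# seeded sweep of randomised locus templates for the filter-completeness check
random_sweep_templates <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("clean", "premature", "frameshift", "short", "long"), 1,
                     prob = c(0.4, 0.15, 0.15, 0.2, 0.1))
      locus_template(
        gene_id = sprintf("SYNG%04d", i),
        strand = sample(c("+", "-"), 1),
        uorf_layout = sample(c("utr_contained", "spans_utr_exons"), 1),
        uorf_length_nt = sample(c(45L, 60L, 90L), 1),
        inject_premature_stop = kind == "premature",
        inject_frameshift = kind == "frameshift",
        target_cds_ratio = switch(kind, short = runif(1, 0.5, 0.85),
                                  long = runif(1, 1.0, 1.3), 1.0),
        junction_coverage = sample(10:200, 1),
        plddt_delta = round(runif(1, -3, 3), 2)
      )
    })
  })
}

sweep_fixture <- function() {
  cached("sweep_fixture", {
    templates <- random_sweep_templates(200, seed = 2024)
    simulate_uorf_fixture(fixture_dir("sweep"), n_loci = 200, seed = 515,
                          templates = templates,
                          target_modes = setNames(list(), character(0)))
  })
}

sweep_transcripts <- function() {
  cached("sweep_transcripts", {
    fx <- sweep_fixture()
    genome <- read_genome_fasta(fx$paths$source_genome)
    annot <- read_annotation(fx$paths$source_annotation)
    uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
    jx <- load_junctions(fx$paths$junction_bed, uorfs, annot, genome)
    build_transcripts(uorfs, jx, annot, genome)
  })
}
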