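# Conservation rubric: additivity, mode-specific levels, dual-space
# reconciliation, protein fallback, exhaustive-scan oracle equivalence,
# strand symmetry, monotonicity and intersection summaries.

test_that("rubric score is the sum of satisfied criterion weights", {
  combos <- expand.grid(s = c(FALSE, TRUE), u = c(FALSE, TRUE), l = c(FALSE, TRUE))
  scores <- mapply(rubric_score, combos$s, combos$u, combos$l)
  expect_setequal(scores, 0:7)
  for (i in seq_len(nrow(combos))) {
    expect_identical(scores[i],
                     4L * combos$s[i] + 2L * combos$u[i] + 1L * combos$l[i])
  }
})

test_that("every mutation mode is scored at its designed conservation level", {
  md <- mode_fixture()
  fx <- md$fx
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  res <- assess_conservation(uorfs, fx$paths$targets["genomeA"])
  got <- tidy(res)
  want <- fx$truth$conservation
  for (i in seq_len(nrow(want))) {
    g <- got[got$uorf_id == want$uorf_id[i], ]
    expect_identical(g$score, as.integer(want$score[i]),
                     label = sprintf("score for mode %s", want$mode[i]))
    expect_identical(g$conserved, want$conserved[i],
                     label = sprintf("conserved for mode %s", want$mode[i]))
    expect_identical(g$displaced_gt_1kbp, want$displaced_gt_1kbp[i],
                     label = sprintf("displacement for mode %s", want$mode[i]))
  }
  # the assessed flags recompose the score additively
  expect_identical(got$score,
                   rubric_score(got$sequence_match, got$utr_containment, got$locus_match))
})

test_that("uORFs spanning two 5'UTR exons are rescued by transcriptomic alignment", {
  fx <- cached("spans_fixture", {
    templates <- list(
      locus_template(gene_id = "SYNG0001", uorf_layout = "spans_utr_exons", strand = "+"),
      locus_template(gene_id = "SYNG0002", uorf_layout = "spans_utr_exons", strand = "-")
    )
    simulate_uorf_fixture(fixture_dir("spans"), n_loci = 2, seed = 3,
                          templates = templates,
                          target_modes = list(genomeA = "perfect"))
  })
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  tgt <- read_target(fx, "genomeA")
  for (i in 1:2) {
    hits <- find_uorf_matches(uorfs[i, ], tgt$genome, tgt$annotation)
    exact <- hits[hits$n_mismatches == 0, ]
    expect_identical(unique(exact$space), "transcriptomic")
    a <- score_conservation(uorfs[i, ], hits, tgt$annotation)
    expect_identical(a$score, 7L)
    expect_identical(a$winning_space, "transcriptomic")
  }
})

test_that("protein fallback tries all six frames", {
  nt <- "ATGCTGGCAAAAGAATTCTAA"
  aa <- translate_nt(nt)
  # synonymous change (CTG -> CTC): protein preserved
  syn <- sub("CTG", "CTC", nt)
  expect_true(protein_fallback(aa, syn))
  # non-synonymous change (CTG -> CCG): protein differs
  expect_false(protein_fallback(aa, sub("CTG", "CCG", nt)))
  # hit recorded on the opposite strand: reverse-complement frame succeeds
  expect_true(protein_fallback(aa, uorfconnect:::revcomp(syn)))
  # fallback is only consulted for mismatched full-length hits, and feeds
  # the sequence-match criterion in the assessments
  md <- mode_fixture()
  fx <- md$fx
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  tgt <- read_target(fx, "genomeA")
  i_syn <- which(md$modes == "synonymous_only")
  hits <- find_uorf_matches(uorfs[i_syn, ], tgt$genome, tgt$annotation)
  mm <- hits[hits$n_mismatches > 0, ]
  expect_gt(nrow(mm), 0)
  expect_true(all(mm$protein_identical))
  expect_true(all(is.na(hits$protein_identical[hits$n_mismatches == 0])))
})

test_that("built-in exact search equals a brute-force substring scan", {
  fx <- mixed_fixture()
  tgt <- read_target(fx, "genomeA")
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  for (i in seq_len(min(6, nrow(uorfs)))) {
    u <- uorfs[i, ]
    hits <- find_uorf_matches(u, tgt$genome, tgt$annotation)
    exact_gen <- hits[hits$space == "genomic" & hits$n_mismatches == 0, ]
    brute <- do.call(rbind, lapply(names(tgt$genome), function(nm) {
      subj <- tgt$genome[[nm]]
      fwd <- oracle_exact_positions(u$nt_sequence, subj)
      rev <- oracle_exact_positions(oracle_revcomp(u$nt_sequence), subj)
      rbind(
        if (length(fwd)) data.frame(target = nm, start = fwd, strand = "+"),
        if (length(rev)) data.frame(target = nm, start = rev, strand = "-")
      )
    }))
    if (is.null(brute)) {
      expect_identical(nrow(exact_gen), 0L)  # two-exon uORFs: no genomic hit
    } else {
      got <- exact_gen[order(exact_gen$target, exact_gen$start),
                       c("target", "start", "strand")]
      want <- brute[order(brute$target, brute$start), ]
      expect_identical(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("reverse-complementing a fixture leaves every score unchanged", {
  mk <- function(strand, dir) {
    templates <- lapply(1:3, function(i) {
      locus_template(gene_id = sprintf("SYNG%04d", i), strand = strand,
                     uorf_layout = c("utr_contained", "spans_utr_exons",
                                     "overlaps_cds")[i])
    })
    simulate_uorf_fixture(fixture_dir(dir), n_loci = 3, seed = 21,
                          templates = templates,
                          target_modes = list(genomeA = c("perfect", "synonymous_only",
                                                          "rename_gene")))
  }
  fwd <- cached("strandsym_fwd", mk("+", "ssf"))
  rev <- cached("strandsym_rev", mk("-", "ssr"))
  # the minus-strand fixture is the exact reverse complement of the plus one
  gf <- read_genome_fasta(fwd$paths$source_genome)
  gr <- read_genome_fasta(rev$paths$source_genome)
  for (nm in names(gf)) expect_identical(gr[[nm]], oracle_revcomp(gf[[nm]]))
  score_of <- function(fx) {
    genome <- read_genome_fasta(fx$paths$source_genome)
    uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
    tidy(assess_conservation(uorfs, fx$paths$targets["genomeA"]))
  }
  af <- score_of(fwd); ar <- score_of(rev)
  expect_identical(af$score, ar$score)
  expect_identical(af$conserved, ar$conserved)
})

test_that("supplying an extra hit never lowers the final score", {
  md <- mode_fixture()
  fx <- md$fx
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  tgt <- read_target(fx, "genomeA")
  chroms <- names(tgt$genome)
  withr::with_seed(99, {
    for (rep in 1:40) {
      i <- sample(nrow(uorfs), 1)
      u <- uorfs[i, ]
      hits <- find_uorf_matches(u, tgt$genome, tgt$annotation)
      base <- score_conservation(u, hits, tgt$annotation)$score
      cn <- sample(chroms, 1)
      st <- sample(c(0L, 5000L), 1)
      extra <- tibble::tibble(
        space = "genomic", target = cn, start = st,
        end = st + nchar(u$nt_sequence),
        strand = sample(c("+", "-"), 1),
        n_mismatches = sample(0:3, 1), full_length = TRUE,
        protein_identical = NA
      )
      more <- score_conservation(u, dplyr::bind_rows(hits, extra), tgt$annotation)$score
      expect_gte(more, base)
    }
  })
})

test_that("intersection counts partition the uORF set", {
  assess <- tibble::tibble(
    uorf_id = rep(sprintf("u%d", 1:5), each = 2),
    target_genome_id = rep(c("A", "B"), 5),
    conserved = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  out <- summarize_intersections(assess)
  expect_identical(out$subsets$n_uorfs[out$subsets$subset == "A,B"], 3L)
  expect_identical(out$subsets$n_uorfs[out$subsets$subset == "A"], 2L)
  expect_identical(sum(out$subsets$n_uorfs), 5L)
  expect_identical(out$per_genome$n_conserved, c(5L, 3L))
  # a missing assessment is a hard error naming the uORF and genome
  expect_error(summarize_intersections(assess[-1, ]), "u1.*genome 'A'")
  # an all-conserved grid collapses to a single subset
  all_cons <- tidyr::expand_grid(uorf_id = sprintf("u%d", 1:4),
                                 target_genome_id = c("A", "B", "C")) |>
    dplyr::mutate(conserved = TRUE)
  out2 <- summarize_intersections(all_cons)
  expect_identical(out2$subsets,
                   tibble::tibble(subset = "A,B,C", n_uorfs = 4L))
})

test_that("precomputed PAF/SAM alignments substitute for the built-in scan", {
  fx <- cached("paf_fixture", {
    simulate_uorf_fixture(fixture_dir("paf"), n_loci = 1, seed = 5,
                          templates = list(locus_template()),
                          target_modes = list(genomeA = "perfect"))
  })
  genome <- read_genome_fasta(fx$paths$source_genome)
  uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
  u <- uorfs[1, ]
  tgt <- read_target(fx, "genomeA")
  qlen <- nchar(u$nt_sequence)
  pos <- u$blocks[[1]]$start[1]
  paf_line <- sprintf("%s\t%d\t0\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t60\tNM:i:0",
                      u$uorf_id, qlen, qlen, u$chrom, nchar(tgt$genome[[u$chrom]]),
                      pos, pos + qlen, qlen, qlen)
  paf <- file.path(fixture_dir("paf"), "hits.paf")
  writeLines(paf_line, paf)
  aln <- read_paf(paf)
  expect_identical(aln$n_mismatches, 0L)
  expect_true(aln$full_length)
  hits <- find_uorf_matches(u, tgt$genome, tgt$annotation, alignments = aln)
  a <- score_conservation(u, hits, tgt$annotation)
  expect_identical(a$score, 7L)
  # malformed lines are rejected with their line number
  writeLines(c(paf_line, "broken\tline"), paf)
  expect_error(read_paf(paf), "line 2")
  sam <- file.path(fixture_dir("paf"), "hits.sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:0",
                       u$uorf_id, u$chrom, pos + 1L, qlen, u$nt_sequence)), sam)
  sam_hits <- read_sam(sam)
  expect_identical(sam_hits$start, pos)
  expect_true(sam_hits$full_length)
  hits2 <- find_uorf_matches(u, tgt$genome, tgt$annotation, alignments = sam_hits)
  expect_identical(score_conservation(u, hits2, tgt$annotation)$score, 7L)
})
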