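# Transcript construction: junction loading filters, donor scanning,
# score-based pairing, grafting by coordinates vs raw string surgery, the
# three validity filters, and coverage summaries.

test_that("junction loading keeps donor-in-uORF, acceptor-in-CDS pairs only", {
  bi <- builder_inputs()
  jx <- load_junctions(bi$fx$paths$junction_bed, bi$uorfs, bi$annot, bi$genome)
  want <- bi$fx$junctions[bi$fx$junctions$provenance == "coverage_backed", ]
  expect_identical(nrow(jx), nrow(want))
  expect_setequal(paste(jx$chrom, jx$donor, jx$acceptor),
                  paste(want$chrom, want$donor, want$acceptor))
  expect_true(all(jx$provenance == "coverage_backed"))

  # donor downstream of the uORF (inside the CDS) is excluded
  u <- bi$uorfs[bi$uorfs$strand == "+", ][1, ]
  rec <- bi$fx$records[[match(u$uorf_id, bi$fx$uorfs$uorf_id)]]
  cds2 <- rec$cds[2, ]
  bad <- tibble::tibble(chrom = u$chrom, donor = cds2$start + 6L,
                        acceptor = cds2$start + 60L, name = "bad", strand = "+",
                        coverage = 5L)
  # (not GT-AG either, so silence the canonicality warning)
  expect_identical(nrow(suppressWarnings(
    load_junctions(bad, bi$uorfs, bi$annot, bi$genome))), 0L)

  # junction at a different locus than the uORF's gene is excluded:
  # same intron coordinates, evaluated against a uORF table whose gene
  # identifiers do not match the locus
  good <- jx[1, c("chrom", "donor", "acceptor", "strand", "coverage")]
  good$name <- "jx"
  renamed <- bi$uorfs
  renamed$gene_id <- paste0(renamed$gene_id, "_OTHER")
  expect_identical(nrow(load_junctions(good, renamed, bi$annot, bi$genome)), 0L)

  # non-GT-AG junctions are dropped with a warning
  shifted <- good
  shifted$donor <- shifted$donor + 1L
  expect_warning(out <- load_junctions(shifted, bi$uorfs, bi$annot, bi$genome),
                 "GT-AG")
  expect_identical(nrow(out), 0L)
})

test_that("donor scan equals a brute-force GT regex scan on the oriented sequence", {
  bi <- builder_inputs()
  for (i in seq_len(nrow(bi$uorfs))) {
    u <- bi$uorfs[i, ]
    got <- scan_donor_candidates(u, bi$genome)
    m <- gregexpr("(?=GT)", u$nt_sequence, perl = TRUE)[[1]]
    offs <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
    len <- nchar(u$nt_sequence)
    offs <- offs[offs >= 3L & offs <= len - 5L]
    if (nrow(u$blocks[[1]]) > 1) {
      # GTs straddling the block boundary are not genomic donors
      q <- if (u$strand == "+") {
        u$blocks[[1]]$end[1] - u$blocks[[1]]$start[1]
      } else {
        u$blocks[[1]]$end[2] - u$blocks[[1]]$start[2]
      }
      offs <- offs[offs != q - 1L]
    }
    expect_identical(sort(got$offset), sort(offs), label = u$uorf_id)
    # genomic positions carry the sense GT
    for (k in seq_len(nrow(got))) {
      di <- substring(bi$genome[[u$chrom]], got$donor_pos[k] + 1L, got$donor_pos[k] + 2L)
      if (u$strand == "-") {
        di <- substring(bi$genome[[u$chrom]], got$donor_pos[k], got$donor_pos[k] + 1L)
        di <- oracle_revcomp(di)
      }
      expect_identical(di, "GT")
    }
  }
  # a uORF built from GT-free codons yields an empty scan
  fx0 <- cached("nodonor_fixture", {
    simulate_uorf_fixture(fixture_dir("nodonor"), n_loci = 1, seed = 13,
                          templates = list(locus_template(has_valid_donor = FALSE,
                                                          evidence = character(0))),
                          target_modes = list(genomeA = "perfect"))
  })
  g0 <- read_genome_fasta(fx0$paths$source_genome)
  u0 <- hydrate_uorfs(read_uorf_table(fx0$paths$uorf_table), g0)
  expect_identical(nrow(scan_donor_candidates(u0[1, ], g0)), 0L)
})

test_that("junction scoring keeps mean >= 0.9, dedupes against coverage evidence", {
  bi <- builder_inputs()
  u <- bi$uorfs[bi$uorfs$strand == "+", ][1, ]
  donors <- scan_donor_candidates(u, bi$genome)
  expect_gt(nrow(donors), 0)
  cands <- pair_and_score(donors, bi$annot, u$host_transcript_id,
                          function(j) tibble::tibble(
                            donor_score = rep(0.95, nrow(j)),
                            acceptor_score = rep(0.91, nrow(j))),
                          known = NULL)
  expect_identical(nrow(cands), nrow(donors))  # mean 0.93 retained
  none <- pair_and_score(donors, bi$annot, u$host_transcript_id,
                         function(j) tibble::tibble(
                           donor_score = rep(0.99, nrow(j)),
                           acceptor_score = rep(0.79, nrow(j))),
                         known = NULL)
  expect_identical(nrow(none), 0L)             # mean 0.89 dropped
  # junctions identical to a coverage-backed one are excluded
  known <- cands[1, c("chrom", "donor", "acceptor", "strand")]
  deduped <- pair_and_score(donors, bi$annot, u$host_transcript_id,
                            function(j) tibble::tibble(
                              donor_score = rep(1, nrow(j)),
                              acceptor_score = rep(1, nrow(j))),
                            known = known)
  expect_identical(nrow(deduped), nrow(cands) - 1L)
  expect_false(any(deduped$donor == known$donor & deduped$acceptor == known$acceptor))
  # out-of-range scorer output is a hard error
  expect_error(pair_and_score(donors, bi$annot, u$host_transcript_id,
                              function(j) tibble::tibble(
                                donor_score = rep(1.2, nrow(j)),
                                acceptor_score = rep(0.9, nrow(j)))),
               "outside \\[0, 1\\]")
})

test_that("grafting concatenates the uORF prefix with the reference CDS tail", {
  bi <- builder_inputs()
  jx <- load_junctions(bi$fx$paths$junction_bed, bi$uorfs, bi$annot, bi$genome)
  for (i in seq_len(nrow(jx))) {
    j <- jx[i, ]
    u <- bi$uorfs[bi$uorfs$uorf_id == j$uorf_id, ]
    rec <- bi$fx$records[[match(u$uorf_id, bi$fx$uorfs$uorf_id)]]
    cand <- build_uorf_transcript(u, j, bi$annot, bi$genome, u$host_transcript_id)
    p <- rec$geom$p
    want <- paste0(substr(u$nt_sequence, 1, p),
                   substring(rec$cds_nt, rec$geom$e1 + 1L))
    expect_identical(cand$cds_nt, want, label = u$uorf_id)
  }
  # mid-exon acceptor: shifting the acceptor into exon 2 by k shortens the
  # downstream contribution by k
  u <- bi$uorfs[bi$uorfs$strand == "+", ][1, ]
  rec <- bi$fx$records[[match(u$uorf_id, bi$fx$uorfs$uorf_id)]]
  j <- jx[jx$uorf_id == u$uorf_id, ][1, ]
  k <- 3L
  j_mid <- j; j_mid$acceptor <- j$acceptor + k
  c0 <- build_uorf_transcript(u, j, bi$annot, bi$genome, u$host_transcript_id)
  c1 <- build_uorf_transcript(u, j_mid, bi$annot, bi$genome, u$host_transcript_id)
  expect_identical(nchar(c0$cds_nt) - nchar(c1$cds_nt), as.integer(k))
  expect_identical(substring(c0$cds_nt, nchar(c0$cds_nt) - 20),
                   substring(c1$cds_nt, nchar(c1$cds_nt) - 20))
  # an acceptor placed inside a reference intron is rejected with a reason
  j_bad <- j; j_bad$acceptor <- rec$cds$end[1] + 5L
  expect_error(build_uorf_transcript(u, j_bad, bi$annot, bi$genome,
                                     u$host_transcript_id),
               "intron of reference")
})

test_that("mirrored minus-strand loci graft to the identical coding sequence", {
  mk <- function(strand, dir) {
    simulate_uorf_fixture(fixture_dir(dir), n_loci = 1, seed = 31,
                          templates = list(locus_template(strand = strand)),
                          target_modes = list(genomeA = "perfect"))
  }
  fp <- cached("graft_plus", mk("+", "gp"))
  fm <- cached("graft_minus", mk("-", "gm"))
  grab <- function(fx) {
    genome <- read_genome_fasta(fx$paths$source_genome)
    annot <- read_annotation(fx$paths$source_annotation)
    uorfs <- hydrate_uorfs(read_uorf_table(fx$paths$uorf_table), genome)
    jx <- load_junctions(fx$paths$junction_bed, uorfs, annot, genome)
    build_uorf_transcript(uorfs[1, ], jx[1, ], annot, genome,
                          uorfs$host_transcript_id[1])$cds_nt
  }
  expect_identical(grab(fp), grab(fm))
})

test_that("validity filters fire on premature stops, frameshifts and short CDS", {
  base <- list(cds_nt = NULL, reference_cds_len = 300L,
               reference_protein = paste0(strrep("A", 99), "*"))
  mk <- function(nt, ref_len = 300L) {
    cand <- base
    cand$cds_nt <- nt
    cand$reference_cds_len <- ref_len
    validate_transcript(cand)
  }
  clean <- paste0("ATG", strrep("GCT", 98), "TAA")  # 300 nt, no premature stop
  v <- mk(clean)
  expect_false(v$premature_stop)
  expect_true(v$frame_multiple_of_3)
  expect_identical(v$length_ratio, 1)
  expect_true(v$passed)
  expect_identical(substr(v$protein_aa, 1, 1), "M")
  expect_false(v$non_aug_start)

  # in-frame TGA at codon 5
  with_stop <- paste0("ATG", strrep("GCT", 3), "TGA", strrep("GCT", 94), "TAA")
  v <- mk(with_stop)
  expect_true(v$premature_stop)
  expect_false(v$passed)

  # 299 nt: frame filter fails
  v <- mk(substr(clean, 1, 299))
  expect_false(v$frame_multiple_of_3)
  expect_false(v$passed)

  # 255/300 = 85% of the reference: length filter fails
  short <- paste0("ATG", strrep("GCT", 83), "TAA")
  v <- mk(short)
  expect_false(v$passed)
  expect_identical(v$length_ratio, 0.85)
  expect_false(v$premature_stop)
  expect_true(v$frame_multiple_of_3)
  # exactly 90% passes (the rule discards only < 90%)
  at_limit <- paste0("ATG", strrep("GCT", 88), "TAA")
  expect_true(mk(at_limit)$passed)

  # isoleucine start is kept but flagged
  ile <- sub("^ATG", "ATA", clean)
  v <- mk(ile)
  expect_true(v$passed)
  expect_true(v$non_aug_start)
  expect_identical(v$start_residue, "I")
  expect_identical(substr(v$protein_aa, 1, 1), "I")

  # a graft encoding exactly the reference protein is flagged
  dup <- base
  dup$cds_nt <- clean
  dup$reference_protein <- translate_nt(clean)
  expect_true(validate_transcript(dup)$identical_to_reference)
})

test_that("filter verdicts match an independent string-surgery oracle on 200 random loci", {
  fx <- sweep_fixture()
  got <- tidy(sweep_transcripts())
  want <- oracle_graft_report(fx)
  expect_gte(nrow(want), 190)  # has_valid_donor is default-on in the sweep
  m <- merge(as.data.frame(got), want,
             by = c("uorf_id", "donor", "acceptor"),
             suffixes = c("_got", "_want"))
  expect_identical(nrow(m), nrow(want))
  expect_identical(m$passed_got, m$passed_want)
  expect_identical(m$premature_stop_got, m$premature_stop_want)
  expect_identical(m$frame_multiple_of_3_got, m$frame_multiple_of_3_want)
  expect_equal(m$length_ratio_got, m$length_ratio_want, tolerance = 1e-12)
  # the grafted sequences themselves agree byte for byte
  full <- sweep_transcripts()$candidates
  m2 <- merge(full[, c("uorf_id", "donor", "acceptor", "cds_nt")], want,
              by = c("uorf_id", "donor", "acceptor"))
  expect_identical(m2$cds_nt.x, m2$cds_nt.y)
  # all three failure classes are exercised by the sweep
  expect_gt(sum(m$premature_stop_want), 0)
  expect_gt(sum(!m$frame_multiple_of_3_want), 0)
  expect_gt(sum(m$length_ratio_want < 0.9 & m$frame_multiple_of_3_want), 0)
  expect_gt(sum(m$passed_want), 0)
})

test_that("passed proteins start with M (or are flagged) and end at the reference stop", {
  tb <- sweep_transcripts()$candidates
  passed <- tb[tb$passed, ]
  expect_gt(nrow(passed), 0)
  ok_start <- substr(passed$protein_aa, 1, 1) == "M" | passed$non_aug_start
  expect_true(all(ok_start))
  expect_true(all(substring(passed$protein_aa, nchar(passed$protein_aa)) == "*"))
})

test_that("re-extracting emitted transcripts from GTF + genome reproduces the CDS", {
  bi <- builder_inputs()
  jx <- load_junctions(bi$fx$paths$junction_bed, bi$uorfs, bi$annot, bi$genome)
  ts <- build_transcripts(bi$uorfs, jx, bi$annot, bi$genome)
  out <- fixture_dir("emitted")
  write_transcript_outputs(ts, out)
  emitted <- read_annotation(file.path(out, "uorf_connected_transcripts.gtf"))
  models <- uorfconnect:::transcript_models(emitted)
  passed <- ts$candidates[ts$candidates$passed, ]
  expect_setequal(names(models), passed$transcript_id)
  for (id in passed$transcript_id) {
    re_cds <- spliced_seq(bi$genome, models[[id]]$chrom, models[[id]]$cds,
                          models[[id]]$strand)
    expect_identical(re_cds, passed$cds_nt[passed$transcript_id == id])
  }
  # protein FASTA carries exactly the passed set
  faa <- Biostrings::readAAStringSet(file.path(out, "uorf_connected_proteins.faa"))
  expect_setequal(names(faa), passed$transcript_id)
})

test_that("coverage summary averages retained vs all construction junctions", {
  mk <- function(cov, passed) {
    x <- list(candidates = tibble::tibble(
      transcript_id = sprintf("t%d", seq_along(cov)),
      provenance = "coverage_backed", coverage = cov, passed = passed
    ))
    class(x) <- "uorf_transcript_set"
    x
  }
  s <- coverage_summary(mk(c(10, 20, 30), c(TRUE, TRUE, TRUE)))
  expect_identical(s$mean_coverage_retained, 20)
  expect_identical(s$mean_coverage_all, 20)
  s <- coverage_summary(mk(c(10, 20, 30), c(FALSE, FALSE, TRUE)))
  expect_identical(s$mean_coverage_retained, 30)
  expect_identical(s$mean_coverage_all, 20)
  # empty sets report NA, not zero
  s <- coverage_summary(mk(numeric(0), logical(0)))
  expect_true(is.na(s$mean_coverage_retained) && is.na(s$mean_coverage_all))
})
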