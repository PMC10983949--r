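# Average-pLDDT gating of novel proteins. Per-residue confidences come from
# ColabFold-style PDB files (pLDDT in the B-factor column of CA atoms) or
# plain residue tables. A novel protein is retained when its average pLDDT
# improves on a reference by more than 1, or stays within +/-1 of it;
# against multiple references the best achievable class counts.

#' Load a per-residue pLDDT profile
#'
#' @param path A PDB file (pLDDT read from the B-factor of CA atoms, model 1
#'   of multi-model files) or a tab-separated table with `residue_index` and
#'   `plddt` columns.
#' @param format `"auto"` (by extension), `"tsv"` or `"pdb"`.
#' @param expected_length Optional declared residue count; a profile of any
#'   other length is rejected.
#' @return Numeric vector of per-residue confidences in `[0, 100]`, with the
#'   protein id (file stem) as the `"protein_id"` attribute.
#' @export
read_plddt_profile <- function(path, format = c("auto", "tsv", "pdb"),
                               expected_length = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "tsv"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ]
    vals <- ca$b
    resno <- ca$resno
  } else {
    tb <- readr::read_tsv(path, col_types = readr::cols(
      residue_index = "i", plddt = "d"
    ))
    vals <- tb$plddt
    resno <- tb$residue_index
  }
  if (length(vals) == 0) abort(sprintf("no residues found in '%s'", path))
  if (any(diff(resno) <= 0)) {
    abort(sprintf("non-monotone residue numbering in '%s'", path))
  }
  if (any(is.na(vals)) || any(vals < 0 | vals > 100)) {
    abort(sprintf("pLDDT values outside [0, 100] in '%s'", path))
  }
  if (!is.null(expected_length) && length(vals) != expected_length) {
    abort(sprintf("profile '%s' has %d residues, expected %d",
                  path, length(vals), expected_length))
  }
  structure(as.numeric(vals),
            protein_id = sub("\\.(tsv|pdb)$", "", basename(path), ignore.case = TRUE))
}

plddt_verdict <- function(deltas, band = 1.0) {
  if (any(deltas > band)) "retained_improved"
  else if (any(abs(deltas) <= band)) "retained_no_change"
  else "eliminated"
}

#' Compare a novel protein's average pLDDT against its reference(s)
#'
#' The verdict is the best class achievable across references:
#' `retained_improved` (delta above the band against some reference) beats
#' `retained_no_change` (|delta| within the band against some reference)
#' beats `eliminated`.
#'
#' @param novel Numeric pLDDT vector (or profile from
#'   [read_plddt_profile()]) of the novel protein.
#' @param references A numeric vector or list of numeric vectors, one per
#'   reference protein; names are used as reference ids.
#' @param novel_id,reference_ids Optional identifiers (defaults taken from
#'   profile attributes/names).
#' @param band Half-width of the "no change" band in average-pLDDT units
#'   (default 1.0: improvement means delta > 1, no change means |delta| <= 1).
#' @return One-row tibble with averages, the best delta, the verdict and the
#'   pLDDT > 70 high-confidence flag.
#' @export
compare_plddt <- function(novel, references, novel_id = NULL,
                          reference_ids = NULL, band = 1.0) {
  if (!is.list(references)) references <- list(references)
  if (length(references) == 0) abort("at least one reference profile is required")
  if (is.null(novel_id)) novel_id <- attr(novel, "protein_id") %||% "novel"
  if (is.null(reference_ids)) {
    reference_ids <- names(references) %||%
      purrr::imap_chr(references, ~ attr(.x, "protein_id") %||% sprintf("ref_%d", .y))
  }
  novel_avg <- mean(as.numeric(novel))
  ref_avgs <- purrr::map_dbl(references, ~ mean(as.numeric(.x)))
  deltas <- novel_avg - ref_avgs
  tibble(
    novel_id = novel_id,
    reference_ids = paste(reference_ids, collapse = ","),
    novel_avg = novel_avg,
    reference_avgs = paste(format(ref_avgs, trim = TRUE), collapse = ","),
    best_delta = max(deltas),
    verdict = plddt_verdict(deltas, band),
    high_confidence = novel_avg > 70
  )
}

#' Batch pLDDT comparison for a set of transcripts
#'
#' @param pairs Tibble with `novel_id` and `reference_id` columns (several
#'   rows per novel id allowed for multi-reference loci) plus any carry-along
#'   columns such as `uorf_id`/`provenance`.
#' @param profile_dir Directory of per-protein pLDDT tables named
#'   `<protein_id>.tsv` (or `.pdb`).
#' @param band "No change" band half-width.
#' @return A `plddt_comparison_set` object.
#' @export
compare_structures <- function(pairs, profile_dir, band = 1.0) {
  load_one <- function(id) {
    for (ext in c(".tsv", ".pdb")) {
      p <- file.path(profile_dir, paste0(id, ext))
      if (file.exists(p)) return(read_plddt_profile(p))
    }
    abort(sprintf("no pLDDT profile found for protein '%s' in '%s'", id, profile_dir))
  }
  rows <- pairs |>
    group_by(novel_id = .data$novel_id) |>
    dplyr::group_map(function(g, key) {
      refs <- setNames(purrr::map(g$reference_id, load_one), g$reference_id)
      cmp <- compare_plddt(load_one(key$novel_id), refs,
                           novel_id = key$novel_id, band = band)
      extra <- g[1, setdiff(names(g), c("novel_id", "reference_id")), drop = FALSE]
      bind_cols(cmp, extra)
    }) |> bind_rows() |> arrange(.data$novel_id)
  out <- list(comparisons = rows, band = band)
  class(out) <- "plddt_comparison_set"
  out
}

#' Retention tally across evidence streams
#'
#' @param comparisons Comparison tibble carrying `verdict`, `provenance` and
#'   `uorf_id` columns (e.g. `tidy()` of a `plddt_comparison_set` joined to
#'   the transcript report).
#' @return List with per-stream transcript and distinct-uORF counts and the
#'   union count of distinct retained uORFs.
#' @export
tally_retention <- function(comparisons) {
  retained <- comparisons |> filter(.data$verdict != "eliminated")
  per_stream <- comparisons |>
    group_by(provenance = .data$provenance) |>
    summarise(
      n_evaluated = n(),
      n_retained = sum(.data$verdict != "eliminated"),
      n_improved = sum(.data$verdict == "retained_improved"),
      n_uorfs_retained = dplyr::n_distinct(.data$uorf_id[.data$verdict != "eliminated"]),
      .groups = "drop"
    )
  list(
    per_stream = per_stream,
    n_retained_total = nrow(retained),
    n_uorfs_union = dplyr::n_distinct(retained$uorf_id)
  )
}

#' @export
print.plddt_comparison_set <- function(x, ...) {
  tb <- x$comparisons
  cat(sprintf("<plddt_comparison_set> %d proteins: %d improved, %d no-change, %d eliminated\n",
              nrow(tb), sum(tb$verdict == "retained_improved"),
              sum(tb$verdict == "retained_no_change"),
              sum(tb$verdict == "eliminated")))
  invisible(x)
}

#' @export
tidy.plddt_comparison_set <- function(x, ...) x$comparisons

#' @export
glance.plddt_comparison_set <- function(x, ...) {
  tb <- x$comparisons
  tibble(
    n_compared = nrow(tb),
    n_retained = sum(tb$verdict != "eliminated"),
    n_improved = sum(tb$verdict == "retained_improved"),
    n_high_confidence = sum(tb$high_confidence),
    mean_delta = mean(tb$best_delta),
    band = x$band
  )
}

#' @export
autoplot.plddt_comparison_set <- function(object, ...) {
  ggplot2::ggplot(object$comparisons,
                  ggplot2::aes(x = .data$best_delta, fill = .data$verdict)) +
    ggplot2::geom_histogram(binwidth = 0.5, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(-object$band, object$band), linetype = 2) +
    ggplot2::labs(x = "average pLDDT delta (novel - reference)", y = "proteins",
                  title = "Structure-confidence gating") +
    ggplot2::theme_minimal()
}
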