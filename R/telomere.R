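#' Scan an assembly for telomeric (TTAGGG)n tandem arrays
#'
#' The forward strand of every chromosome is scanned for maximal runs of
#' exact, phase-aligned motif hexamers; the motif and its reverse
#' complement (`CCCTAA` for the canonical motif) are scanned separately,
#' so a 5' terminus planted as reverse-complement units is still found.
#' Up to `max_mismatch_run` consecutive interrupted (inexact) units
#' between exact units are tolerated inside a run. Runs with at least
#' `min_units` exact units are reported.
#'
#' @param assembly Assembly tibble (`chrom`, `sequence`).
#' @param motif Telomeric motif (default `"TTAGGG"`).
#' @param min_units Minimum exact units per reported array (default 5).
#' @param max_mismatch_run Maximum interrupted units bridged between exact
#'   units (default 1).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `motif`
#'   (orientation actually matched), `n_units` (span / motif length),
#'   `n_exact_units`, `purity` (exact units / total units in span).
#' @export
scan_telomeric <- function(assembly, motif = "TTAGGG", min_units = 5,
                           max_mismatch_run = 1) {
  if (nchar(motif) == 0) stop("motif must be non-empty", call. = FALSE)
  w <- nchar(motif)
  motifs <- unique(c(motif, revcomp(motif)))
  out <- list()
  for (ci in seq_len(nrow(assembly))) {
    s <- assembly$sequence[ci]
    for (m in motifs) {
      hits <- stringr::str_locate_all(s, stringr::fixed(m))[[1]]
      if (nrow(hits) == 0) next
      pos <- hits[, 1] - 1L  # 0-based starts of exact units
      # join successive exact units when separated by at most
      # max_mismatch_run interrupted, phase-aligned units
      gap_units <- (diff(pos) - w) / w
      new_run <- c(TRUE, !(gap_units %in% 0:max_mismatch_run))
      run <- cumsum(new_run)
      for (r in unique(run)) {
        p <- pos[run == r]
        if (length(p) < min_units) next
        span_start <- p[1]
        span_end <- p[length(p)] + w
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = assembly$chrom[ci],
          start = span_start, end = span_end, motif = m,
          n_units = (span_end - span_start) / w,
          n_exact_units = length(p),
          purity = length(p) / ((span_end - span_start) / w)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      motif = character(), n_units = double(), n_exact_units = integer(),
      purity = double()
    ))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Classify telomeric arrays as terminal or interstitial
#'
#' An array is terminal when either endpoint falls within
#' `terminal_window` of a chromosome end; otherwise it is an interstitial
#' telomeric sequence (ITS).
#'
#' @param arrays Tibble from [scan_telomeric()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param terminal_window Window from each terminus in bp (default 10 kb).
#' @return `arrays` with an added `location_class` column
#'   (`"terminal"` / `"interstitial"`).
#' @export
classify_terminal <- function(arrays, chrom_lengths, terminal_window = 1e4) {
  assert_cols(arrays, c("chrom", "start", "end"), "arrays")
  len <- unname(chrom_lengths[arrays$chrom])
  arrays$location_class <- ifelse(
    arrays$start < terminal_window | arrays$end > len - terminal_window,
    "terminal", "interstitial"
  )
  arrays
}

#' Write telomeric arrays as BED6
#'
#' Names are `TEL_terminal` / `TEL_ITS`; score is `purity * 1000`.
#'
#' @param arrays Classified array tibble from [classify_terminal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telomere_bed <- function(arrays, path) {
  bed <- arrays |>
    dplyr::transmute(
      chrom = .data$chrom, start = .data$start, end = .data$end,
      family_id = ifelse(.data$location_class == "terminal",
                         "TEL_terminal", "TEL_ITS"),
      identity = .data$purity,
      strand = ifelse(.data$motif == "TTAGGG", "+", "-")
    )
  write_bed(bed, path)
}
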