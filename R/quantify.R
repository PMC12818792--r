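#' Per-chromosome quantification of satDNA families
#'
#' One row per (family, chromosome) with at least one locus: `copies` is
#' the merged-locus count (the discrete-hit copy metric), `bp` the summed
#' locus lengths, `pct_of_chrom` and `pct_of_genome` the occupied
#' percentages of the chromosome and of the whole assembly.
#'
#' @param loci Locus tibble from [merge_hits()].
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @return A `FamilyChromStats` tibble.
#' @export
per_chromosome_table <- function(loci, chrom_lengths) {
  assert_cols(loci, c("family_id", "chrom", "start", "end"), "loci")
  unknown <- setdiff(unique(loci$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    stop("locus on unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  genome_bp <- sum(chrom_lengths)
  loci |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::summarise(
      copies = dplyr::n(),
      bp = sum(.data$end - .data$start),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_of_chrom = 100 * .data$bp / unname(chrom_lengths[.data$chrom]),
      pct_of_genome = 100 * .data$bp / genome_bp
    )
}

# union length of half-open intervals
interval_union_bp <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  run_end <- cummax(end)
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)])
  grp <- cumsum(new_run)
  sum(tapply(end, grp, max) - tapply(start, grp, min))
}

#' Genome-wide satDNA abundance
#'
#' Per-family percentage of the genome (summed over chromosomes) and the
#' total satellitome percentage, where base pairs covered by loci of more
#' than one family are counted once (interval union across families).
#'
#' @param loci Locus tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return List with `per_family` (tibble `family_id`, `bp`,
#'   `pct_of_genome`), `total_bp`, and `total_pct`.
#' @export
genome_abundance <- function(loci, chrom_lengths) {
  genome_bp <- sum(chrom_lengths)
  if (nrow(loci) == 0) {
    return(list(
      per_family = tibble::tibble(family_id = character(), bp = double(),
                                  pct_of_genome = double()),
      total_bp = 0, total_pct = 0
    ))
  }
  per_family <- loci |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::mutate(pct_of_genome = 100 * .data$bp / genome_bp) |>
    dplyr::arrange(dplyr::desc(.data$bp))
  total_bp <- loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bp = interval_union_bp(.data$start, .data$end),
                     .groups = "drop") |>
    dplyr::pull(.data$bp) |>
    sum()
  list(per_family = per_family, total_bp = total_bp,
       total_pct = 100 * total_bp / genome_bp)
}

#' Classify families by chromosomal distribution
#'
#' A family is `unmapped` when it has no loci, `chromosome_specific` when
#' its loci fall on exactly one chromosome, `pan_chromosomal` when present
#' on every chromosome, and `multi_chromosomal` otherwise. `low_copy_flag`
#' marks families for which no single chromosome reaches `min_copies`
#' merged loci — the conservative noise threshold of 10 copies per
#' chromosome — without suppressing them from any count.
#'
#' @param stats `FamilyChromStats` tibble from [per_chromosome_table()].
#' @param n_chromosomes Number of chromosomes in the complement.
#' @param min_copies Per-chromosome copy threshold for the low-copy flag.
#' @param catalog Optional catalog tibble; families absent from `stats`
#'   are then included as `unmapped`.
#' @return Tibble: `family_id`, `n_chroms_present`, `total_copies`,
#'   `category`, `low_copy_flag`.
#' @export
classify_families <- function(stats, n_chromosomes, min_copies = 10,
                              catalog = NULL) {
  stopifnot(n_chromosomes >= 1)
  mapped <- stats |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_chroms_present = dplyr::n_distinct(.data$chrom),
      total_copies = sum(.data$copies),
      low_copy_flag = max(.data$copies) < min_copies,
      .groups = "drop"
    )
  if (!is.null(catalog)) {
    absent <- setdiff(catalog$id, mapped$family_id)
    if (length(absent) > 0) {
      mapped <- dplyr::bind_rows(
        mapped,
        tibble::tibble(family_id = absent, n_chroms_present = 0L,
                       total_copies = 0L, low_copy_flag = TRUE)
      )
    }
  }
  mapped |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_chroms_present == 0 ~ "unmapped",
      .data$n_chroms_present == 1 ~ "chromosome_specific",
      .data$n_chroms_present == n_chromosomes ~ "pan_chromosomal",
      TRUE ~ "multi_chromosomal"
    )) |>
    dplyr::arrange(.data$family_id)
}

#' Gini index of a vector of window counts
#'
#' `sum_i sum_j |x_i - x_j| / (2 n^2 mean)`; 0 for uniform counts and for
#' a single window; approaches 1 as counts concentrate in one window.
#'
#' @param x Non-negative counts.
#' @return Gini index in `[0, 1]`, or `NA` when all counts are zero.
#' @export
gini_index <- function(x) {
  n <- length(x)
  if (n == 0 || all(x == 0)) return(NA_real_)
  if (n == 1) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Windowed enrichment Gini per family and chromosome
#'
#' Each chromosome is partitioned into fixed windows; loci are counted per
#' window by midpoint and the Gini index of the window counts measures how
#' locally concentrated the family is. Families with Gini at or above
#' `threshold` on a chromosome are flagged locally enriched there.
#'
#' @param loci Locus tibble.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window size in bp (default 1 Mb).
#' @param threshold Enrichment flag threshold (default 0.8).
#' @return Tibble: `family_id`, `chrom`, `n_loci`, `gini`,
#'   `locally_enriched`.
#' @export
enrichment_gini <- function(loci, chrom_lengths, window = 1e6,
                            threshold = 0.8) {
  if (any(chrom_lengths < window)) {
    stop("window exceeds a chromosome length; choose a smaller window",
         call. = FALSE)
  }
  loci |>
    dplyr::mutate(.mid = (.data$start + .data$end) / 2) |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      gini = {
        len <- unname(chrom_lengths[.data$chrom[1]])
        nw <- ceiling(len / window)
        counts <- tabulate(pmin(nw, floor(.data$.mid / window) + 1), nw)
        gini_index(counts)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(locally_enriched = .data$gini >= threshold)
}

#' Fraction of a family's loci in the pericentromeric band
#'
#' A locus is pericentromeric when its midpoint lies within
#' `centromere +/- band_halfwidth` on its chromosome.
#'
#' @param loci Locus tibble.
#' @param centromeres Tibble with `chrom`, `position`.
#' @param band_halfwidth Band half-width in bp.
#' @return Tibble: `family_id`, `n_loci`, `pericentromeric_fraction`.
#' @export
pericentromeric_fraction <- function(loci, centromeres, band_halfwidth) {
  assert_cols(centromeres, c("chrom", "position"), "centromeres")
  loci |>
    dplyr::left_join(centromeres, by = "chrom") |>
    dplyr::mutate(
      .mid = (.data$start + .data$end) / 2,
      .in_band = abs(.data$.mid - .data$position) <= band_halfwidth
    ) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      pericentromeric_fraction = mean(.data$.in_band),
      .groups = "drop"
    )
}

#' Top families by total copy number, with per-chromosome copy matrix
#'
#' Families ranked by descending total merged-locus count (ties broken
#' lexicographically by family id); the copy matrix has one row per family
#' and one column per chromosome.
#'
#' @param stats `FamilyChromStats` tibble.
#' @param n Number of families to keep (default 20).
#' @param chroms Optional chromosome ordering for the matrix columns.
#' @return A wide tibble of class `sat_copy_matrix`: `family_id`,
#'   `total_copies`, then one column per chromosome.
#' @export
top_families_by_copies <- function(stats, n = 20, chroms = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  chroms <- chroms %||% unique(stats$chrom)
  ranked <- stats |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(total_copies = sum(.data$copies), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_copies), .data$family_id) |>
    dplyr::slice_head(n = n)
  wide <- stats |>
    dplyr::filter(.data$family_id %in% ranked$family_id) |>
    dplyr::select("family_id", "chrom", "copies") |>
    tidyr::pivot_wider(names_from = "chrom", values_from = "copies",
                       values_fill = 0L)
  for (ch in setdiff(chroms, names(wide))) wide[[ch]] <- 0L
  out <- ranked |>
    dplyr::left_join(wide, by = "family_id") |>
    dplyr::select("family_id", "total_copies", dplyr::all_of(chroms))
  class(out) <- c("sat_copy_matrix", class(out))
  out
}
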