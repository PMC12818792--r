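#' Kimura 2-parameter distance between aligned sequences
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` the transition
#' and `Q` the transversion fraction over comparable columns. Columns
#' containing a gap (`-`) or `N` in either sequence are excluded from the
#' denominator. Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are
#' flagged and get `K = Inf` rather than being clamped.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequence strings
#'   (vectorized; pairs are recycled element-wise).
#' @return Tibble with `P`, `Q`, `K`, `comparable` (column count) and
#'   `saturated`.
#' @examples
#' k2p("ACGT", "ACGA")
#' @export
k2p <- function(aligned_a, aligned_b) {
  n <- max(length(aligned_a), length(aligned_b))
  aligned_a <- rep_len(toupper(aligned_a), n)
  aligned_b <- rep_len(toupper(aligned_b), n)
  if (any(nchar(aligned_a) != nchar(aligned_b))) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  out <- purrr::map2(aligned_a, aligned_b, function(a, b) {
    av <- strsplit(a, NULL)[[1]]
    bv <- strsplit(b, NULL)[[1]]
    comp <- av %in% DNA_BASES & bv %in% DNA_BASES
    m <- sum(comp)
    if (m == 0) {
      stop("no comparable (non-gap, non-N) columns", call. = FALSE)
    }
    av <- av[comp]; bv <- bv[comp]
    diff <- av != bv
    ts <- sum(diff & ((av == "A" & bv == "G") | (av == "G" & bv == "A") |
                        (av == "C" & bv == "T") | (av == "T" & bv == "C")))
    tv <- sum(diff) - ts
    c(P = ts / m, Q = tv / m, comparable = m)
  })
  res <- tibble::tibble(
    P = purrr::map_dbl(out, "P"),
    Q = purrr::map_dbl(out, "Q"),
    comparable = purrr::map_dbl(out, "comparable")
  )
  res |>
    dplyr::mutate(
      saturated = (1 - 2 * .data$P - .data$Q) <= 0 | (1 - 2 * .data$Q) <= 0,
      K = ifelse(.data$saturated, Inf,
                 -0.5 * log((1 - 2 * .data$P - .data$Q) *
                              sqrt(1 - 2 * .data$Q)))
    ) |>
    dplyr::select("P", "Q", "K", "comparable", "saturated")
}

k2p_from_counts <- function(ts, tv, comparable) {
  P <- ts / comparable
  Q <- tv / comparable
  saturated <- (1 - 2 * P - Q) <= 0 | (1 - 2 * Q) <= 0
  ifelse(saturated, Inf, -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
}

#' Annotate loci with K2P divergence from their consensus
#'
#' Each locus sequence is extracted from the assembly and re-aligned,
#' ungapped, against a head-to-tail dimer of its family consensus (both
#' strands, best-scoring offset), so array copies starting at an arbitrary
#' monomer phase still align. K2P is computed over the aligned span.
#' Loci whose best alignment covers less than `min_aln_frac` of the locus
#' (or that find no seed at all) get `divergence = NA`.
#'
#' @param loci Locus tibble.
#' @param assembly Assembly tibble.
#' @param catalog Catalog tibble.
#' @param params A [mapping_params()] (seed size and X-drop reused).
#' @param min_aln_frac Minimum aligned fraction of `min(locus length,
#'   monomer length)` for a divergence call (default 0.5).
#' @return `loci` with an added `divergence` column (K2P, fraction).
#' @export
copy_divergence <- function(loci, assembly, catalog,
                            params = mapping_params(),
                            min_aln_frac = 0.5) {
  assert_cols(loci, c("family_id", "chrom", "start", "end"), "loci")
  if (nrow(loci) == 0) {
    loci$divergence <- double()
    return(loci)
  }
  seq_by_chrom <- stats::setNames(assembly$sequence, assembly$chrom)
  loci$divergence <- NA_real_
  for (fam in unique(loci$family_id)) {
    mono <- catalog$sequence[catalog$id == fam]
    if (length(mono) != 1) stop("family not in catalog: ", fam,
                                call. = FALSE)
    idx <- which(loci$family_id == fam)
    seqs <- substring(seq_by_chrom[loci$chrom[idx]],
                      loci$start[idx] + 1, loci$end[idx])
    bm <- cpp_best_match(seqs, strrep(mono, 2), params$seed_k,
                         as.integer(params$xdrop))
    floor_len <- pmin(nchar(seqs), nchar(mono)) * min_aln_frac
    ok <- !is.na(bm$span) & bm$span >= floor_len & bm$comparable > 0
    div <- rep(NA_real_, length(idx))
    div[ok] <- k2p_from_counts(bm$transitions[ok], bm$transversions[ok],
                               bm$comparable[ok])
    loci$divergence[idx] <- div
  }
  loci
}

#' Build a divergence landscape
#'
#' Abundance (percent of the genome, or of read bases) accumulated into
#' divergence bins of `bin_width` by each item's K2P divergence. The
#' default bins span 0-30%; they extend upward automatically when a
#' divergence exceeds the last edge so that the bin sum always equals the
#' total abundance. Items with `NA` divergence are dropped (with a
#' warning); an error is raised when nothing remains.
#'
#' @param divergence K2P divergences (fractions).
#' @param weight_bp Abundance weight per item (bp).
#' @param total_bp Denominator (genome bp or total read bp).
#' @param bin_width Bin width as a fraction (default 0.01 = 1%).
#' @param max_bin Default upper edge as a fraction (default 0.30).
#' @return Tibble of class `sat_landscape`: `bin_lo`, `bin_hi` (percent),
#'   `abundance_pct`; attributes `mean_divergence_pct` (abundance-weighted
#'   mean of bin midpoints) and `total_pct`.
#' @export
build_landscape <- function(divergence, weight_bp, total_bp,
                            bin_width = 0.01, max_bin = 0.30) {
  keep <- is.finite(divergence)
  if (any(!keep)) {
    warning(sum(!keep), " item(s) without finite divergence dropped")
  }
  divergence <- divergence[keep]
  weight_bp <- weight_bp[keep]
  if (length(divergence) == 0) {
    stop("no items with finite divergence", call. = FALSE)
  }
  n_bins <- max(ceiling(max_bin / bin_width),
                floor(max(divergence) / bin_width) + 1)
  bin <- pmin(floor(divergence / bin_width), n_bins - 1)
  abundance <- tapply(100 * weight_bp / total_bp, factor(bin, levels = 0:(n_bins - 1)),
                      sum, default = 0)
  out <- tibble::tibble(
    bin_lo = 100 * bin_width * (0:(n_bins - 1)),
    bin_hi = 100 * bin_width * (1:n_bins),
    abundance_pct = as.numeric(abundance)
  )
  mid <- (out$bin_lo + out$bin_hi) / 2
  attr(out, "mean_divergence_pct") <-
    sum(mid * out$abundance_pct) / sum(out$abundance_pct)
  attr(out, "total_pct") <- sum(out$abundance_pct)
  class(out) <- c("sat_landscape", class(out))
  out
}

#' Assembly-based divergence landscape from annotated loci
#'
#' @param loci Locus tibble with a `divergence` column
#'   (see [copy_divergence()]).
#' @param genome_bp Assembly size in bp.
#' @param bin_width Bin width (fraction).
#' @return A `sat_landscape` (see [build_landscape()]).
#' @export
landscape_from_loci <- function(loci, genome_bp, bin_width = 0.01) {
  assert_cols(loci, c("start", "end", "divergence"), "loci")
  build_landscape(loci$divergence, loci$end - loci$start, genome_bp,
                  bin_width = bin_width)
}

#' Read-based abundance and divergence surrogate
#'
#' Each read is compared against every family's consensus dimer (both
#' strands) with the same seed-and-extend matcher used for mapping, at a
#' deliberately permissive identity floor (default 0.60, versus 0.80 for
#' assembly mapping) mirroring read clustering's tolerance of divergent
#' copies. A read is assigned to its best-scoring family when the best
#' alignment reaches the floor and spans at least `min_span_frac` of the
#' read (a background-noise control). Family abundance is assigned aligned
#' bases over total read bases; per-read K2P feeds the read-based
#' landscape.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param catalog Catalog tibble.
#' @param min_identity Assignment identity floor (default 0.60).
#' @param min_span_frac Minimum aligned span as a fraction of read length.
#' @param params A [mapping_params()] (seed size and X-drop reused).
#' @param bin_width Landscape bin width (fraction).
#' @return List of class `sat_read_profile`: `per_family` (tibble
#'   `family_id`, `assigned_bp`, `pct_of_reads`), `landscape`
#'   (`sat_landscape`), `total_pct`, `mean_divergence_pct`,
#'   `n_reads_assigned`, `total_read_bp`.
#' @export
read_abundance <- function(reads, catalog, min_identity = 0.60,
                           min_span_frac = 0.30,
                           params = mapping_params(), bin_width = 0.01) {
  if (nrow(reads) == 0 || nrow(catalog) == 0) {
    stop("reads and catalog must be non-empty", call. = FALSE)
  }
  total_read_bp <- sum(nchar(reads$sequence))
  bm <- cpp_best_match(reads$sequence, strrep(catalog$sequence, 2),
                       params$seed_k, as.integer(params$xdrop))
  identity <- ifelse(bm$comparable > 0, bm$matches / bm$span, 0)
  assigned <- !is.na(bm$span) &
    identity >= min_identity &
    bm$span >= min_span_frac * nchar(reads$sequence)
  fam <- catalog$id[bm$subject_idx]
  per_family <- tibble::tibble(
    family_id = fam[assigned],
    bp = bm$span[assigned]
  ) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(assigned_bp = sum(.data$bp), .groups = "drop") |>
    dplyr::mutate(pct_of_reads = 100 * .data$assigned_bp / total_read_bp) |>
    dplyr::arrange(dplyr::desc(.data$assigned_bp))
  if (any(assigned)) {
    K <- k2p_from_counts(bm$transitions[assigned],
                         bm$transversions[assigned],
                         bm$comparable[assigned])
    landscape <- build_landscape(K, bm$span[assigned], total_read_bp,
                                 bin_width = bin_width)
  } else {
    # nothing assigned: an all-zero landscape, not an error
    landscape <- build_landscape(0, 0, total_read_bp,
                                 bin_width = bin_width)
    attr(landscape, "mean_divergence_pct") <- NA_real_
  }
  structure(
    list(
      per_family = per_family,
      landscape = landscape,
      total_pct = sum(per_family$pct_of_reads),
      mean_divergence_pct = attr(landscape, "mean_divergence_pct"),
      n_reads_assigned = sum(assigned),
      total_read_bp = total_read_bp
    ),
    class = "sat_read_profile"
  )
}

#' Compare assembly-based and read-based satellitome estimates
#'
#' Reports the two abundance totals, their ratio, the two abundance-
#' weighted mean divergences, and per-bin abundance differences. On real
#' data the mapped total and mean divergence sit below the read-based
#' values because assemblies collapse arrays and the mapping identity
#' threshold excludes divergent copies.
#'
#' @param assembly_landscape `sat_landscape` from [landscape_from_loci()].
#' @param read_landscape `sat_landscape` from [read_abundance()].
#' @return Object of class `sat_method_comparison`; see
#'   [tidy.sat_method_comparison()] and [glance.sat_method_comparison()].
#' @export
compare_methods <- function(assembly_landscape, read_landscape) {
  bins <- dplyr::full_join(
    tibble::as_tibble(assembly_landscape) |>
      dplyr::rename(mapped_pct = "abundance_pct"),
    tibble::as_tibble(read_landscape) |>
      dplyr::rename(read_pct = "abundance_pct"),
    by = c("bin_lo", "bin_hi")
  ) |>
    tidyr::replace_na(list(mapped_pct = 0, read_pct = 0)) |>
    dplyr::arrange(.data$bin_lo) |>
    dplyr::mutate(diff_pct = .data$mapped_pct - .data$read_pct)
  mapped_total <- attr(assembly_landscape, "total_pct")
  read_total <- attr(read_landscape, "total_pct")
  structure(
    list(
      bins = bins,
      mapped_total_pct = mapped_total,
      read_total_pct = read_total,
      mapped_to_read_ratio = mapped_total / read_total,
      mapped_mean_divergence_pct = attr(assembly_landscape,
                                        "mean_divergence_pct"),
      read_mean_divergence_pct = attr(read_landscape, "mean_divergence_pct")
    ),
    class = "sat_method_comparison"
  )
}

#' @describeIn compare_methods Per-bin abundance table (tidy method).
#' @param x A `sat_method_comparison`.
#' @param ... Unused.
#' @export
tidy.sat_method_comparison <- function(x, ...) {
  x$bins
}

#' @describeIn compare_methods One-row summary (glance method).
#' @export
glance.sat_method_comparison <- function(x, ...) {
  tibble::tibble(
    mapped_total_pct = x$mapped_total_pct,
    read_total_pct = x$read_total_pct,
    mapped_to_read_ratio = x$mapped_to_read_ratio,
    mapped_mean_divergence_pct = x$mapped_mean_divergence_pct,
    read_mean_divergence_pct = x$read_mean_divergence_pct
  )
}

#' @export
print.sat_method_comparison <- function(x, ...) {
  cat("Satellitome method comparison\n")
  cat(sprintf("  read-based total:   %.2f%% of read bases\n",
              x$read_total_pct))
  cat(sprintf("  mapped total:       %.2f%% of assembly\n",
              x$mapped_total_pct))
  cat(sprintf("  mapped/read ratio:  %.3f\n", x$mapped_to_read_ratio))
  cat(sprintf("  mean divergence:    %.2f%% (mapped) vs %.2f%% (reads)\n",
              x$mapped_mean_divergence_pct, x$read_mean_divergence_pct))
  invisible(x)
}
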