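#' Mapping parameters
#'
#' Bundles the thresholds used throughout mapping: minimum identity and
#' query coverage (both default 0.80), the e-value ceiling applied to
#' imported BLAST tabular hits (1e-5; the internal matcher computes no
#' e-values), the seed k-mer size, the X-drop for ungapped extension
#' (+1 match / -2 mismatch scoring), and the maximum gap across which
#' neighbouring hits of one family are merged into a single locus.
#'
#' @param min_identity Minimum identity fraction in (0, 1].
#' @param min_query_cov Minimum query coverage fraction in (0, 1].
#' @param max_evalue E-value ceiling for imported hits.
#' @param seed_k Seed k-mer size (>= 4).
#' @param max_gap_merge Maximum merge gap in bp (default 0: overlapping or
#'   exactly adjacent hits merge).
#' @param xdrop X-drop termination threshold for ungapped extension.
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(min_identity = 0.80, min_query_cov = 0.80,
                           max_evalue = 1e-5, seed_k = 13,
                           max_gap_merge = 0, xdrop = 20) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_query_cov > 0, min_query_cov <= 1, seed_k >= 4)
  structure(
    list(min_identity = min_identity, min_query_cov = min_query_cov,
         max_evalue = max_evalue, seed_k = as.integer(seed_k),
         max_gap_merge = as.integer(max_gap_merge), xdrop = xdrop),
    class = "mapping_params"
  )
}

#' Build a k-mer index over an assembly
#'
#' Exact k-mers of the forward strand of every chromosome are indexed;
#' k-mers containing N (or any ambiguity code) are skipped. Reverse-strand
#' matches are found at query time by reverse-complementing the query.
#'
#' @param assembly Assembly tibble (`chrom`, `sequence`).
#' @param k K-mer size.
#' @return A list of class `genome_index`.
#' @export
index_genome <- function(assembly, k = 13) {
  assert_cols(assembly, c("chrom", "sequence"), "assembly")
  if (k > min(nchar(assembly$sequence))) {
    stop("k exceeds the shortest chromosome", call. = FALSE)
  }
  structure(
    list(
      chrom = assembly$chrom,
      chrom_lengths = chrom_lengths_of(assembly),
      k = as.integer(k),
      ptr = lapply(assembly$sequence, cpp_build_index, k = as.integer(k))
    ),
    class = "genome_index"
  )
}

#' Look up the positions of an exact k-mer
#'
#' @param index A [index_genome()] result.
#' @param kmer A string of length `k`; k-mers containing N never match.
#' @return Tibble with `chrom` and `pos` (0-based) of every occurrence on
#'   the forward strand.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "genome_index"))
  purrr::map2_dfr(index$chrom, index$ptr, function(chrom, ptr) {
    pos <- cpp_index_lookup(ptr, kmer)
    tibble::tibble(chrom = rep(chrom, length(pos)), pos = pos)
  })
}

empty_hits <- function() {
  tibble::tibble(
    family_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), identity = double(),
    query_coverage = double(), evalue = double()
  )
}

#' Map satDNA consensus monomers with the seed-and-extend matcher
#'
#' For every exact seed k-mer shared between a family monomer (either
#' orientation) and the assembly, the match is extended ungapped in both
#' directions under +1/-2 scoring with X-drop termination; extensions from
#' seeds on the same diagonal are deduplicated to maximal segments. Each
#' hit reports identity over its aligned span and query coverage
#' (span / monomer length). No e-value is computed for internal hits.
#'
#' @param catalog Catalog tibble from [read_fasta()].
#' @param index A [index_genome()] result.
#' @param params A [mapping_params()].
#' @return Unfiltered hit tibble (`family_id`, `chrom`, `start`, `end`,
#'   `strand`, `identity`, `query_coverage`, `evalue` = NA).
#' @export
seed_and_extend <- function(catalog, index, params = mapping_params()) {
  stopifnot(inherits(index, "genome_index"))
  assert_cols(catalog, c("id", "sequence"), "catalog")
  res <- vector("list", nrow(catalog) * length(index$chrom))
  n <- 0
  for (fi in seq_len(nrow(catalog))) {
    fam <- catalog$id[fi]
    q <- catalog$sequence[fi]
    if (nchar(q) < index$k) next
    for (ci in seq_along(index$chrom)) {
      df <- cpp_seed_extend(index$ptr[[ci]], q, as.integer(params$xdrop))
      if (nrow(df) == 0) next
      n <- n + 1
      res[[n]] <- tibble::tibble(
        family_id = fam,
        chrom = index$chrom[ci],
        start = df$sstart,
        end = df$send,
        strand = df$strand,
        identity = ifelse(df$comparable > 0,
                          df$matches / (df$send - df$sstart), 0),
        query_coverage = (df$qend - df$qstart) / nchar(q),
        evalue = NA_real_
      )
    }
  }
  if (n == 0) return(empty_hits())
  dplyr::bind_rows(res[seq_len(n)])
}

#' Filter hits on identity, query coverage and (when present) e-value
#'
#' @param hits Hit tibble ([seed_and_extend()] or [parse_blast_tab()]).
#' @param params A [mapping_params()].
#' @return The surviving hits.
#' @export
filter_hits <- function(hits, params = mapping_params()) {
  assert_cols(hits, c("identity", "query_coverage"), "hits")
  keep <- hits$identity >= params$min_identity &
    hits$query_coverage >= params$min_query_cov
  if ("evalue" %in% names(hits)) {
    keep <- keep & (is.na(hits$evalue) | hits$evalue <= params$max_evalue)
  }
  hits[keep, , drop = FALSE]
}

#' Merge overlapping hits of one family into discrete loci
#'
#' Per (family, chromosome), hits from both strands are pooled, sorted by
#' start, and unioned whenever the gap to the next hit is at most
#' `max_gap_merge` bp. The resulting locus is strandless; its copy number
#' downstream is the locus count, so head-to-tail tandem runs count as one
#' locus. `monomer_units` (locus length / monomer length) is reported
#' alongside when the catalog is supplied.
#'
#' @param hits Filtered hit tibble.
#' @param max_gap_merge Maximum gap in bp (default 0).
#' @param catalog Optional catalog tibble to derive `monomer_units`.
#' @return Locus tibble: `family_id`, `chrom`, `start`, `end`,
#'   `n_hits_merged`, `mean_identity`, and optionally `monomer_units`.
#' @export
merge_hits <- function(hits, max_gap_merge = 0, catalog = NULL) {
  assert_cols(hits, c("family_id", "chrom", "start", "end", "identity"),
              "hits")
  if (nrow(hits) == 0) {
    out <- tibble::tibble(
      family_id = character(), chrom = character(), start = integer(),
      end = integer(), n_hits_merged = integer(), mean_identity = double()
    )
    if (!is.null(catalog)) out$monomer_units <- double()
    return(out)
  }
  loci <- hits |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(
      .new_run = .data$start > cummax(dplyr::lag(.data$end,
                                                 default = dplyr::first(.data$end))) +
        max_gap_merge,
      .run = cumsum(.data$.new_run)
    ) |>
    dplyr::group_by(.data$family_id, .data$chrom, .data$.run) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_hits_merged = dplyr::n(),
      mean_identity = mean(.data$identity),
      .groups = "drop"
    ) |>
    dplyr::select(-".run") |>
    dplyr::arrange(.data$family_id, .data$chrom, .data$start)
  if (!is.null(catalog)) {
    loci <- loci |>
      dplyr::left_join(
        dplyr::select(catalog, family_id = "id", monomer_length = "length"),
        by = "family_id"
      ) |>
      dplyr::mutate(
        monomer_units = (.data$end - .data$start) / .data$monomer_length
      ) |>
      dplyr::select(-"monomer_length")
  }
  loci
}

#' Map a catalog onto an assembly: index, match, filter, merge
#'
#' Convenience wrapper running [index_genome()], [seed_and_extend()] (or
#' taking pre-parsed BLAST hits), [filter_hits()] and [merge_hits()].
#'
#' @param catalog Catalog tibble.
#' @param assembly Assembly tibble.
#' @param params A [mapping_params()].
#' @param hits Optional externally produced hit tibble (e.g. from
#'   [parse_blast_tab()]); when given, the internal matcher is skipped.
#' @return Locus tibble (see [merge_hits()]).
#' @export
map_families <- function(catalog, assembly, params = mapping_params(),
                         hits = NULL) {
  if (is.null(hits)) {
    index <- index_genome(assembly, params$seed_k)
    hits <- seed_and_extend(catalog, index, params)
  }
  hits |>
    filter_hits(params) |>
    merge_hits(params$max_gap_merge, catalog = catalog)
}
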