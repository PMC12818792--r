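#' Read a FASTA file into a tibble
#'
#' Reads a multi-FASTA file (a satDNA consensus catalog or a genome assembly)
#' and returns one row per record. Sequences are uppercased; record order is
#' preserved; the record id is the header up to the first whitespace.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A tibble with columns `id`, `sequence`, `length`. For a catalog,
#'   `id` is the family id and `length` the monomer length in bp.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  tibble::tibble(id = ids, sequence = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` (or `chrom`/`family_id`) and
#'   `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  id_col <- intersect(c("id", "chrom", "family_id", "read_id"), names(seqs))[1]
  if (is.na(id_col)) stop("no id column found", call. = FALSE)
  assert_cols(seqs, "sequence", "seqs")
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs[[id_col]]
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse BLAST tabular hits against a satDNA catalog
#'
#' Reads standard 12-column BLAST tabular output (outfmt 6: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' converts subject coordinates from 1-based inclusive to 0-based half-open,
#' normalizes minus-strand rows (`sstart > send`), and applies the mapping
#' filters: e-value at most `max_evalue`, identity at least `min_identity`,
#' and alignment length at least `min_query_cov` of the query monomer length.
#' Gapped columns count toward the alignment length.
#'
#' @param path Path to the tabular file.
#' @param catalog Catalog tibble from [read_fasta()] supplying monomer
#'   lengths (`id`, `length`).
#' @param max_evalue Maximum e-value (default `1e-5`).
#' @param min_identity Minimum identity fraction (default `0.80`).
#' @param min_query_cov Minimum query coverage fraction (default `0.80`).
#' @return A tibble of hits: `family_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`, `query_coverage`, `evalue`.
#' @export
parse_blast_tab <- function(path, catalog, max_evalue = 1e-5,
                            min_identity = 0.80, min_query_cov = 0.80) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- readr::read_tsv(
    path, col_names = cols, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", pident = "d", length = "i", mismatch = "i",
      gapopen = "i", qstart = "i", qend = "i", sstart = "i", send = "i",
      evalue = "d", bitscore = "d"
    )
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed BLAST tabular row at line %d of %s",
                 probs$row[1], path), call. = FALSE)
  }
  unknown <- setdiff(unique(raw$qseqid), catalog$id)
  if (length(unknown) > 0) {
    stop("query id(s) not in catalog: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  raw |>
    dplyr::left_join(
      dplyr::select(catalog, qseqid = "id", monomer_length = "length"),
      by = "qseqid"
    ) |>
    dplyr::mutate(
      strand = ifelse(.data$sstart <= .data$send, "+", "-"),
      start = pmin(.data$sstart, .data$send) - 1L,
      end = pmax(.data$sstart, .data$send),
      identity = .data$pident / 100,
      query_coverage = .data$length / .data$monomer_length
    ) |>
    dplyr::filter(
      .data$evalue <= max_evalue,
      .data$identity >= min_identity,
      .data$query_coverage >= min_query_cov
    ) |>
    dplyr::transmute(
      family_id = .data$qseqid, chrom = .data$sseqid,
      start = .data$start, end = .data$end, strand = .data$strand,
      identity = .data$identity, query_coverage = .data$query_coverage,
      evalue = .data$evalue
    )
}

#' Write loci (or hits) as BED6
#'
#' BED is 0-based half-open: columns chrom, start, end, name (family id),
#' score (`as.integer(identity * 1000)`), strand. Rows are sorted by
#' (chrom, start); merged loci, which are strandless, get strand `"."`.
#'
#' @param loci Tibble with `chrom`, `start`, `end`, `family_id` (or `name`),
#'   optionally `identity`/`mean_identity` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  assert_cols(loci, c("chrom", "start", "end"), "loci")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(loci)) return(loci[[nm]])
    NULL
  }
  name <- pick("family_id", "name") %||% rep(".", nrow(loci))
  ident <- pick("identity", "mean_identity") %||% rep(1, nrow(loci))
  strand <- pick("strand") %||% rep(".", nrow(loci))
  bed <- tibble::tibble(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    name = name, score = as.integer(ident * 1000), strand = strand
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to a BED6 file.
#' @return Tibble with `chrom`, `start`, `end`, `family_id`, `identity`
#'   (score / 1000), `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      family_id = character(), identity = double(), strand = character()
    ))
  }
  readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "family_id", "score",
                        "strand"),
    col_types = "ciicic", progress = FALSE
  ) |>
    dplyr::transmute(
      chrom = .data$chrom, start = .data$start, end = .data$end,
      family_id = .data$family_id, identity = .data$score / 1000,
      strand = .data$strand
    )
}
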