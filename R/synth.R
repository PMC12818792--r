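#' Synthetic satellitome generation
#'
#' The generator plants satellite-DNA arrays into random background sequence
#' under a Kimura-style substitution process and emits exact ground truth,
#' so every downstream step (mapping, quantification, classification,
#' divergence landscapes, telomere detection, method comparison) can be
#' validated against known answers.
#'
#' @name synth
NULL

#' Genome specification for the synthetic generator
#'
#' Defaults emulate a 15-chromosome bivalve-like complement at desk scale:
#' equal-length chromosomes, a centromere placed off-centre, and
#' `(TTAGGG)n` telomeric caps at both termini (`CCCTAA` units at the 5'
#' end of the forward strand, `TTAGGG` units at the 3' end).
#'
#' @param n_chromosomes Number of chromosomes (default 15).
#' @param chrom_length Chromosome length(s) in bp; scalar recycled.
#' @param centromere_frac Centromere position as a fraction of length.
#' @param telomere_units Number of telomeric hexamer units per terminus.
#' @param peri_band_frac Pericentromeric placement half-width as a fraction
#'   of chromosome length.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 15, chrom_length = 2e5,
                        centromere_frac = 0.45, telomere_units = 50,
                        peri_band_frac = 0.08) {
  lengths <- as.integer(rep_len(chrom_length, n_chromosomes))
  cen <- as.integer(round(lengths * centromere_frac))
  stopifnot(all(cen > 0), all(cen < lengths))
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom = sprintf("chr%d", seq_len(n_chromosomes)),
      chrom_lengths = stats::setNames(lengths,
                                      sprintf("chr%d", seq_len(n_chromosomes))),
      centromeres = tibble::tibble(
        chrom = sprintf("chr%d", seq_len(n_chromosomes)), position = cen
      ),
      telomere_units = as.integer(telomere_units),
      peri_band = as.integer(round(lengths * peri_band_frac))
    ),
    class = "genome_spec"
  )
}

#' Sample a random consensus monomer
#'
#' Uniform i.i.d. bases; deterministic given `seed`.
#'
#' @param length Monomer length in bp (>= 1).
#' @param seed Optional integer seed.
#' @return A DNA string of the requested length.
#' @export
sample_monomer <- function(length, seed = NULL) {
  if (length < 1) stop("monomer length must be >= 1", call. = FALSE)
  if (is.null(seed)) return(random_dna(length))
  withr::with_seed(seed, random_dna(length))
}

#' Mutate a monomer copy under a Kimura-style substitution process
#'
#' Exactly `round(divergence * length)` positions are chosen without
#' replacement and substituted; each substitution is a transition with
#' probability `kappa / (kappa + 2)` and otherwise one of the two
#' transversions, chosen uniformly. No indels, so coordinates stay exact.
#'
#' @param monomer DNA string.
#' @param divergence Target per-copy divergence in `[0, 0.3]` (substitution
#'   proportion; approximately the K2P distance at these levels).
#' @param kappa Transition/transversion rate ratio (> 0), default 2.
#' @param seed Optional integer seed.
#' @return A list with `sequence` (mutated string) and `n_sub` (realized
#'   substitution count).
#' @export
mutate_copy <- function(monomer, divergence, kappa = 2, seed = NULL) {
  if (divergence < 0 || divergence > 0.3) {
    stop("divergence must be in [0, 0.3]", call. = FALSE)
  }
  run <- function() {
    L <- nchar(monomer)
    m <- round(divergence * L)
    if (m == 0) return(list(sequence = monomer, n_sub = 0L))
    bases <- strsplit(monomer, NULL)[[1]]
    pos <- sample.int(L, m)
    transition_map <- c(A = "G", G = "A", C = "T", T = "C")
    transversion_map <- list(A = c("C", "T"), G = c("C", "T"),
                             C = c("A", "G"), T = c("A", "G"))
    is_ts <- stats::runif(m) < kappa / (kappa + 2)
    for (i in seq_len(m)) {
      b <- bases[pos[i]]
      if (!b %in% DNA_BASES) next
      bases[pos[i]] <- if (is_ts[i]) transition_map[[b]] else
        sample(transversion_map[[b]], 1)
    }
    list(sequence = paste(bases, collapse = ""), n_sub = m)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Sample a non-overlapping interval of width w within [lo, hi), avoiding
# `occupied` (2-col matrix of half-open intervals), with bounded retries.
place_interval <- function(w, lo, hi, occupied, min_spacing, retries = 500) {
  if (hi - lo < w) return(NULL)
  for (. in seq_len(retries)) {
    s <- lo + sample.int(hi - lo - w + 1, 1) - 1
    e <- s + w
    ok <- TRUE
    if (nrow(occupied) > 0) {
      ok <- all(s >= occupied[, 2] + min_spacing |
                  e <= occupied[, 1] - min_spacing)
    }
    if (ok) return(c(s, e))
  }
  NULL
}

#' Generate a synthetic genome with planted satellite arrays
#'
#' Background sequence is i.i.d. random; telomeric caps are written at both
#' termini of every chromosome; each family's copies are mutated from its
#' consensus monomer and planted according to its placement model:
#' `pericentromeric` (individual copies within the pericentromeric band),
#' `uniform` (individual copies anywhere), or `clustered` (one head-to-tail
#' tandem run at a random position). Individually placed copies keep a
#' minimum spacing of `min_spacing` bp so that merged loci correspond 1:1
#' to planted copies.
#'
#' @param genome A [genome_spec()].
#' @param families Tibble with columns `family_id`, `monomer_length`,
#'   `placement` (one of pericentromeric/uniform/clustered), `divergence`
#'   (target per-copy divergence), `kappa`.
#' @param copies Long tibble with columns `family_id`, `chrom`, `copies`.
#' @param seed Integer seed; the whole genome is deterministic given it.
#' @param min_spacing Minimum gap between individually placed copies (bp).
#' @return A list of class `sat_genome` with elements `assembly` (tibble
#'   `chrom`, `sequence`, `length`), `catalog` (tibble `id`, `sequence`,
#'   `length`), `truth` (tibble `family_id`, `chrom`, `start`, `end`,
#'   `strand`, `realized_divergence`, `array_id`), `centromeres`, and
#'   `spec` (the genome spec).
#' @export
generate_genome <- function(genome, families, copies, seed,
                            min_spacing = 50L) {
  stopifnot(inherits(genome, "genome_spec"))
  assert_cols(families, c("family_id", "monomer_length", "placement",
                          "divergence", "kappa"), "families")
  assert_cols(copies, c("family_id", "chrom", "copies"), "copies")
  if (anyDuplicated(families$family_id)) {
    stop("duplicate family_id in families", call. = FALSE)
  }
  bad_chrom <- setdiff(copies$chrom, genome$chrom)
  if (length(bad_chrom) > 0) {
    stop("copies reference unknown chromosome(s): ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  planted_bp <- copies |>
    dplyr::left_join(dplyr::select(families, "family_id", "monomer_length"),
                     by = "family_id") |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bp = sum(.data$copies * .data$monomer_length))
  over <- planted_bp$bp >= genome$chrom_lengths[planted_bp$chrom] * 0.8
  if (any(over)) {
    stop("planted bp approaches chromosome length on: ",
         paste(planted_bp$chrom[over], collapse = ", "), call. = FALSE)
  }

  withr::with_seed(seed, {
    catalog <- tibble::tibble(
      id = families$family_id,
      sequence = vapply(families$monomer_length, random_dna, character(1)),
      length = families$monomer_length
    )
    tel_fwd <- strrep("TTAGGG", genome$telomere_units)
    tel_rev <- strrep("CCCTAA", genome$telomere_units)
    tel_bp <- nchar(tel_fwd)

    seqs <- character(genome$n_chromosomes)
    truth <- vector("list", genome$n_chromosomes)
    for (ci in seq_len(genome$n_chromosomes)) {
      chrom <- genome$chrom[ci]
      len <- genome$chrom_lengths[[ci]]
      cen <- genome$centromeres$position[ci]
      band <- genome$peri_band[ci]
      s <- random_dna(len)
      if (tel_bp > 0) {
        substr(s, 1, tel_bp) <- tel_rev
        substr(s, len - tel_bp + 1, len) <- tel_fwd
      }
      # occupied half-open intervals (0-based): telomeres to start with
      occupied <- rbind(c(0, tel_bp), c(len - tel_bp, len))
      rows <- list()
      # pericentromeric families go first so the band is not blocked by
      # arrays that could have been placed anywhere
      fam_here <- copies |>
        dplyr::filter(.data$chrom == !!chrom, .data$copies > 0) |>
        dplyr::left_join(families, by = "family_id") |>
        dplyr::arrange(match(.data$placement,
                             c("pericentromeric", "clustered", "uniform")),
                       dplyr::desc(.data$monomer_length))
      for (fi in seq_len(nrow(fam_here))) {
        fam <- fam_here[fi, ]
        mono <- catalog$sequence[catalog$id == fam$family_id]
        L <- fam$monomer_length
        n_cop <- fam$copies
        if (fam$placement == "clustered") {
          iv <- place_interval(n_cop * L, tel_bp, len - tel_bp, occupied,
                               min_spacing)
          if (is.null(iv)) {
            stop("could not place clustered array of ", fam$family_id,
                 " on ", chrom, call. = FALSE)
          }
          occupied <- rbind(occupied, iv)
          at <- iv[1]
          aid <- sprintf("%s_%s_a%d", fam$family_id, chrom, fi)
          for (k in seq_len(n_cop)) {
            mut <- mutate_copy(mono, fam$divergence, fam$kappa)
            substr(s, at + 1, at + L) <- mut$sequence
            rows[[length(rows) + 1]] <- tibble::tibble(
              family_id = fam$family_id, chrom = chrom,
              start = at, end = at + L, strand = "+",
              realized_divergence = mut$n_sub / L, array_id = aid
            )
            at <- at + L
          }
        } else {
          lo <- if (fam$placement == "pericentromeric") {
            max(tel_bp, cen - band)
          } else tel_bp
          hi <- if (fam$placement == "pericentromeric") {
            min(len - tel_bp, cen + band)
          } else len - tel_bp
          for (k in seq_len(n_cop)) {
            iv <- place_interval(L, lo, hi, occupied, min_spacing)
            if (is.null(iv)) {
              stop("could not place copy ", k, " of ", fam$family_id,
                   " on ", chrom, call. = FALSE)
            }
            occupied <- rbind(occupied, iv)
            mut <- mutate_copy(mono, fam$divergence, fam$kappa)
            substr(s, iv[1] + 1, iv[2]) <- mut$sequence
            rows[[length(rows) + 1]] <- tibble::tibble(
              family_id = fam$family_id, chrom = chrom,
              start = iv[1], end = iv[2], strand = "+",
              realized_divergence = mut$n_sub / L,
              array_id = sprintf("%s_%s_u%d_%d", fam$family_id, chrom, fi, k)
            )
          }
        }
      }
      seqs[ci] <- s
      truth[[ci]] <- if (length(rows) > 0) dplyr::bind_rows(rows) else NULL
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(
        family_id = character(), chrom = character(), start = integer(),
        end = integer(), strand = character(),
        realized_divergence = double(), array_id = character()
      )
    }
    structure(
      list(
        assembly = tibble::tibble(chrom = genome$chrom, sequence = seqs,
                                  length = nchar(seqs)),
        catalog = catalog,
        truth = dplyr::arrange(truth, .data$chrom, .data$start),
        centromeres = genome$centromeres,
        spec = genome
      ),
      class = "sat_genome"
    )
  })
}

#' Plant interstitial telomeric arrays into an assembly
#'
#' Overwrites the background at the requested positions with `(TTAGGG)`
#' units, producing interstitial telomeric sequences (ITS) for testing the
#' telomere scanner.
#'
#' @param assembly Assembly tibble (`chrom`, `sequence`).
#' @param sites Tibble with `chrom`, `pos` (0-based start), `units`.
#' @return The modified assembly tibble.
#' @export
plant_its <- function(assembly, sites) {
  assert_cols(sites, c("chrom", "pos", "units"), "sites")
  for (i in seq_len(nrow(sites))) {
    j <- match(sites$chrom[i], assembly$chrom)
    if (is.na(j)) stop("unknown chromosome: ", sites$chrom[i], call. = FALSE)
    ins <- strrep("TTAGGG", sites$units[i])
    s <- assembly$sequence[j]
    substr(s, sites$pos[i] + 1, sites$pos[i] + nchar(ins)) <- ins
    assembly$sequence[j] <- s
  }
  assembly$length <- nchar(assembly$sequence)
  assembly
}

#' Simulate single-end shotgun reads from an assembly
#'
#' Read starts are uniform over valid positions on both strands; base-call
#' errors are i.i.d. substitutions at `error_rate`. The number of reads is
#' Poisson with mean `coverage * genome_size / read_length`.
#'
#' @param assembly Assembly tibble (`chrom`, `sequence`).
#' @param read_length Read length (must not exceed the shortest chromosome).
#' @param coverage Expected fold coverage (> 0).
#' @param error_rate Per-base substitution error rate.
#' @param seed Optional integer seed.
#' @return Tibble with `read_id`, `sequence`.
#' @export
simulate_reads <- function(assembly, read_length = 100, coverage = 2,
                           error_rate = 0.001, seed = NULL) {
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  lens <- nchar(assembly$sequence)
  if (read_length > min(lens)) {
    stop("read_length exceeds the shortest chromosome", call. = FALSE)
  }
  run <- function() {
    genome_bp <- sum(lens)
    n <- stats::rpois(1, coverage * genome_bp / read_length)
    if (n == 0) return(tibble::tibble(read_id = character(),
                                      sequence = character()))
    valid <- lens - read_length + 1
    ci <- sample.int(length(lens), n, replace = TRUE, prob = valid)
    starts <- floor(stats::runif(n) * valid[ci]) + 1
    reads <- substring(assembly$sequence[ci], starts,
                       starts + read_length - 1)
    flip <- stats::runif(n) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    if (error_rate > 0) {
      n_err <- stats::rbinom(n, read_length, error_rate)
      for (i in which(n_err > 0)) {
        b <- strsplit(reads[i], NULL)[[1]]
        pos <- sample.int(read_length, n_err[i])
        for (p in pos) {
          b[p] <- sample(setdiff(DNA_BASES, b[p]), 1)
        }
        reads[i] <- paste(b, collapse = "")
      }
    }
    tibble::tibble(read_id = sprintf("read%07d", seq_len(n)),
                   sequence = reads)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Collapse planted tandem arrays in a synthetic assembly
#'
#' Emulates assembly collapse of repetitive regions: each contiguous planted
#' array (consecutive truth rows of one family with zero gap, or a single
#' planted copy) is truncated to `ceiling(keep_fraction * copies)` copies by
#' removing trailing copies and splicing the sequence. Truth coordinates are
#' remapped onto the collapsed assembly. Positions in other tables (e.g.
#' centromeres) refer to the uncollapsed assembly.
#'
#' @param assembly Assembly tibble.
#' @param truth Ground-truth tibble from [generate_genome()].
#' @param keep_fraction Fraction of copies kept per array, in (0, 1].
#' @param seed Unused; kept for call-signature symmetry with the other
#'   generators (truncation is deterministic).
#' @return List with `assembly` (collapsed) and `truth` (remapped).
#' @export
collapse_arrays <- function(assembly, truth, keep_fraction, seed = NULL) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  if (keep_fraction == 1 || nrow(truth) == 0) {
    return(list(assembly = assembly, truth = truth))
  }
  if (!"array_id" %in% names(truth)) {
    stop("truth must carry the generator's array_id column", call. = FALSE)
  }
  drop <- truth |>
    dplyr::group_by(.data$array_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.copy = dplyr::row_number(),
                  .keep_n = ceiling(keep_fraction * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.copy > .data$.keep_n)
  new_assembly <- assembly
  new_truth <- truth
  for (ci in seq_len(nrow(assembly))) {
    chrom <- assembly$chrom[ci]
    cuts <- drop |>
      dplyr::filter(.data$chrom == !!chrom) |>
      dplyr::arrange(.data$start)
    if (nrow(cuts) == 0) next
    s <- assembly$sequence[ci]
    keep_parts <- character(0)
    prev <- 0
    for (i in seq_len(nrow(cuts))) {
      keep_parts <- c(keep_parts, substr(s, prev + 1, cuts$start[i]))
      prev <- cuts$end[i]
    }
    keep_parts <- c(keep_parts, substr(s, prev + 1, nchar(s)))
    new_assembly$sequence[ci] <- paste(keep_parts, collapse = "")
    # remap: shift = removed bp strictly before each kept interval
    removed_before <- function(pos) {
      vapply(pos, function(p) {
        sum(pmax(0L, pmin(cuts$end, p) - cuts$start))
      }, numeric(1))
    }
    sel <- new_truth$chrom == chrom
    kept <- !(paste(new_truth$array_id, new_truth$start) %in%
                paste(cuts$array_id, cuts$start)) & sel
    shift_start <- removed_before(new_truth$start[kept & sel])
    new_truth$start[kept & sel] <- new_truth$start[kept & sel] - shift_start
    new_truth$end[kept & sel] <- new_truth$end[kept & sel] -
      removed_before(new_truth$end[kept & sel])
    new_truth <- new_truth[!(sel & !kept), ]
  }
  new_assembly$length <- nchar(new_assembly$sequence)
  list(assembly = new_assembly,
       truth = dplyr::arrange(new_truth, .data$chrom, .data$start))
}

#' Default synthetic satellitome family table
#'
#' Draws a catalog of families emulating the structure reported for real
#' bivalve satellitomes: monomer lengths log-uniform over 22-2,891 bp,
#' per-family genomic abundance log-uniform (a few dominant families, a
#' long tail), per-copy divergence concentrated at 0-5% with a minority of
#' older, highly divergent families, and a mixture of placement modes with
#' about a quarter of families restricted to a single chromosome and a
#' subset present on every chromosome.
#'
#' @param genome A [genome_spec()].
#' @param n_families Number of families (default 100).
#' @param target_total_frac Target total planted fraction of the genome
#'   (default 0.09).
#' @param frac_specific Fraction of families planted on exactly one
#'   chromosome (default 0.25).
#' @param frac_pan Fraction planted on every chromosome (default 0.15).
#' @param frac_old Fraction of old families with divergence drawn from
#'   0.12-0.25, beyond the default mapping identity threshold
#'   (default 0.10).
#' @param seed Integer seed.
#' @return List with `families` and `copies` tibbles ready for
#'   [generate_genome()].
#' @export
default_family_specs <- function(genome, n_families = 100,
                                 target_total_frac = 0.09,
                                 frac_specific = 0.25, frac_pan = 0.15,
                                 frac_old = 0.10, seed = 1) {
  stopifnot(genome$n_chromosomes >= 4)
  withr::with_seed(seed, {
    ids <- sprintf("SynSat%03d", seq_len(n_families))
    mono <- round(exp(stats::runif(n_families, log(22), log(2891))))
    # keep very long monomers placeable inside the pericentromeric band
    placement <- sample(c("uniform", "pericentromeric", "clustered"),
                        n_families, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
    # pericentromeric satellites are modeled as mid-length monomers so the
    # individually placed copies fit the pericentromeric band
    placement[(mono > 1500 | mono < 150) & placement == "pericentromeric"] <-
      "uniform"
    n_old <- round(frac_old * n_families)
    d <- pmin(0.05, abs(stats::rnorm(n_families, 0.02, 0.015)))
    if (n_old > 0) {
      old_idx <- sample.int(n_families, n_old)
      d[old_idx] <- stats::runif(n_old, 0.12, 0.25)
    }
    genome_bp <- sum(genome$chrom_lengths)
    w <- exp(stats::runif(n_families, log(1), log(100)))
    fam_bp <- w / sum(w) * target_total_frac * genome_bp
    # chromosome breadth follows abundance rank, as in real satellitomes:
    # the dominant families are pan-chromosomal, the rare ones
    # chromosome-specific
    n_spec <- round(frac_specific * n_families)
    n_pan <- round(frac_pan * n_families)
    ord <- order(fam_bp, decreasing = TRUE)
    breadth <- sample(2:(genome$n_chromosomes - 1), n_families,
                      replace = TRUE)
    breadth[ord[seq_len(n_pan)]] <- genome$n_chromosomes
    breadth[ord[seq.int(n_families - n_spec + 1, n_families)]] <- 1L
    copies_rows <- vector("list", n_families)
    for (i in seq_len(n_families)) {
      total_copies <- max(1, round(fam_bp[i] / mono[i]))
      # families meant to be multi-chromosomal need at least two copies;
      # beyond that the bp budget, not the breadth draw, sets copy number
      total_copies <- max(total_copies, min(2L, breadth[i]))
      k <- min(breadth[i], total_copies)
      chroms <- sample(genome$chrom, k)
      split <- as.vector(stats::rmultinom(1, total_copies - k,
                                          rep(1, k))) + 1L
      if (placement[i] == "pericentromeric") {
        # keep each family's per-chromosome footprint (copies plus placement
        # spacing) well inside the pericentromeric band
        budget <- 0.6 * min(genome$peri_band)
        split <- pmin(split, max(1L, floor(budget / (mono[i] + 100))))
      }
      copies_rows[[i]] <- tibble::tibble(
        family_id = ids[i], chrom = chroms, copies = split
      )
    }
    list(
      families = tibble::tibble(
        family_id = ids, monomer_length = as.integer(mono),
        placement = placement, divergence = d, kappa = 2
      ),
      copies = dplyr::bind_rows(copies_rows)
    )
  })
}
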