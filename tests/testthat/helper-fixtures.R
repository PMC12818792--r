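# Small in-code fixtures shared across test files.

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

# a random sequence pair mutated at proportion d (substitutions only)
random_pair <- function(L, d, kappa = 2) {
  a <- sample_monomer(L)
  b <- mutate_copy(a, d, kappa = kappa)$sequence
  list(a = a, b = b)
}

# literal count-then-formula K2P, independent of the package implementation
k2p_oracle <- function(a, b) {
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  ts <- 0; tv <- 0
  for (i in seq_len(n)) {
    if (av[i] == bv[i]) next
    pur_a <- av[i] %in% c("A", "G")
    pur_b <- bv[i] %in% c("A", "G")
    if (pur_a == pur_b) ts <- ts + 1 else tv <- tv + 1
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# a minimal two-family synthetic genome used by several module tests
tiny_genome <- function(seed = 7, d2 = 0.05) {
  gs <- genome_spec(n_chromosomes = 4, chrom_length = 3e4,
                    telomere_units = 20)
  fam <- tibble::tibble(
    family_id = c("f1", "f2"),
    monomer_length = c(300L, 500L),
    placement = c("uniform", "clustered"),
    divergence = c(0, d2), kappa = 2
  )
  cop <- tibble::tibble(
    family_id = c("f1", "f1", "f2"),
    chrom = c("chr1", "chr2", "chr3"),
    copies = c(5L, 3L, 8L)
  )
  generate_genome(gs, fam, cop, seed = seed)
}

truth_intervals <- function(truth) {
  dplyr::arrange(
    tibble::tibble(family_id = truth$family_id, chrom = truth$chrom,
                   start = as.integer(truth$start),
                   end = as.integer(truth$end)),
    family_id, chrom, start
  )
}

loci_intervals <- function(loci) {
  dplyr::arrange(
    tibble::tibble(family_id = loci$family_id, chrom = loci$chrom,
                   start = as.integer(loci$start),
                   end = as.integer(loci$end)),
    family_id, chrom, start
  )
}
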