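test_that("sample_monomer is deterministic and respects length", {
  expect_identical(sample_monomer(40, seed = 3), sample_monomer(40, seed = 3))
  expect_equal(nchar(sample_monomer(668, seed = 1)), 668)
  expect_equal(nchar(sample_monomer(1783, seed = 1)), 1783)
  expect_error(sample_monomer(0), "length")
})

test_that("mutate_copy plants exactly round(d * L) substitutions", {
  m <- sample_monomer(668, seed = 5)
  out <- mutate_copy(m, 0, seed = 1)
  expect_identical(out$sequence, m)
  expect_equal(out$n_sub, 0L)

  out <- mutate_copy(m, 0.05, seed = 2)
  expect_equal(out$n_sub, 33)                       # round(0.05 * 668)
  diffs <- sum(strsplit(m, NULL)[[1]] != strsplit(out$sequence, NULL)[[1]])
  expect_equal(diffs, 33)

  expect_error(mutate_copy(m, 0.5), "divergence")
})

test_that("kappa controls the transition/transversion split", {
  m <- sample_monomer(2000, seed = 8)
  # kappa -> Inf: all substitutions are transitions, so Q == 0
  out <- mutate_copy(m, 0.1, kappa = 1e9, seed = 3)
  est <- k2p(m, out$sequence)
  expect_equal(est$Q, 0)
  expect_gt(est$P, 0.08)
})

test_that("K2P re-estimation of mutated copies recovers target divergence", {
  m <- sample_monomer(800, seed = 11)
  for (d in c(0.01, 0.03, 0.05, 0.08, 0.10)) {
    est <- k2p(m, mutate_copy(m, d, seed = round(1000 * d))$sequence)
    expect_lt(abs(est$K - d), 0.01)
  }
})

test_that("generate_genome with no families yields telomeres only", {
  gs <- genome_spec(n_chromosomes = 3, chrom_length = 2e4,
                    telomere_units = 10)
  g <- generate_genome(gs, tibble::tibble(
    family_id = character(), monomer_length = integer(),
    placement = character(), divergence = double(), kappa = double()
  ), tibble::tibble(family_id = character(), chrom = character(),
                    copies = integer()), seed = 1)
  expect_equal(nrow(g$truth), 0)
  expect_equal(nrow(g$assembly), 3)
  expect_true(all(startsWith(g$assembly$sequence, strrep("CCCTAA", 10))))
  expect_true(all(endsWith(g$assembly$sequence, strrep("TTAGGG", 10))))
})

test_that("planted copies land where requested and conserve bp", {
  gs <- genome_spec(n_chromosomes = 4, chrom_length = 3e4,
                    telomere_units = 10)
  fam <- tibble::tibble(family_id = "fx", monomer_length = 200L,
                        placement = "uniform", divergence = 0.02, kappa = 2)
  cop <- tibble::tibble(family_id = "fx", chrom = "chr3", copies = 12L)
  g <- generate_genome(gs, fam, cop, seed = 9)
  expect_equal(nrow(g$truth), 12)
  expect_true(all(g$truth$chrom == "chr3"))
  expect_equal(sum(g$truth$end - g$truth$start), 12 * 200)
  # planted intervals are mutually disjoint and inside the chromosome
  tr <- dplyr::arrange(g$truth, start)
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
  expect_true(all(tr$start >= 0 & tr$end <= 3e4))
})

test_that("ground truth is base-for-base consistent with the assembly", {
  g <- tiny_genome(seed = 13, d2 = 0.08)
  seqs <- stats::setNames(g$assembly$sequence, g$assembly$chrom)
  for (i in seq_len(nrow(g$truth))) {
    row <- g$truth[i, ]
    planted <- substring(seqs[row$chrom], row$start + 1, row$end)
    mono <- g$catalog$sequence[g$catalog$id == row$family_id]
    diffs <- sum(strsplit(planted, NULL)[[1]] != strsplit(mono, NULL)[[1]])
    expect_equal(diffs / nchar(mono), row$realized_divergence)
  }
})

test_that("simulate_reads matches the coverage expectation and is exact at zero error", {
  gs <- genome_spec(n_chromosomes = 2, chrom_length = 5e3,
                    telomere_units = 5)
  g <- generate_genome(gs, tibble::tibble(
    family_id = character(), monomer_length = integer(),
    placement = character(), divergence = double(), kappa = double()
  ), tibble::tibble(family_id = character(), chrom = character(),
                    copies = integer()), seed = 2)
  reads <- simulate_reads(g$assembly, read_length = 100, coverage = 1,
                          error_rate = 0, seed = 4)
  n <- nrow(reads)                     # expectation 100; Poisson tolerance
  expect_gt(n, 100 - 4 * 10)
  expect_lt(n, 100 + 4 * 10)
  hay <- c(g$assembly$sequence,
           as.character(Biostrings::reverseComplement(
             Biostrings::DNAStringSet(g$assembly$sequence))))
  found <- vapply(reads$sequence[seq_len(min(50, n))], function(r) {
    any(vapply(hay, function(h) grepl(r, h, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_true(all(found))
  expect_identical(
    simulate_reads(g$assembly, 100, 1, 0.01, seed = 4),
    simulate_reads(g$assembly, 100, 1, 0.01, seed = 4)
  )
  expect_error(simulate_reads(g$assembly, 100, 0), "coverage")
})

test_that("collapse_arrays truncates arrays and remaps truth", {
  gs <- genome_spec(n_chromosomes = 2, chrom_length = 4e4,
                    telomere_units = 10)
  fam <- tibble::tibble(family_id = "arr", monomer_length = 400L,
                        placement = "clustered", divergence = 0.01,
                        kappa = 2)
  cop <- tibble::tibble(family_id = "arr", chrom = c("chr1", "chr2"),
                        copies = c(10L, 10L))
  g <- generate_genome(gs, fam, cop, seed = 21)

  same <- collapse_arrays(g$assembly, g$truth, keep_fraction = 1)
  expect_identical(same$assembly, g$assembly)

  half <- collapse_arrays(g$assembly, g$truth, keep_fraction = 0.5)
  expect_equal(nrow(half$truth), 10)               # 5 copies kept per array
  before <- sum(g$truth$end - g$truth$start)
  after <- sum(half$truth$end - half$truth$start)
  expect_equal(after, before * 0.5)
  # remapped truth still matches the collapsed sequence base-for-base
  seqs <- stats::setNames(half$assembly$sequence, half$assembly$chrom)
  mono <- g$catalog$sequence[1]
  for (i in seq_len(nrow(half$truth))) {
    row <- half$truth[i, ]
    planted <- substring(seqs[row$chrom], row$start + 1, row$end)
    diffs <- sum(strsplit(planted, NULL)[[1]] != strsplit(mono, NULL)[[1]])
    expect_equal(diffs / nchar(mono), row$realized_divergence)
  }
  expect_error(collapse_arrays(g$assembly, g$truth, 0), "keep_fraction")
})
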