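test_that("k2p handles identical, worked, symmetric and excluded-column cases", {
  id <- k2p("ACGTACGT", "ACGTACGT")
  expect_equal(c(id$P, id$Q, id$K), c(0, 0, 0))

  # P = 0.1, Q = 0.05 over 200 columns
  a <- strrep("A", 200)
  b <- paste0(strrep("G", 20), strrep("C", 10), strrep("A", 170))
  wk <- k2p(a, b)
  expect_equal(wk$K, -0.5 * log(0.75 * sqrt(0.9)))
  expect_equal(round(wk$K, 4), 0.1702)
  expect_equal(k2p(a, b)$K, k2p(b, a)$K)

  # gap and N columns are excluded from the denominator
  g <- k2p("AC-GN", "ATCGA")
  expect_equal(g$comparable, 3)
  expect_equal(g$P, 1 / 3)

  expect_error(k2p("NNN", "NNN"), "comparable")
})

test_that("saturated pairs are flagged infinite, never clamped", {
  a <- strrep("A", 10)
  b <- strrep("G", 10)     # P = 1: 1 - 2P - Q < 0
  out <- k2p(a, b)
  expect_true(out$saturated)
  expect_equal(out$K, Inf)
})

test_that("k2p matches an independent count-then-formula oracle", {
  withr::with_seed(99, {
    for (i in 1:200) {
      pr <- random_pair(200, stats::runif(1, 0, 0.2))
      expect_equal(k2p(pr$a, pr$b)$K, k2p_oracle(pr$a, pr$b),
                   tolerance = 1e-12)
    }
  })
})

test_that("k2p agrees with ape's K80 distance", {
  skip_if_not_installed("ape")
  withr::with_seed(123, {
    for (i in 1:25) {
      pr <- random_pair(300, stats::runif(1, 0, 0.15))
      bin <- ape::as.DNAbin(lapply(list(pr$a, pr$b), function(x) {
        tolower(strsplit(x, NULL)[[1]])
      }))
      expect_equal(k2p(pr$a, pr$b)$K,
                   as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-10)
    }
  })
})

test_that("K2P dominates the p-distance (Jensen direction)", {
  withr::with_seed(7, {
    for (i in 1:50) {
      pr <- random_pair(300, stats::runif(1, 0.01, 0.2))
      est <- k2p(pr$a, pr$b)
      expect_gt(est$K, est$P + est$Q)
    }
  })
  expect_equal(k2p("AAAA", "AAAA")$K, 0)     # equality only at zero
})

test_that("copy_divergence recovers planted divergence, both strands", {
  g <- tiny_genome(seed = 51, d2 = 0.05)
  loci <- map_families(g$catalog, g$assembly)
  loci <- copy_divergence(loci, g$assembly, g$catalog)
  f1 <- dplyr::filter(loci, family_id == "f1")     # planted at d = 0
  expect_true(all(f1$divergence == 0))
  f2 <- dplyr::filter(loci, family_id == "f2")     # planted at d = 0.05
  expect_true(all(f2$divergence >= 0.03 & f2$divergence <= 0.07))

  # a reverse-complemented planted copy yields the same divergence
  mono <- g$catalog$sequence[g$catalog$id == "f1"]
  mut <- mutate_copy(mono, 0.04, seed = 3)$sequence
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mut)))
  asm <- tibble::tibble(
    chrom = c("p", "m"),
    sequence = c(paste0(sample_monomer(2000, seed = 4), mut,
                        sample_monomer(2000, seed = 5)),
                 paste0(sample_monomer(2000, seed = 4), rc,
                        sample_monomer(2000, seed = 5)))
  )
  loci2 <- tibble::tibble(family_id = "f1", chrom = c("p", "m"),
                          start = 2000L, end = 2000L + nchar(mut))
  div <- copy_divergence(loci2, asm, g$catalog)$divergence
  expect_equal(div[1], div[2])
  expect_gt(div[1], 0.02)
})

test_that("build_landscape bins abundance and conserves the total", {
  ls <- build_landscape(c(0.012, 0.018), c(100, 300), 1e4)
  expect_equal(ls$abundance_pct[ls$bin_lo == 1], 4)  # both in [1%, 2%)
  expect_equal(sum(ls$abundance_pct), attr(ls, "total_pct"))
  expect_equal(attr(ls, "total_pct"), 4)

  ls0 <- build_landscape(rep(0, 5), rep(10, 5), 1e3)
  expect_equal(ls0$abundance_pct[1], 5)
  expect_equal(attr(ls0, "mean_divergence_pct"), 0.5)  # first-bin midpoint

  expect_warning(ls2 <- build_landscape(c(0.01, NA), c(5, 5), 100),
                 "dropped")
  expect_equal(attr(ls2, "total_pct"), 5)
  expect_error(suppressWarnings(build_landscape(NA_real_, 1, 100)),
               "divergence")

  # bins extend beyond the default 30% edge rather than losing abundance
  ls3 <- build_landscape(c(0.02, 0.34), c(50, 50), 1e3)
  expect_equal(sum(ls3$abundance_pct), 10)
  expect_gte(max(ls3$bin_hi), 35)
})

test_that("read_abundance estimates planted genome fractions", {
  gs <- genome_spec(n_chromosomes = 2, chrom_length = 5e4,
                    telomere_units = 10)
  fam <- tibble::tibble(family_id = "ten", monomer_length = 500L,
                        placement = "clustered", divergence = 0.01,
                        kappa = 2)
  cop <- tibble::tibble(family_id = "ten", chrom = c("chr1", "chr2"),
                        copies = 10L)                  # 10 kb = 10 %
  g <- generate_genome(gs, fam, cop, seed = 61)
  reads <- simulate_reads(g$assembly, 100, coverage = 5, error_rate = 0,
                          seed = 62)
  prof <- read_abundance(reads, g$catalog)
  expect_lt(abs(prof$total_pct - 10), 1.5)
  expect_identical(read_abundance(reads, g$catalog)$total_pct,
                   prof$total_pct)                     # deterministic

  # background-only genome: false assignment stays below 0.1 %
  g0 <- generate_genome(gs, fam[0, ], cop[0, ], seed = 63)
  reads0 <- simulate_reads(g0$assembly, 100, coverage = 3, error_rate = 0,
                           seed = 64)
  catalog <- tibble::tibble(id = "decoy",
                            sequence = sample_monomer(600, seed = 65),
                            length = 600L)
  prof0 <- read_abundance(reads0, catalog)
  expect_lt(prof0$total_pct, 0.1)
})

test_that("mapping bias: divergent families shift mapped estimates down", {
  gs <- genome_spec(n_chromosomes = 3, chrom_length = 5e4,
                    telomere_units = 10)
  fam <- tibble::tibble(
    family_id = c("young", "old"), monomer_length = 500L,
    placement = "clustered", divergence = c(0.02, 0.25), kappa = 2
  )
  cop <- tibble::tibble(family_id = c("young", "young", "old"),
                        chrom = c("chr1", "chr2", "chr3"),
                        copies = c(10L, 10L, 6L))
  g <- generate_genome(gs, fam, cop, seed = 71)
  loci <- map_families(g$catalog, g$assembly)
  expect_false("old" %in% loci$family_id)      # beyond the 0.80 threshold
  loci <- copy_divergence(loci, g$assembly, g$catalog)
  map_land <- landscape_from_loci(loci, sum(nchar(g$assembly$sequence)))
  reads <- simulate_reads(g$assembly, 100, coverage = 4, error_rate = 0,
                          seed = 72)
  prof <- read_abundance(reads, g$catalog)
  expect_true("old" %in% prof$per_family$family_id)  # floor 0.60 keeps it
  cmp <- compare_methods(map_land, prof$landscape)
  expect_lt(cmp$mapped_mean_divergence_pct, cmp$read_mean_divergence_pct)
  expect_lt(cmp$mapped_total_pct, cmp$read_total_pct)

  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mapped_to_read_ratio,
               cmp$mapped_total_pct / cmp$read_total_pct)
  td <- tidy(cmp)
  expect_equal(sum(td$mapped_pct), cmp$mapped_total_pct)
  expect_equal(sum(td$read_pct), cmp$read_total_pct)
})
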