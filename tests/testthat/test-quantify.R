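mk_loci <- function(family_id, chrom, start, end) {
  tibble::tibble(family_id = family_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 n_hits_merged = 1L, mean_identity = 1)
}

test_that("per_chromosome_table counts copies and percentages", {
  loci <- mk_loci("f", "chr1", c(0, 200, 400), c(100, 300, 500))
  tab <- per_chromosome_table(loci, c(chr1 = 1000))
  expect_equal(tab$copies, 3L)
  expect_equal(tab$bp, 300)
  expect_equal(tab$pct_of_chrom, 30)

  loci2 <- mk_loci("f", "chr1", 0, 53000)
  tab2 <- per_chromosome_table(loci2, c(chr1 = 6e5, chr2 = 4e5))
  expect_equal(tab2$pct_of_genome, 5.3)

  expect_error(per_chromosome_table(mk_loci("f", "chrX", 0, 10),
                                    c(chr1 = 100)), "chrX")
})

test_that("genome_abundance sums per family and unions across families", {
  lens <- c(chr1 = 1e4, chr2 = 1e4)
  loci <- mk_loci("f", c("chr1", "chr2"), c(0, 0), c(100, 100))
  ab <- genome_abundance(loci, lens)
  expect_equal(ab$per_family$pct_of_genome, 1)      # 1% on each of two
  expect_equal(ab$total_pct, 1)

  # two families covering the same interval count once in the total
  loci2 <- mk_loci(c("f", "g"), "chr1", c(0, 0), c(200, 200))
  ab2 <- genome_abundance(loci2, lens)
  expect_equal(ab2$total_bp, 200)
  expect_equal(sum(ab2$per_family$bp), 400)

  expect_equal(genome_abundance(loci2[0, ], lens)$total_pct, 0)
})

test_that("classify_families follows the chromosome-count rules", {
  stats <- dplyr::bind_rows(
    per_chromosome_table(mk_loci("spec1", "chr12", 0, 100),
                         stats::setNames(rep(1e4, 15),
                                         sprintf("chr%d", 1:15))),
    per_chromosome_table(
      mk_loci("multi14", sprintf("chr%d", 1:14), rep(0, 14), rep(100, 14)),
      stats::setNames(rep(1e4, 15), sprintf("chr%d", 1:15))),
    per_chromosome_table(
      mk_loci("pan", sprintf("chr%d", 1:15), rep(200, 15), rep(300, 15)),
      stats::setNames(rep(1e4, 15), sprintf("chr%d", 1:15)))
  )
  catalog <- tibble::tibble(id = c("spec1", "multi14", "pan", "ghost"))
  cl <- classify_families(stats, 15, catalog = catalog)
  expect_equal(cl$category[cl$family_id == "spec1"], "chromosome_specific")
  expect_equal(cl$category[cl$family_id == "multi14"], "multi_chromosomal")
  expect_equal(cl$category[cl$family_id == "pan"], "pan_chromosomal")
  expect_equal(cl$category[cl$family_id == "ghost"], "unmapped")
  # partition: category counts sum to catalog size
  expect_equal(sum(table(cl$category)), nrow(catalog))
  # all three mapped families are below 10 copies per chromosome
  expect_true(all(cl$low_copy_flag))
})

test_that("gini_index matches the double-sum definition", {
  expect_equal(gini_index(c(2, 2, 2, 2)), 0)
  expect_equal(gini_index(c(0, 0, 0, 10)), 0.75)
  expect_equal(gini_index(5), 0)
})

test_that("clustered placement scores higher enrichment gini than uniform", {
  wins <- 0
  for (s in 1:20) {
    gs <- genome_spec(n_chromosomes = 4, chrom_length = 4e4,
                      telomere_units = 10)
    fam <- tibble::tibble(
      family_id = c("clu", "uni"), monomer_length = 200L,
      placement = c("clustered", "uniform"), divergence = 0, kappa = 2
    )
    cop <- tibble::tibble(family_id = c("clu", "uni"),
                          chrom = c("chr1", "chr2"), copies = 10L)
    g <- generate_genome(gs, fam, cop, seed = 100 + s)
    gini <- enrichment_gini(truth_intervals(g$truth),
                            chrom_lengths_of_truth <- c(chr1 = 4e4,
                                                        chr2 = 4e4,
                                                        chr3 = 4e4,
                                                        chr4 = 4e4),
                            window = 4e3)
    g_clu <- gini$gini[gini$family_id == "clu"]
    g_uni <- gini$gini[gini$family_id == "uni"]
    if (g_clu > g_uni) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("pericentromeric_fraction measures band membership", {
  cen <- tibble::tibble(chrom = "chr1", position = 500000)
  loci <- mk_loci("f", "chr1", c(449950, 519950, 899950),
                  c(450050, 520050, 900050))
  pf <- pericentromeric_fraction(loci, cen, band_halfwidth = 1e5)
  expect_equal(pf$pericentromeric_fraction, 2 / 3)
  pf0 <- pericentromeric_fraction(mk_loci("f", "chr1", 0, 100), cen, 1e5)
  expect_equal(pf0$pericentromeric_fraction, 0)
  pf1 <- pericentromeric_fraction(mk_loci("f", "chr1", 499000, 499100),
                                  cen, 1e5)
  expect_equal(pf1$pericentromeric_fraction, 1)
})

test_that("placement models are recovered via the pericentromeric fraction", {
  gs <- genome_spec(n_chromosomes = 4, chrom_length = 5e4,
                    telomere_units = 10, peri_band_frac = 0.08)
  fam <- tibble::tibble(
    family_id = c("peri", "uni"), monomer_length = 250L,
    placement = c("pericentromeric", "uniform"), divergence = 0.01,
    kappa = 2
  )
  cop <- tidyr::expand_grid(family_id = c("peri", "uni"),
                            chrom = sprintf("chr%d", 1:4)) |>
    dplyr::mutate(copies = 8L)
  g <- generate_genome(gs, fam, cop, seed = 77)
  pf <- pericentromeric_fraction(g$truth, g$centromeres,
                                 band_halfwidth = 0.08 * 5e4)
  expect_gte(pf$pericentromeric_fraction[pf$family_id == "peri"], 0.9)
  expect_lte(pf$pericentromeric_fraction[pf$family_id == "uni"], 0.3)
})

test_that("top_families_by_copies ranks, breaks ties, and caps at n", {
  lens <- c(chr1 = 1e4, chr2 = 1e4)
  stats <- dplyr::bind_rows(
    per_chromosome_table(mk_loci("b", "chr1", seq(0, 900, 100) + 0:9,
                                 seq(0, 900, 100) + 50 + 0:9), lens),
    per_chromosome_table(mk_loci("a", "chr2", seq(0, 400, 100),
                                 seq(0, 400, 100) + 50), lens),
    per_chromosome_table(mk_loci("c", "chr1", c(2000, 3000, 4000, 5000,
                                                6000),
                                 c(2050, 3050, 4050, 5050, 6050)), lens)
  )
  top2 <- top_families_by_copies(stats, 2)
  expect_equal(top2$family_id, c("b", "a"))         # 10 copies, then tie a/c
  expect_equal(top2$total_copies, c(10L, 5L))
  all3 <- top_families_by_copies(stats, 99)
  expect_equal(all3$family_id, c("b", "a", "c"))
  expect_equal(all3$chr1[all3$family_id == "b"], 10L)
  expect_equal(all3$chr2[all3$family_id == "b"], 0L)
  expect_error(top_families_by_copies(stats, 0), "n")
})
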