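#' Default pipeline configuration
#'
#' One document holding every tunable parameter of the pipeline, with all
#' defaults materialized. Unknown keys in a user-supplied config are
#' rejected; the resolved config is written next to the outputs of
#' [run_satellitome()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_chromosomes = 15L, chrom_length = 2e5,
                  centromere_frac = 0.45, telomere_units = 50L,
                  peri_band_frac = 0.08),
    families = list(n_families = 100L, target_total_frac = 0.09,
                    frac_specific = 0.25, frac_pan = 0.15,
                    frac_old = 0.10),
    mapping = list(min_identity = 0.80, min_query_cov = 0.80,
                   max_evalue = 1e-5, seed_k = 13L, max_gap_merge = 0L,
                   xdrop = 20),
    reads = list(read_length = 100L, coverage = 2, error_rate = 0.001,
                 min_identity = 0.60, min_span_frac = 0.30),
    collapse = list(keep_fraction = 1.0),
    quantify = list(min_copies = 10L, gini_window = 2e4,
                    gini_threshold = 0.8),
    landscape = list(bin_width = 0.01),
    telomere = list(motif = "TTAGGG", min_units = 5L,
                    max_mismatch_run = 1L, terminal_window = 1e4),
    ideogram = list(window = 1e4)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        stop("config key must be a mapping: ", full, call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and resolve a pipeline configuration
#'
#' @param config A YAML file path, a (possibly partial) named list, or
#'   `NULL` for the defaults. Unknown keys are rejected; defaults are
#'   materialized for everything unspecified.
#' @return The resolved config list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

#' Run the full synthetic-satellitome analysis pipeline
#'
#' Simulate -> (collapse) -> map -> quantify -> classify -> landscapes ->
#' read-based surrogate -> method comparison -> telomere scan, writing
#' every table as TSV (figures get a machine-readable twin), the resolved
#' config as YAML, and a run log. Reads are simulated from the full
#' genome; mapping runs against the (optionally collapsed) assembly,
#' emulating reference-assembly collapse of arrays. The telomere scan runs
#' on the uncollapsed assembly.
#'
#' @param config See [load_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_satellitome <- function(config = NULL, out_dir, figures = TRUE) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  logf("config written (seed=%d)", cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    gs <- genome_spec(
      n_chromosomes = cfg$genome$n_chromosomes,
      chrom_length = cfg$genome$chrom_length,
      centromere_frac = cfg$genome$centromere_frac,
      telomere_units = cfg$genome$telomere_units,
      peri_band_frac = cfg$genome$peri_band_frac
    )
    specs <- default_family_specs(
      gs, n_families = cfg$families$n_families,
      target_total_frac = cfg$families$target_total_frac,
      frac_specific = cfg$families$frac_specific,
      frac_pan = cfg$families$frac_pan,
      frac_old = cfg$families$frac_old,
      seed = cfg$seed
    )
    generate_genome(gs, specs$families, specs$copies, seed = cfg$seed)
  })
  logf("simulated %d chromosomes, %d families, %d planted copies",
       nrow(sim$assembly), nrow(sim$catalog), nrow(sim$truth))
  write_fasta(sim$catalog, file.path(out_dir, "catalog.fa"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  readr::write_tsv(sim$centromeres, file.path(out_dir, "centromeres.tsv"))

  reads <- stage("reads", simulate_reads(
    sim$assembly, read_length = cfg$reads$read_length,
    coverage = cfg$reads$coverage, error_rate = cfg$reads$error_rate,
    seed = cfg$seed + 1L
  ))
  logf("simulated %d reads", nrow(reads))

  ref <- stage("collapse", {
    if (cfg$collapse$keep_fraction < 1) {
      collapse_arrays(sim$assembly, sim$truth,
                      cfg$collapse$keep_fraction)$assembly
    } else sim$assembly
  })

  params <- mapping_params(
    min_identity = cfg$mapping$min_identity,
    min_query_cov = cfg$mapping$min_query_cov,
    max_evalue = cfg$mapping$max_evalue,
    seed_k = cfg$mapping$seed_k,
    max_gap_merge = cfg$mapping$max_gap_merge,
    xdrop = cfg$mapping$xdrop
  )
  loci <- stage("map", map_families(sim$catalog, ref, params))
  logf("mapped %d loci (%d families)", nrow(loci),
       dplyr::n_distinct(loci$family_id))
  write_bed(loci, file.path(out_dir, "loci.bed"))

  ref_lengths <- chrom_lengths_of(ref)
  stats <- stage("quantify", per_chromosome_table(loci, ref_lengths))
  abundance <- genome_abundance(loci, ref_lengths)
  classification <- classify_families(
    stats, nrow(ref), min_copies = cfg$quantify$min_copies,
    catalog = sim$catalog
  )
  top20 <- top_families_by_copies(stats, 20, chroms = ref$chrom)
  gini <- enrichment_gini(loci, ref_lengths,
                          window = cfg$quantify$gini_window,
                          threshold = cfg$quantify$gini_threshold)
  readr::write_tsv(stats, file.path(out_dir, "family_chrom_stats.tsv"))
  readr::write_tsv(classification, file.path(out_dir,
                                             "classification.tsv"))
  readr::write_tsv(tibble::as_tibble(top20),
                   file.path(out_dir, "top20_copy_matrix.tsv"))
  readr::write_tsv(gini, file.path(out_dir, "enrichment_gini.tsv"))
  logf("total mapped abundance %.2f%%", abundance$total_pct)

  loci <- stage("landscape",
                copy_divergence(loci, ref, sim$catalog, params))
  map_land <- landscape_from_loci(loci, sum(ref_lengths),
                                  bin_width = cfg$landscape$bin_width)
  readr::write_tsv(loci, file.path(out_dir, "loci_divergence.tsv"))
  readr::write_tsv(tibble::as_tibble(map_land),
                   file.path(out_dir, "landscape_mapped.tsv"))

  profile <- stage("read_abundance", read_abundance(
    reads, sim$catalog, min_identity = cfg$reads$min_identity,
    min_span_frac = cfg$reads$min_span_frac, params = params,
    bin_width = cfg$landscape$bin_width
  ))
  readr::write_tsv(profile$per_family,
                   file.path(out_dir, "read_abundance.tsv"))
  readr::write_tsv(tibble::as_tibble(profile$landscape),
                   file.path(out_dir, "landscape_reads.tsv"))

  comparison <- compare_methods(map_land, profile$landscape)
  jsonlite::write_json(glance(comparison),
                       file.path(out_dir, "method_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("read-based %.2f%% vs mapped %.2f%% (ratio %.3f)",
       comparison$read_total_pct, comparison$mapped_total_pct,
       comparison$mapped_to_read_ratio)

  tel <- stage("telomere", {
    scan_telomeric(sim$assembly, motif = cfg$telomere$motif,
                   min_units = cfg$telomere$min_units,
                   max_mismatch_run = cfg$telomere$max_mismatch_run) |>
      classify_terminal(chrom_lengths_of(sim$assembly),
                        terminal_window = cfg$telomere$terminal_window)
  })
  write_telomere_bed(tel, file.path(out_dir, "telomeres.bed"))
  readr::write_tsv(tel, file.path(out_dir, "telomeres.tsv"))
  logf("%d terminal / %d interstitial telomeric arrays",
       sum(tel$location_class == "terminal"),
       sum(tel$location_class == "interstitial"))

  if (figures) {
    stage("figures", {
      ggplot2::ggsave(file.path(out_dir, "landscape_mapped.png"),
                      autoplot(map_land), width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "landscape_reads.png"),
                      autoplot(profile$landscape), width = 7, height = 4,
                      dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "top20_heatmap.png"),
                      autoplot(top20), width = 8, height = 6, dpi = 150)
      dens <- ideogram_density(loci, ref_lengths,
                               window = cfg$ideogram$window)
      readr::write_tsv(dens, file.path(out_dir, "ideogram_density.tsv"))
      ggplot2::ggsave(file.path(out_dir, "ideogram.png"),
                      plot_ideogram(loci, ref_lengths,
                                    window = cfg$ideogram$window),
                      width = 8, height = 6, dpi = 150)
      invisible(NULL)
    })
  }

  invisible(list(
    config = cfg, genome = sim, reads = reads, reference = ref,
    loci = loci, stats = stats, abundance = abundance,
    classification = classification, top20 = top20, gini = gini,
    landscape_mapped = map_land, read_profile = profile,
    comparison = comparison, telomeres = tel
  ))
}
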