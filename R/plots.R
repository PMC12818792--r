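#' Plot a divergence landscape
#'
#' Bar plot of abundance per K2P divergence bin, the standard repeat-
#' landscape layout: recent amplification shows as mass near 0%.
#'
#' @param object A `sat_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sat_landscape <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$abundance_pct)) +
    ggplot2::geom_col(width = df$bin_hi[1] - df$bin_lo[1],
                      fill = "steelblue", colour = "grey30",
                      linewidth = 0.1) +
    ggplot2::labs(x = "Kimura substitution level (%)",
                  y = "Abundance (% of genome)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sat_landscape
#' @param landscape A `sat_landscape`.
#' @export
plot_landscape <- function(landscape, ...) autoplot.sat_landscape(landscape)

#' Per-window locus density table for ideograms
#'
#' The machine-readable twin of the ideogram figure: locus bp per window
#' per chromosome for one family (or all).
#'
#' @param loci Locus tibble.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param family Optional family id to restrict to.
#' @param window Window size in bp.
#' @return Tibble: `chrom`, `win_lo`, `win_hi`, `bp`, `density`.
#' @export
ideogram_density <- function(loci, chrom_lengths, family = NULL,
                             window = 1e4) {
  if (!is.null(family)) {
    if (!family %in% loci$family_id) {
      stop("unknown family: ", family, call. = FALSE)
    }
    loci <- dplyr::filter(loci, .data$family_id == !!family)
  }
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chrom) {
    edges <- seq(0, len, by = window)
    if (edges[length(edges)] < len) edges <- c(edges, len)
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    bp <- vapply(seq_len(length(edges) - 1), function(i) {
      lo <- edges[i]; hi <- edges[i + 1]
      sum(pmax(0, pmin(sub$end, hi) - pmax(sub$start, lo)))
    }, numeric(1))
    tibble::tibble(
      chrom = chrom, win_lo = edges[-length(edges)], win_hi = edges[-1],
      bp = bp, density = bp / (edges[-1] - edges[-length(edges)])
    )
  })
}

#' Ideogram with satDNA density shading
#'
#' One bar per chromosome scaled by length; per-window locus density is
#' shaded on a monotone colour ramp, mirroring density-shaded ideogram
#' figures used for chromosomal satDNA distributions.
#'
#' @inheritParams ideogram_density
#' @return A ggplot object.
#' @export
plot_ideogram <- function(loci, chrom_lengths, family = NULL,
                          window = 1e4) {
  dens <- ideogram_density(loci, chrom_lengths, family, window)
  dens$chrom <- factor(dens$chrom, levels = names(chrom_lengths))
  ggplot2::ggplot(dens) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$win_lo, xmax = .data$win_hi,
      ymin = as.integer(.data$chrom) - 0.35,
      ymax = as.integer(.data$chrom) + 0.35,
      fill = .data$density
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "satDNA bp / bp") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(dens$chrom)), labels = levels(dens$chrom)
    ) +
    ggplot2::labs(x = "Position (bp)", y = NULL,
                  title = family %||% "all families") +
    ggplot2::theme_minimal()
}

#' Copy-number heatmap of the top families
#'
#' Families (rows) ordered by decreasing total copy number; colour bounds
#' run from 0 to the matrix maximum.
#'
#' @param object A `sat_copy_matrix` from [top_families_by_copies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sat_copy_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-c("family_id", "total_copies"),
                        names_to = "chrom", values_to = "copies")
  df$family_id <- factor(df$family_id,
                         levels = rev(unique(object$family_id)))
  df$chrom <- factor(df$chrom, levels = setdiff(names(object),
                                                c("family_id",
                                                  "total_copies")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$family_id,
                                   fill = .data$copies)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(
      low = "white", high = "darkblue",
      limits = c(0, max(df$copies)), name = "copies"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sat_copy_matrix
#' @param matrix A `sat_copy_matrix`.
#' @export
plot_copy_heatmap <- function(matrix, ...) autoplot.sat_copy_matrix(matrix)
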