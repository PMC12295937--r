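#' Render the four diagnostic figures
#'
#' Writes (1) a per-species RSCU stacked-bar panel, (2) the ENC plot
#' (per-gene ENC against GC3s with the expected curve overlaid), (3) the
#' PR2-bias plot (unit square with centre lines at 0.5) and (4) the
#' neutrality plot (GC12 against GC3 with the fitted line and its
#' slope/adjusted R-squared annotated). Styling is deliberately plain and
#' configurable; it is not matched to any published figure.
#'
#' @param profiles Per-gene profiles (rows from [gene_bias_profiles()],
#'   possibly several species).
#' @param rscu_tables Named list of \code{rscu_table} objects (one per
#'   species).
#' @param regressions Named list of \code{neutrality_fit} objects keyed by
#'   species.
#' @param out_dir Output directory (created if needed).
#' @param formats Image formats to write; any of \code{"png"}, \code{"svg"}.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the character vector of files written; with empty
#'   inputs, a warning and no files.
#' @export
render_figures <- function(profiles, rscu_tables, regressions, out_dir,
                           formats = c("png", "svg"),
                           width = 7, height = 5, dpi = 150) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    warning("no profiles supplied; no figures rendered")
    return(invisible(character(0)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plots <- list(
    rscu = plot_rscu(rscu_tables),
    enc_plot = plot_enc(profiles),
    pr2_plot = plot_pr2(profiles),
    neutrality_plot = plot_neutrality(profiles, regressions)
  )
  written <- character(0)
  for (name in names(plots)) {
    for (fmt in formats) {
      f <- file.path(out_dir, paste0(name, ".", fmt))
      dev <- if (fmt == "svg") grDevices::svg else fmt
      ggplot2::ggsave(f, plots[[name]], device = dev, width = width,
                      height = height, dpi = dpi)
      written <- c(written, f)
    }
  }
  invisible(written)
}

plot_rscu <- function(rscu_tables) {
  long <- do.call(rbind, lapply(names(rscu_tables), function(sp) {
    tb <- as.data.frame(rscu_tables[[sp]])
    tb$species <- sp
    tb
  }))
  long <- long[!is.na(long$rscu), ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = aa, y = rscu,
                               fill = third_base)) +
    ggplot2::geom_col(position = "stack", colour = "grey30",
                      linewidth = 0.1) +
    ggplot2::facet_wrap(~species, ncol = 1) +
    ggplot2::labs(x = "Amino acid", y = "RSCU",
                  fill = "Third base") +
    ggplot2::theme_minimal()
}

plot_enc <- function(profiles) {
  curve_df <- data.frame(GC3s = seq(0, 1, by = 0.005))
  curve_df$ENC <- enc_expected(curve_df$GC3s)
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = GC3s, y = ENC,
                               colour = species)) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(x = GC3s,
                                                     y = ENC),
                       inherit.aes = FALSE, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::theme_minimal()
}

plot_pr2 <- function(profiles) {
  df <- profiles[!is.na(profiles$pr2_x) & !is.na(profiles$pr2_y), ]
  ggplot2::ggplot(df, ggplot2::aes(x = pr2_x, y = pr2_y,
                                   colour = species)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)") +
    ggplot2::theme_minimal()
}

plot_neutrality <- function(profiles, regressions) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = GC3, y = GC12,
                                    colour = species)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "GC3", y = "GC12") +
    ggplot2::theme_minimal()
  if (length(regressions) > 0) {
    lab <- paste(vapply(names(regressions), function(sp) {
      fit <- regressions[[sp]]
      sprintf("%s: slope %.4f, adj R2 %.4f", sp, fit$slope,
              fit$adj_r_squared)
    }, character(1)), collapse = "\n")
    p <- p + ggplot2::labs(subtitle = lab)
  }
  p
}
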