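#' Plot an I-site curve
#'
#' Mean I-site counts per generation with a one-standard-deviation band
#' across replicates; solid line for all invariant sites, dashed for the
#' tested-at-least-once adjusted count.
#'
#' @param x An [isite_curve()].
#' @param col Line color.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.isite_curve <- function(x, col = "#4B0082", ...) {
  g <- x$generation
  band <- grDevices::adjustcolor(col, alpha.f = 0.25)
  graphics::plot(g, x$i_all_mean, type = "n", ylim = c(0, x$n_sites),
                 xlab = "generation", ylab = "invariant sites",
                 main = paste0("I-sites (", x$mode, ")"), ...)
  if (!all(is.na(x$i_all_sd)))
    graphics::polygon(c(g, rev(g)),
                      c(x$i_all_mean + x$i_all_sd,
                        rev(x$i_all_mean - x$i_all_sd)),
                      col = band, border = NA)
  graphics::lines(g, x$i_all_mean, col = col, lwd = 2)
  graphics::lines(g, x$i_adj_mean, col = col, lwd = 2, lty = 2)
  graphics::legend("topright", legend = c("I_all", "I_adj"),
                   col = col, lty = c(1, 2), lwd = 2, bty = "n")
  invisible(x)
}

#' Heatmap of pairwise coupling strengths
#'
#' Displays [frobenius_coupling_map()] as an image, the standard view of
#' which site pairs carry coupling weight.
#'
#' @param model A [potts_model()].
#' @param ... Passed to [graphics::image()].
#' @return The coupling map matrix, invisibly.
#' @export
plot_coupling_map <- function(model, ...) {
  fm <- frobenius_coupling_map(model)
  n <- nrow(fm)
  graphics::image(seq_len(n), seq_len(n), fm,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "site", ylab = "site",
                  main = "Frobenius norm of couplings", ...)
  invisible(fm)
}
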