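# Base-graphics plots following the package's figure conventions.

#' Image of an ITPC Rayleigh Z matrix with sub-threshold masking
#'
#' Time-frequency image of Rayleigh Z; points at or below the display
#' threshold are rendered black.
#'
#' @param res an `itpc_result` from [itpc_events()].
#' @param z_threshold display threshold (default 5).
#' @param ... passed to [graphics::image()].
#' @export
plot_itpc_z <- function(res, z_threshold = 5, ...) {
  Z <- res$Z
  Zm <- Z
  Zm[!significance_mask(Z, z_threshold)] <- NA
  cols <- grDevices::hcl.colors(64, "viridis")
  graphics::image(res$time, seq_len(nrow(Z)), t(Zm),
                  col = cols, xlab = "time (s)", ylab = "band",
                  useRaster = TRUE, ...)
  graphics::rect(graphics::par("usr")[1], graphics::par("usr")[3],
                 graphics::par("usr")[2], graphics::par("usr")[4],
                 col = NA, border = "black")
  invisible(res)
}

#' Polar histogram of onset phases
#'
#' @param hist_res output of [onset_phase_histogram()].
#' @param main plot title.
#' @export
plot_phase_histogram <- function(hist_res, main = "onset phases") {
  counts <- hist_res$counts
  breaks <- hist_res$breaks
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rmax <- max(counts)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_along(counts)) {
    th <- seq(breaks[i], breaks[i + 1], length.out = 10)
    graphics::polygon(c(0, counts[i] * cos(th)),
                      c(0, counts[i] * sin(th)), col = "grey70")
  }
  graphics::arrows(0, 0, rmax * hist_res$r * cos(hist_res$mean_direction),
                   rmax * hist_res$r * sin(hist_res$mean_direction),
                   col = "red", lwd = 2, length = 0.08)
  invisible(hist_res)
}

#' Channel-adding curve with SD shading
#'
#' @param curve data.frame from [channel_adding()].
#' @param chance optional chance level drawn as a dashed line.
#' @export
plot_channel_adding <- function(curve, chance = NULL) {
  graphics::plot(curve$n_channels, curve$mean_accuracy, type = "n",
                 ylim = c(0, 1), xlab = "channels included",
                 ylab = "accuracy")
  graphics::polygon(c(curve$n_channels, rev(curve$n_channels)),
                    c(curve$mean_accuracy + curve$sd_accuracy,
                      rev(curve$mean_accuracy - curve$sd_accuracy)),
                    col = "grey85", border = NA)
  graphics::lines(curve$n_channels, curve$mean_accuracy, lwd = 2)
  if (!is.null(chance))
    graphics::abline(h = chance, lty = 2, col = "red")
  invisible(curve)
}
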