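#' Plot a Kaplan--Meier curve with fitted parametric overlays
#'
#' @param data Endpoint data frame (`time`, `event`).
#' @param models Named list of `survmodel`s to overlay.
#' @param main Plot title.
#' @param xmax Right edge of the time axis (days); defaults to 1.5x the
#'   largest observed time.
#' @return Invisibly, the x grid used.
#' @export
plot_km_fit <- function(data, models = list(), main = "", xmax = NULL) {
  km <- km_estimate(data)
  if (is.null(xmax)) xmax <- 1.5 * max(data$time)
  plot(c(0, km$time), c(1, km$surv), type = "s", ylim = c(0, 1),
       xlim = c(0, xmax), xlab = "days", ylab = "survival", main = main)
  xs <- seq(0, xmax, length.out = 300)
  for (i in seq_along(models)) {
    graphics::lines(xs, survival_at(models[[i]], xs), col = i + 1, lty = 2)
  }
  if (length(models)) {
    graphics::legend("topright", bty = "n", lty = c(1, rep(2, length(models))),
                     col = c(1, seq_along(models) + 1),
                     legend = c("Kaplan-Meier", names(models)))
  }
  invisible(xs)
}

#' Plot state occupancy over time
#'
#' For the 5-state structure, `combine_bm = TRUE` plots PF+BMIT and
#' PP+BMST as single curves, matching how the three structures are
#' usually compared (the brain-metastasis states refine the
#' pre/post-switch phases).
#'
#' @param x A `cohort_trace`.
#' @param combine_bm Combine brain-metastasis states with their parent
#'   phases (only relevant for 5-state traces).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_trace <- function(x, combine_bm = FALSE, ...) {
  occ <- x$occupancy
  if (combine_bm && all(c("BMIT", "BMST") %in% colnames(occ))) {
    occ <- cbind(`PF+BMIT` = occ[, "PF"] + occ[, "BMIT"],
                 `PP+BMST` = occ[, "PP"] + occ[, "BMST"],
                 Death = occ[, "Death"])
  }
  graphics::matplot(x$time / 365.25, occ, type = "l", lty = 1,
                    xlab = "years", ylab = "proportion of cohort",
                    main = x$structure, ylim = c(0, 1), ...)
  graphics::legend("right", bty = "n", lty = 1,
                   col = seq_len(ncol(occ)), legend = colnames(occ))
  invisible(x)
}
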