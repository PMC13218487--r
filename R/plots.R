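#' @import ggplot2
NULL

#' ECDF difference plot for SBC ranks
#'
#' One panel per parameter: the ECDF of the PIT ranks minus the uniform
#' diagonal, with simultaneous confidence bands; a curve escaping its band
#' indicates a calibration failure (ranks piling low mean overestimation,
#' high mean underestimation).
#'
#' @param sbc An [SBCResult-class] object.
#' @param parameters Parameters to plot (default all).
#' @param level Simultaneous band level.
#' @param bandSeed Seed for band calibration.
#' @return A ggplot object.
#' @export
plotEcdfDifference <- function(sbc, parameters = NULL, level = 0.95,
                               bandSeed = 1) {
  pars <- parameters %||% colnames(sbc@ranks)
  df <- do.call(rbind, lapply(pars, function(p) {
    e <- ecdfDifference(pitRanks(sbc, p), level = level, bandSeed = bandSeed)
    data.frame(parameter = p, x = e$x, diff = e$diff, lower = e$lower,
               upper = e$upper)
  }))
  ggplot(df, aes(x = .data$x)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), fill = "grey85") +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_step(aes(y = .data$diff), colour = "steelblue") +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "PIT rank", y = "ECDF difference") +
    theme_minimal()
}

#' Coverage plot for an SBC study
#'
#' True generating value against the 95% HPD interval for each replicate,
#' per parameter; intervals missing the truth are drawn in red.
#'
#' @param sbc An [SBCResult-class] object.
#' @param parameters Parameters to plot (default all).
#' @return A ggplot object.
#' @export
plotCoverage <- function(sbc, parameters = NULL) {
  pars <- parameters %||% colnames(sbc@ranks)
  df <- do.call(rbind, lapply(pars, function(p) {
    data.frame(parameter = p, true = sbc@trueValues[[p]],
               lo = sbc@hpdLow[[p]], hi = sbc@hpdHigh[[p]])
  }))
  df$inside <- df$true >= df$lo & df$true <= df$hi
  ggplot(df, aes(x = .data$true)) +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi,
                      colour = .data$inside), width = 0) +
    scale_colour_manual(values = c(`TRUE` = "steelblue", `FALSE` = "firebrick"),
                        guide = "none") +
    facet_wrap(~parameter, scales = "free") +
    labs(x = "true value", y = "95% HPD") +
    theme_minimal()
}

#' Clade reliability diagram
#'
#' Conditional event probability (isotonic fit) against posterior clade
#' support, with bootstrap bands; calibrated supports lie on the diagonal.
#'
#' @param rel Output of [cladeReliability()].
#' @return A ggplot object.
#' @export
plotReliability <- function(rel) {
  band <- data.frame(x = rel$bandGrid, lo = rel$bandLow, hi = rel$bandHigh)
  curve <- data.frame(x = rel$support, y = rel$cep)
  ggplot() +
    geom_ribbon(data = band, aes(x = .data$x, ymin = .data$lo,
                                 ymax = .data$hi),
                fill = "mediumpurple1", alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    geom_step(data = curve, aes(x = .data$x, y = .data$y),
              colour = "mediumpurple4") +
    coord_cartesian(xlim = 0:1, ylim = 0:1) +
    labs(x = "posterior clade probability",
         y = "conditional event probability") +
    theme_minimal()
}

#' Posterior predictive metric histograms
#'
#' One panel per adequacy metric: the predictive distribution with the
#' observed value and its mid-point two-tailed p-value.
#'
#' @param pps Output of [runPps()].
#' @return A ggplot object.
#' @export
plotPps <- function(pps) {
  sim <- utils::stack(pps$simulated)
  names(sim) <- c("value", "metric")
  obs <- data.frame(metric = names(pps$observed),
                    value = as.numeric(pps$observed),
                    label = sprintf("p[B] == %.3f", pps$pB))
  ggplot(sim, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "steelblue") +
    geom_vline(data = obs, aes(xintercept = .data$value), colour = "firebrick") +
    facet_wrap(~metric, scales = "free") +
    labs(x = "metric value", y = "predictive count") +
    theme_minimal()
}
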