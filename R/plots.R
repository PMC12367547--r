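#' Plot a power comparison curve
#'
#' MZ-differences power across the heritability grid, with horizontal
#' reference lines for the DRM power at the matched and large population
#' sample sizes. Requires \pkg{ggplot2}.
#'
#' @param x A `power_result` from [power_curve()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(h2 = x$h2_grid, power = x$power_mz)
  ggplot2::ggplot(df, ggplot2::aes(x = h2, y = power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = x$power_drm_matched, linetype = 2) +
    ggplot2::geom_hline(yintercept = x$power_drm_large, linetype = 3) +
    ggplot2::labs(x = "narrow-sense heritability",
                  y = sprintf("power at alpha = %g", x$alpha_sig),
                  title = "MZ-differences power vs population DRM",
                  subtitle = sprintf(
                    "dashed: DRM n = %d; dotted: DRM n = %d",
                    2 * x$n_pairs, x$n_large)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Plot the phantom-vQTL false-positive study
#'
#' False-positive rate of the MZ-differences and DRM tests across the LD
#' grid, with the nominal level marked. Requires \pkg{ggplot2}.
#'
#' @param x An `fdr_result` from [fdr_study()].
#' @return A ggplot object.
#' @export
plot_fdr_study <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(r2 = rep(x$r2_grid, 2),
                   fpr = c(x$fpr_mz, x$fpr_drm),
                   method = rep(c("MZ differences", "DRM (population)"),
                                each = length(x$r2_grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = r2, y = fpr, colour = method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = x$alpha_sig, linetype = 2) +
    ggplot2::labs(x = expression(LD~r^2~with~the~additive~locus),
                  y = sprintf("false-positive rate at alpha = %g",
                              x$alpha_sig)) +
    ggplot2::theme_minimal()
}
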