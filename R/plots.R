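#' Bar charts of experiment outcomes by condition
#'
#' Per-condition means with standard-error bars for the chosen outcome
#' variables, in the style of a factorial-comparison panel. Requires
#' ggplot2.
#'
#' @param results a `worksim_results` (see [run_matrix()]).
#' @param outcomes outcome columns to plot (default all eight).
#' @return A ggplot object.
#' @export
plot_condition_bars <- function(results, outcomes = outcome_variables()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_condition_bars() requires the ggplot2 package", call. = FALSE)
  }
  sm <- results$summary
  long <- do.call(rbind, lapply(outcomes, function(v) {
    data.frame(condition = sm$condition, outcome = v,
               mean = sm[[paste0("mean_", v)]], se = sm[[paste0("se_", v)]],
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = condition, y = mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 0.3) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
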