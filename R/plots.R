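# ggplot2 views of the result objects.

#' @rdname compute_phix_profile
#' @param object An `error_profile`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.error_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle,
                                       y = .data$pct_mismatch)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~mate, scales = "free_x") +
    ggplot2::labs(x = "sequencing cycle", y = "% mismatches",
                  title = "Control-derived per-cycle error rate",
                  subtitle = "dashed: 1% flagging threshold") +
    ggplot2::theme_minimal()
}

#' @rdname cardinality_histogram
#' @param object A `cardinality_histogram`.
#' @exportS3Method ggplot2::autoplot
autoplot.cardinality_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cardinality,
                                       y = .data$n_clusters)) +
    ggplot2::geom_col(width = 0.9, fill = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster cardinality", y = "number of clusters",
                  title = "Distribution of cluster cardinality") +
    ggplot2::theme_minimal()
}

#' @rdname fit_truncated_negbin
#' @param object A `negbin_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.negbin_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cardinality)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster cardinality", y = "number of clusters",
                  title = sprintf(
                    "Truncated NB fit: C = %.3g (p = %.3f, s = %.2f)",
                    object$C, object$p, object$s)) +
    ggplot2::theme_minimal()
}

#' @rdname assortment
#' @param object An `assortment_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.assortment_table <- function(object, ...) {
  d <- as.data.frame.table(object$log2_ratio, responseName = "log2_ratio")
  names(d)[1:2] <- c("fwd", "rev")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rev, y = .data$fwd,
                                  fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "reverse class", y = "forward class",
                  fill = "log2(obs/exp)",
                  title = "Primer-pair assortment vs independence") +
    ggplot2::theme_minimal()
}

#' Length distribution coloured by reading frame
#'
#' @param translated A [translate_clusters()] result.
#' @return A ggplot.
#' @export
plot_length_by_frame <- function(translated) {
  ggplot2::ggplot(translated,
                  ggplot2::aes(x = .data$nt_length,
                               fill = .data$frame_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "sequence length (nt)", y = "clusters",
                  fill = "frame",
                  title = "Cluster length distribution by reading frame") +
    ggplot2::theme_minimal()
}
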