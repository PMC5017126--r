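#' Running-sum profile for one gene set
#'
#' Recomputes the full running sum for a set against the fitted ranking and
#' draws it with the peak (the enrichment score) marked.
#'
#' @param fit a [gsea()] result.
#' @param set a gene-set name present in the fit.
#' @return A ggplot object.
#' @export
plot_running_sum <- function(fit, set) {
  stopifnot(inherits(fit, "gsea_result"))
  if (!set %in% names(fit$collection)) abort(sprintf("unknown set: %s", set))
  es <- enrichment_score(fit$ranking, fit$collection[[set]],
    exponent = fit$params$exponent
  )
  d <- tibble::tibble(position = seq_along(es$running_sum), running_sum = es$running_sum)
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::annotate("point",
      x = es$peak_index, y = es$es, colour = "red", size = 2
    ) +
    ggplot2::labs(
      title = set,
      subtitle = sprintf("ES = %.3f at position %d", es$es, es$peak_index),
      x = "rank position", y = "running enrichment sum"
    ) +
    ggplot2::theme_minimal()
}

#' NES summary bar chart
#'
#' One bar per gene set, signed NES, shaded by the leading-edge contribution
#' category and annotated with the nominal-p significance code — the style of
#' a two-class enrichment summary panel.
#'
#' @param object a [gsea()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- object$table |>
    dplyr::filter(!.data$flagged) |>
    dplyr::mutate(set = factor(.data$set, levels = rev(.data$set)))
  ggplot2::ggplot(d, ggplot2::aes(.data$nes, .data$set,
    fill = .data$contribution_category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$significance_code),
      hjust = ifelse(d$nes >= 0, -0.3, 1.3), size = 3
    ) +
    ggplot2::scale_fill_grey(
      start = 0.85, end = 0.1,
      limits = c("<20%", "20-50%", "50-75%", "75-100%"),
      name = "leading-edge\ncontribution"
    ) +
    ggplot2::labs(x = "normalized enrichment score (NES)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stemness-spectrum plot
#'
#' Background density of corpus distances to the stem consensus, with query
#' and reference groups overlaid as rug marks.
#'
#' @param object a [stem_spectrum()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stem_spectrum
#' @export
autoplot.stem_spectrum <- function(object, ...) {
  bg <- dplyr::filter(object, .data$group == "corpus")
  fg <- dplyr::filter(object, .data$group != "corpus")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$distance)) +
    ggplot2::labs(
      x = "fingerprint distance to stem consensus",
      y = "corpus density"
    ) +
    ggplot2::theme_minimal()
  if (nrow(bg) > 1) {
    p <- p + ggplot2::geom_density(data = bg, fill = "grey85", colour = "grey60")
  }
  if (nrow(fg) > 0) {
    p <- p + ggplot2::geom_rug(
      data = fg,
      ggplot2::aes(colour = .data$group),
      linewidth = 0.8
    )
  }
  p
}

#' @rdname autoplot.stem_spectrum
#' @param spectrum a [stem_spectrum()] tibble.
#' @export
plot_spectrum <- function(spectrum, ...) autoplot.stem_spectrum(spectrum, ...)
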