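#' Heatmap of signed log10 enrichment/depletion p-values
#'
#' Rows are SNPs, columns are populations (or groups). Cells are colored
#' red for enrichment (positive signed values) and green for depletion
#' (negative values), the conventional encoding for these matrices.
#'
#' @param x An [enrichment_matrix()] (or any numeric matrix).
#' @param row_tree,col_tree Optional `cluster_tree`s used to order the axes.
#' @param reorder Reorder axes by the trees (ignored when trees are NULL).
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(x, row_tree = NULL, col_tree = NULL,
                                    reorder = TRUE) {
  m <- as.matrix(x)
  if (reorder && !is.null(row_tree)) {
    m <- m[row_tree$labels[row_tree$order], , drop = FALSE]
  }
  if (reorder && !is.null(col_tree)) {
    m <- m[, col_tree$labels[col_tree$order], drop = FALSE]
  }
  df <- tibble::tibble(
    rsid = factor(
      rep(rownames(m), times = ncol(m)),
      levels = rev(rownames(m))
    ),
    stratum = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  lim <- max(abs(df$value), 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$rsid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(
      low = "green3", mid = "black", high = "red2",
      limits = c(-lim, lim), name = "signed\nlog10 p"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
      axis.text.y = ggplot2::element_text(size = 5)
    )
}

#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  plot_enrichment_heatmap(object, ...)
}

#' Box plot of composite risk scores per population
#'
#' Populations are ordered by mean score; boxes show quartiles and median,
#' whiskers extend 1.5 x IQR from the quartiles, and the mean is marked
#' with a plus symbol.
#'
#' @param scores A `risk_scores` tibble ([composite_risk_score()]).
#' @param by `"population"` or `"group"`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, by = c("population", "group")) {
  by <- match.arg(by)
  key <- if (by == "population") "pop" else "super_pop"
  means <- population_score_summary(scores, by = by)
  df <- dplyr::mutate(
    tibble::as_tibble(scores),
    stratum = factor(.data[[key]], levels = means$stratum)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$score)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(fill = .data$super_pop),
      outlier.shape = 1, coef = 1.5
    ) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 2) +
    ggplot2::labs(
      x = NULL, y = "composite genetic risk score", fill = "group"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)
    )
}

#' @export
autoplot.risk_scores <- function(object, ...) {
  plot_score_distribution(object, ...)
}

#' Scatter plot of prevalence against mean composite score, with OLS fit
#'
#' @param object A `prevalence_fit` ([prevalence_correlation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prevalence_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(.data$mean_score, .data$prevalence_pct)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE, color = "steelblue"
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$country),
      vjust = -0.6, size = 2.8
    ) +
    ggplot2::labs(
      x = "population mean composite risk score",
      y = "obesity prevalence (%)",
      subtitle = sprintf(
        "R^2 = %.2f, p = %.3g", g$r.squared, g$p.value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise LD matrix
#'
#' @param object An [ld_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    snp_a = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    snp_b = factor(
      rep(colnames(m), each = nrow(m)),
      levels = rev(colnames(m))
    ),
    r2 = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$snp_a, .data$snp_b)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r2)) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "red3", limits = c(0, 1), na.value = "grey85",
      name = expression(r^2)
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)
    )
}
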