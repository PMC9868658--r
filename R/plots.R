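# Plotting: score decomposition per isoform and template coverage maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the selection-score decomposition of a run
#'
#' Stacked bars of the weighted structural and mutation contributions per
#' isoform, faceted by gene; the winning isoform is marked.
#'
#' @param object An `isoselect_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.isoselect_run <- function(object, ...) {
  scores <- tidy(object)
  if (is.null(scores) || nrow(scores) == 0) {
    stop("no scored isoforms to plot", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(
      scores,
      structural = object$config$w1 * .data$structural_function,
      mutation = object$config$w2 * .data$mutation_function
    ),
    cols = c("structural", "mutation"),
    names_to = "component", values_to = "contribution"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$accession, y = .data$contribution, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$winner, .data$component == "structural"),
      ggplot2::aes(y = .data$selection), shape = 8, size = 3,
      show.legend = FALSE
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_name), scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "selection score contribution",
      title = "Isoform selection scores",
      subtitle = "* marks the isoform selected for modelling"
    ) +
    ggplot2::theme_minimal()
}

#' Coverage map of the templates selected for each isoform of a gene
#'
#' Horizontal segments show, per isoform, the intervals each selected
#' template newly contributed along the sequence.
#'
#' @param run An `isoselect_run`.
#' @param gene Gene symbol (must be part of the run).
#' @return A ggplot object.
#' @export
plot_coverage <- function(run, gene) {
  rep <- purrr::detect(run$reports, ~ identical(.x$gene_name, gene))
  if (is.null(rep) || !is.null(rep$failure)) {
    stop("no coverage available for gene ", gene, call. = FALSE)
  }
  seg <- purrr::list_rbind(purrr::imap(rep$coverages, function(cov, acc) {
    if (nrow(cov$selected) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(
        accession = acc,
        template_id = rep(cov$selected$template_id,
                          purrr::map_int(cov$selected$intervals, nrow))
      ),
      purrr::list_rbind(cov$selected$intervals)
    )
  }))
  lens <- tibble::tibble(
    accession = rep$isoforms$accession,
    length = rep$isoforms$length
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = 1, xend = .data$length, y = "sequence", yend = "sequence"),
      linewidth = 0.5, colour = "grey60"
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$template_id, yend = .data$template_id,
                   colour = .data$template_id),
      linewidth = 3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$accession), ncol = 1) +
    ggplot2::labs(x = "residue position", y = NULL,
                  title = paste0("Template coverage: ", gene)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
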