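#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Tidy and summary methods
#'
#' broom-style accessors: `tidy()` returns the per-unit result table of a
#' fitted/analysed object, `glance()` a one-row summary.
#'
#' @param x a `gsea_result`, `ora_result`, `mapping_report` or `gene_set`.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.gsea_result <- function(x, ...) {
  dplyr::mutate(x$results,
                n_leading_edge = lengths(.data$leading_edge),
                .after = "rank_at_max")
}

#' @rdname tidiers
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$results),
    n_significant = sum(x$results$fdr_q <= x$params$fdr_threshold, na.rm = TRUE),
    fdr_threshold = x$params$fdr_threshold,
    n_permutations = x$params$n_permutations,
    weight_exponent = x$params$weight_exponent,
    seed = x$params$seed,
    metric = x$ranked$metric)
}

#' @rdname tidiers
#' @export
tidy.ora_result <- function(x, ...) x$results

#' @rdname tidiers
#' @export
glance.ora_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$results),
    n_significant = sum(x$results$fdr <= 0.05),
    universe_policy = x$universe_policy,
    universe_size = x$universe_size,
    n_deg = x$n_deg,
    p_threshold = x$p_threshold)
}

#' @rdname tidiers
#' @export
glance.mapping_report <- function(x, ...) {
  tibble::tibble(
    n_input_rows = x$n_input_rows, n_unmapped = x$n_unmapped,
    n_multi_mapped = x$n_multi_mapped,
    n_synonym_resolved = x$n_synonym_resolved,
    n_collapsed_groups = x$n_collapsed_groups,
    n_output_genes = x$n_output_genes,
    strategy = x$strategy, mapping_version = x$mapping_version)
}

#' @rdname tidiers
#' @export
tidy.gene_set <- function(x, ...) as_tibble.gene_set(x)

#' Enrichment result plots
#'
#' `autoplot()` on a `gsea_result` draws NES per gene set coloured by FDR
#' significance; on an `ora_result`, -log10 FDR per set.
#' `plot_running_sum()` draws the running enrichment score of one set with
#' member positions as a rug.
#'
#' @param object a `gsea_result` or `ora_result`.
#' @param fdr_threshold significance colouring threshold.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gsea_result <- function(object, fdr_threshold = object$params$fdr_threshold, ...) {
  tb <- object$results
  tb$significant <- !is.na(tb$fdr_q) & tb$fdr_q <= fdr_threshold
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$set_name, .data$nes),
                                   y = .data$nes, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized enrichment score",
                  fill = sprintf("FDR <= %s", format(fdr_threshold))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gsea_result
#' @export
autoplot.ora_result <- function(object, fdr_threshold = 0.05, ...) {
  tb <- object$results
  tb$significant <- tb$fdr <= fdr_threshold
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$set_name, -.data$fdr),
                                   y = -log10(.data$fdr), fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 FDR",
                  fill = sprintf("FDR <= %s", format(fdr_threshold))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gsea_result
#' @param result a `gsea_result`.
#' @param set_name name of one analysed gene set.
#' @export
plot_running_sum <- function(result, set_name) {
  stopifnot(inherits(result, "gsea_result"))
  tb <- result$results
  i <- match(set_name, tb$set_name)
  if (is.na(i)) gsf_abort("unknown_set", sprintf("set '%s' not in this result", set_name))
  hits <- result$hits[[set_name]]
  absw <- abs(result$ranked$entries$score)^result$params$weight_exponent
  es <- es_stat(absw, hits, nrow(result$ranked$entries), want_running = TRUE)
  es$hits <- hits
  df <- tibble::tibble(rank = seq_along(es$running), running = es$running)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = tb$rank_at_max[i], colour = "red",
                        linetype = 3) +
    ggplot2::geom_rug(data = tibble::tibble(rank = es$hits),
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank in list", y = "Running enrichment score",
                  title = set_name,
                  subtitle = sprintf("ES = %.3f, NES = %.2f, FDR = %.3g",
                                     tb$es[i], tb$nes[i], tb$fdr_q[i])) +
    ggplot2::theme_minimal()
}
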