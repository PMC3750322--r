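#' Cross-contrast enrichment results matrix
#'
#' Collects one or more GSEA results (typically the same collection run
#' against several contrasts) into a single spreadsheet-style table: one
#' row per gene set (union across results, alphabetical), and per result a
#' group of the selected columns (`NES`, `FDR`, `rank`). A set absent from
#' a result is an explicit `NA`, never zero.
#'
#' @param results a named list of `gsea_result` objects (names label the
#'   column groups; unnamed lists fall back to the contrast of origin).
#' @param columns subset of `c("NES", "FDR", "rank")`.
#' @return tibble with `set_name` plus `<label>.<column>` columns.
#' @export
extract_results_matrix <- function(results, columns = c("NES", "FDR", "rank")) {
  if (inherits(results, "gsea_result")) results <- list(results)
  if (length(results) == 0L) gsf_abort("no_results", "no enrichment results supplied")
  bad <- setdiff(columns, c("NES", "FDR", "rank"))
  if (length(bad)) {
    gsf_abort("unknown_column",
      sprintf("unknown results column '%s' (available: NES, FDR, rank)", bad[1L]))
  }
  labels <- names(results) %||% rep("", length(results))
  fallback <- vapply(results, function(r) r$ranked$contrast_ref$contrast %||% "result", "")
  blank <- !nzchar(labels)
  labels[blank] <- fallback[blank]
  labels <- make.unique(labels, sep = "_")

  all_sets <- sort(unique(unlist(lapply(results, function(r) r$results$set_name))))
  out <- tibble::tibble(set_name = all_sets)
  field_of <- c(NES = "nes", FDR = "fdr_q", rank = "rank_at_max")
  for (i in seq_along(results)) {
    tb <- results[[i]]$results
    idx <- match(all_sets, tb$set_name)
    for (col in columns) {
      out[[paste0(labels[i], ".", col)]] <- tb[[field_of[[col]]]][idx]
    }
  }
  out
}

#' Leading-edge matrix of a GSEA result
#'
#' The leading edge of an enriched set is the run of member genes driving
#' its enrichment score (at or before `rank_at_max` for positive ES, at or
#' after it for negative ES). This matrix gathers, for every set passing
#' the FDR filter (columns), the union of their leading-edge genes (rows,
#' in ranked-list order) with cells holding boolean membership, the
#' gene's rank-metric score, or its 1-based rank in the list.
#'
#' @param result a `gsea_result`.
#' @param fdr_threshold keep sets with `fdr_q <= fdr_threshold`
#'   (default 0.05).
#' @param mode `"boolean"`, `"statistic"` or `"rank"`.
#' @return tibble: `gene_id`, `rank_in_list`, then one column per passing
#'   set (`NA`/`FALSE` outside the set's leading edge).
#' @export
extract_leading_edge_matrix <- function(result, fdr_threshold = 0.05,
                                        mode = c("boolean", "statistic", "rank")) {
  stopifnot(inherits(result, "gsea_result"))
  mode <- match.arg(mode)
  tb <- result$results
  pass <- !is.na(tb$fdr_q) & tb$fdr_q <= fdr_threshold
  if (!any(pass)) {
    gsf_abort("no_set_passes_threshold",
      sprintf("no gene set has FDR <= %s", format(fdr_threshold)))
  }
  tb <- tb[pass, , drop = FALSE]
  entries <- result$ranked$entries
  genes <- sort(unique(unlist(tb$leading_edge, use.names = FALSE)))
  rank_in_list <- match(genes, entries$gene_id)
  ord <- order(rank_in_list)
  genes <- genes[ord]; rank_in_list <- rank_in_list[ord]
  out <- tibble::tibble(gene_id = genes, rank_in_list = rank_in_list)
  for (i in seq_len(nrow(tb))) {
    inle <- genes %in% tb$leading_edge[[i]]
    out[[tb$set_name[i]]] <- switch(mode,
      boolean = inle,
      statistic = ifelse(inle, entries$score[rank_in_list], NA_real_),
      rank = ifelse(inle, rank_in_list, NA_integer_))
  }
  out
}

#' Write a results or leading-edge matrix as TSV
#'
#' Tab-delimited, header row included, missing values as `NA` — the layout
#' consumed by spreadsheet tools.
#'
#' @param x a data frame (e.g. from [extract_results_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
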