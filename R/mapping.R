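#' RefSeq curation-status vocabulary, best first
#'
#' Ordered quality tiers of a gene record's RefSeq annotation, used to pick
#' the best gene when one source ID maps to several.
#' @export
refseq_status_levels <- c("Reviewed", "Validated", "Provisional",
                          "Predicted", "Model", "Inferred", "Unknown")

#' Source-ID-to-gene mapping tables
#'
#' A mapping table relates source IDs (probe sets, gene symbols, Entrez
#' gene IDs) to gene-centric records carrying the official symbol, a RefSeq
#' curation status, and symbol synonyms. Tables are versioned
#' (`version` = build date + source label) so that every processed artifact
#' can be stamped for reproducibility.
#'
#' The file format is tab-delimited with a `#%version=` header line and the
#' columns `source_id`, `gene_id`, `official_symbol`, `refseq_status`,
#' `synonyms` (`|`-separated, may be empty). One row per (source_id,
#' gene_id) pair; a source ID appearing in several rows multi-maps.
#'
#' @param records data frame with columns `source_id` (chr), `gene_id`
#'   (positive int), `official_symbol` (chr), `refseq_status` (chr in
#'   [refseq_status_levels]), `synonyms` (list of chr, or `|`-separated chr).
#' @param version non-empty version tag.
#' @return a `mapping_table` with derived lookup indexes: `genes` (one row
#'   per gene), `symbol_index`, `synonym_index` (lower-cased keys;
#'   matching is case-insensitive, output case-preserving).
#' @export
mapping_table <- function(records, version) {
  stopifnot(is.character(version), length(version) == 1L, nzchar(version))
  records <- tibble::as_tibble(records)
  need <- c("source_id", "gene_id", "official_symbol", "refseq_status", "synonyms")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    gsf_abort("malformed_mapping_table",
      sprintf("mapping table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (is.character(records$synonyms)) {
    records$synonyms <- lapply(strsplit(records$synonyms, "|", fixed = TRUE),
                               function(s) s[nzchar(s)])
  }
  bad <- setdiff(unique(records$refseq_status), refseq_status_levels)
  if (length(bad)) {
    gsf_abort("malformed_mapping_table",
      sprintf("unknown RefSeq status '%s' (vocabulary: %s)", bad[1L],
              paste(refseq_status_levels, collapse = ", ")))
  }
  records$gene_id <- as.integer(records$gene_id)
  if (any(is.na(records$gene_id) | records$gene_id <= 0L)) {
    gsf_abort("malformed_mapping_table", "gene_id must be a positive integer")
  }

  genes <- records |>
    dplyr::distinct(.data$gene_id, .data$official_symbol, .data$refseq_status) |>
    dplyr::arrange(.data$gene_id)
  if (anyDuplicated(genes$gene_id)) {
    gsf_abort("malformed_mapping_table",
      sprintf("gene %d has inconsistent symbol/status across rows",
              genes$gene_id[duplicated(genes$gene_id)][1L]))
  }
  syn <- records |>
    dplyr::select("gene_id", "synonyms") |>
    tidyr::unnest_longer("synonyms", values_to = "synonym") |>
    dplyr::distinct()
  genes$synonyms <- lapply(genes$gene_id, function(g) syn$synonym[syn$gene_id == g])

  sym_key <- tolower(genes$official_symbol)
  if (anyDuplicated(sym_key)) {
    gsf_abort("malformed_mapping_table",
      sprintf("official symbol '%s' assigned to more than one gene",
              genes$official_symbol[duplicated(sym_key)][1L]))
  }
  symbol_index <- stats::setNames(genes$gene_id, sym_key)
  synonym_index <- if (nrow(syn)) {
    split(syn$gene_id, tolower(syn$synonym))
  } else list()

  structure(list(
    version = version,
    records = records,
    genes = genes,
    symbol_index = symbol_index,
    synonym_index = synonym_index
  ), class = "mapping_table")
}

#' @rdname mapping_table
#' @param file path to a mapping-table file (or its lines for `read_`,
#'   target path for `write_`).
#' @export
read_mapping_table <- function(file) {
  lines <- read_text_lines(file)
  meta <- grep("^#%", lines, value = TRUE)
  vline <- grep("^#%version=", meta, value = TRUE)
  if (length(vline) != 1L) {
    gsf_abort("malformed_mapping_table", "mapping table needs exactly one #%version= header line")
  }
  version <- sub("^#%version=", "", vline)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) c(x, rep("", length(header) - length(x))))
  mat <- matrix(unlist(cells, use.names = FALSE), ncol = length(header),
                byrow = TRUE, dimnames = list(NULL, header))
  rec <- tibble::as_tibble(mat)
  rec$gene_id <- as.integer(rec$gene_id)
  mapping_table(rec, version = version)
}

#' @rdname mapping_table
#' @param x a `mapping_table`.
#' @export
write_mapping_table <- function(x, file = NULL) {
  stopifnot(inherits(x, "mapping_table"))
  syn <- vapply(x$records$synonyms, paste, "", collapse = "|")
  lines <- c(
    paste0("#%version=", x$version),
    paste(c("source_id", "gene_id", "official_symbol", "refseq_status", "synonyms"),
          collapse = "\t"),
    paste(x$records$source_id, x$records$gene_id, x$records$official_symbol,
          x$records$refseq_status, syn, sep = "\t")
  )
  if (is.null(file)) return(lines)
  writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> version %s: %d source IDs, %d genes\n",
              x$version, dplyr::n_distinct(x$records$source_id), nrow(x$genes)))
  invisible(x)
}

gene_records <- function(table, gene_ids) {
  idx <- match(gene_ids, table$genes$gene_id)
  table$genes[idx, , drop = FALSE]
}

#' Resolve one source ID to candidate gene records
#'
#' Resolution depends on the ID type: `entrez` matches the gene ID
#' directly; `gene_symbol` matches the official symbol first and falls back
#' to synonyms only when no official symbol matches (official symbols take
#' precedence); `probe_set` returns every gene the probe maps to
#' (multi-mappings are returned in full — the caller decides whether to
#' fan out or pick the best record). Matching is case-insensitive for
#' symbols. An empty result means the ID is unmapped.
#'
#' @param id single source ID.
#' @param table a [mapping_table()].
#' @param id_type one of `"probe_set"`, `"gene_symbol"`, `"entrez"`.
#' @return tibble of gene records (possibly zero rows) with a
#'   `via_synonym` column.
#' @export
resolve_source_id <- function(id, table, id_type) {
  stopifnot(inherits(table, "mapping_table"))
  if (!id_type %in% c("probe_set", "gene_symbol", "entrez")) {
    gsf_abort("unknown_id_type", sprintf("unknown ID type '%s'", id_type))
  }
  id <- trimws(id)
  hit <- switch(id_type,
    entrez = {
      g <- suppressWarnings(as.integer(id))
      if (!is.na(g) && g %in% table$genes$gene_id) {
        list(gene_ids = g, via_synonym = FALSE)
      } else list(gene_ids = integer(0), via_synonym = FALSE)
    },
    gene_symbol = {
      key <- tolower(id)
      official <- table$symbol_index[key]
      if (!is.na(official)) {
        list(gene_ids = unname(official), via_synonym = FALSE)
      } else {
        syn <- table$synonym_index[[key]]
        list(gene_ids = sort(unique(syn %||% integer(0))), via_synonym = TRUE)
      }
    },
    probe_set = {
      g <- table$records$gene_id[table$records$source_id == id]
      list(gene_ids = sort(unique(g)), via_synonym = FALSE)
    })
  out <- gene_records(table, hit$gene_ids)
  out$via_synonym <- if (nrow(out)) hit$via_synonym else logical(0)
  out
}

#' Pick the best gene record by RefSeq status
#'
#' Among candidate records, selects the one with the best (earliest in
#' [refseq_status_levels]) curation status; ties are broken by the smallest
#' gene ID so the choice is deterministic.
#'
#' @param records tibble of gene records as returned by [resolve_source_id()].
#' @return a one-row tibble.
#' @export
select_best_gene <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    gsf_abort("empty_record_list", "no gene records to select from")
  }
  ord <- order(match(records$refseq_status, refseq_status_levels), records$gene_id)
  records[ord[1L], , drop = FALSE]
}

#' Map source IDs to genes and collapse to one row per gene
#'
#' Maps every row of a contrast dataset into the gene-centric ID space of
#' `table` and collapses multiple measurements per gene to a single
#' representative row, yielding a dataset ready for enrichment analysis
#' (which requires one value per gene). A source ID mapping to several
#' genes contributes its row to each gene's group (fan-out) before
#' collapsing; such rows are counted as multi-mapped in the report.
#'
#' Collapsing strategies (`strategy`):
#' \describe{
#'   \item{best_p}{keep the row with the smallest P; ties by largest |S|,
#'     then input order. Requires a P column.}
#'   \item{max_abs_s}{keep the row with the largest |S|. Requires S.}
#'   \item{max_a}{keep the row with the largest A. Requires A.}
#'   \item{mean}{per-column arithmetic mean of M, A and S across the
#'     group; for P the group minimum (conservatively optimistic —
#'     a mean of p-values would not be a p-value).}
#'   \item{auto}{`best_p` when P exists, else `max_abs_s`, else `max_a`,
#'     else `mean`.}
#' }
#' For the row-picking strategies the representative row per gene is chosen
#' once per dataset using the first contrast's values and reused for all
#' contrasts, keeping every contrast on the same underlying measurement
#' (per-contrast selection would mix probes within a gene and break
#' cross-contrast comparability). Rows with a missing value in the deciding
#' column rank worst. Output rows are ordered by gene ID.
#'
#' @param dataset a `contrast_dataset`.
#' @param table a [mapping_table()].
#' @param strategy collapsing strategy (see above).
#' @return list with `dataset` (a `gene_dataset`) and `report`
#'   (a `mapping_report`; see [glance.mapping_report()]).
#' @export
map_and_collapse <- function(dataset, table, strategy = "auto") {
  validate_contrast_dataset(dataset)
  stopifnot(inherits(table, "mapping_table"))
  strategy <- match.arg(strategy, c("auto", "best_p", "max_abs_s", "max_a", "mean"))
  letters_avail <- names(dataset$contrasts[[1L]])
  if (strategy == "auto") {
    strategy <- if ("P" %in% letters_avail) "best_p"
    else if ("S" %in% letters_avail) "max_abs_s"
    else if ("A" %in% letters_avail) "max_a"
    else "mean"
  }
  needs <- c(best_p = "P", max_abs_s = "S", max_a = "A")[strategy]
  if (!is.na(needs) && !needs %in% letters_avail) {
    gsf_abort("strategy_requires_column",
      sprintf("strategy '%s' requires column %s, absent from this dataset",
              strategy, needs))
  }

  id_type <- dataset$header$source_id_type
  ids <- dataset$source_ids
  uids <- unique(ids)
  res <- lapply(uids, resolve_source_id, table = table, id_type = id_type)
  names(res) <- uids
  n_genes_per_id <- vapply(res, nrow, 0L)[ids]
  via_syn <- vapply(res, function(r) any(r$via_synonym), NA)[ids]

  unmapped <- n_genes_per_id == 0L
  unmapped_ids <- unique(ids[unmapped])
  if (all(unmapped)) {
    gsf_abort("empty_after_mapping", "no source ID could be mapped to a gene")
  }

  # long mapped frame: one row per (input row, target gene)
  row_idx <- rep(seq_along(ids), n_genes_per_id)
  gene_id <- unlist(lapply(ids, function(i) res[[i]]$gene_id), use.names = FALSE)
  first <- dataset$contrasts[[1L]]

  key_order <- switch(strategy,
    best_p = {
      p <- first$P[row_idx]
      s <- if ("S" %in% letters_avail) abs(first$S[row_idx]) else rep(0, length(row_idx))
      p[is.na(p)] <- Inf
      s[is.na(s)] <- -Inf
      order_in_group <- order(gene_id, p, -s, row_idx)
      order_in_group
    },
    max_abs_s = {
      s <- abs(first$S[row_idx])
      s[is.na(s)] <- -Inf
      order(gene_id, -s, row_idx)
    },
    max_a = {
      a <- first$A[row_idx]
      a[is.na(a)] <- -Inf
      order(gene_id, -a, row_idx)
    },
    mean = order(gene_id, row_idx)
  )

  sorted_gene <- gene_id[key_order]
  sorted_row <- row_idx[key_order]
  grp_first <- !duplicated(sorted_gene)
  out_gene_ids <- sorted_gene[grp_first]
  grp_sizes <- as.vector(table(factor(sorted_gene, levels = out_gene_ids)))

  out_contrasts <- vector("list", length(dataset$contrasts))
  names(out_contrasts) <- names(dataset$contrasts)
  if (strategy == "mean") {
    gf <- factor(sorted_gene, levels = out_gene_ids)
    for (nm in names(dataset$contrasts)) {
      tb <- dataset$contrasts[[nm]]
      cols <- list()
      for (letter in letters_avail) {
        v <- tb[[letter]][sorted_row]
        cols[[letter]] <- if (letter == "P") {
          suppressWarnings(as.vector(tapply(v, gf, function(z)
            if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))))
        } else {
          as.vector(tapply(v, gf, function(z)
            if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)))
        }
      }
      out_contrasts[[nm]] <- tibble::as_tibble(cols)
    }
  } else {
    rep_rows <- sorted_row[grp_first]
    for (nm in names(dataset$contrasts)) {
      out_contrasts[[nm]] <- dataset$contrasts[[nm]][rep_rows, , drop = FALSE]
    }
  }

  symbols <- gene_records(table, out_gene_ids)$official_symbol
  gd <- structure(list(
    dataset_name = dataset$header$dataset_name,
    dataset_description = dataset$header$dataset_description,
    organism = dataset$header$organism,
    contrast_names = dataset$header$contrast_names,
    extraction_overrides = dataset$header$extraction_overrides,
    skip_gene_sets = dataset$header$skip_gene_sets,
    gene_ids = out_gene_ids,
    symbols = symbols,
    contrasts = out_contrasts,
    mapping_version = table$version,
    strategy = strategy
  ), class = "gene_dataset")

  report <- structure(list(
    n_input_rows = length(ids),
    n_unmapped = sum(unmapped),
    n_multi_mapped = sum(n_genes_per_id > 1L),
    n_synonym_resolved = sum(via_syn & !unmapped, na.rm = TRUE),
    n_collapsed_groups = sum(grp_sizes > 1L),
    n_output_genes = length(out_gene_ids),
    unmapped_ids = unmapped_ids,
    strategy = strategy,
    mapping_version = table$version
  ), class = "mapping_report")

  list(dataset = gd, report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<mapping_report> (mapping version %s, strategy %s)\n",
    "  input rows      %6d\n  unmapped rows   %6d\n  multi-mapped    %6d\n",
    "  via synonym     %6d\n  collapsed genes %6d\n  output genes    %6d\n"),
    x$mapping_version, x$strategy, x$n_input_rows, x$n_unmapped,
    x$n_multi_mapped, x$n_synonym_resolved, x$n_collapsed_groups, x$n_output_genes))
  invisible(x)
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat(sprintf("<gene_dataset> %s: %d genes x %d contrast(s) [%s], mapping %s\n",
              x$dataset_name, length(x$gene_ids), length(x$contrast_names),
              paste(x$contrast_names, collapse = ", "), x$mapping_version))
  invisible(x)
}

#' Per-contrast gene-level statistics
#'
#' @param gd a `gene_dataset` (output of [map_and_collapse()]).
#' @param contrast contrast name.
#' @return tibble with `gene_id`, `symbol` and the available M/A/P/S columns.
#' @export
contrast_table <- function(gd, contrast) {
  stopifnot(inherits(gd, "gene_dataset"))
  if (!contrast %in% gd$contrast_names) {
    gsf_abort("unknown_contrast", sprintf("unknown contrast '%s'", contrast))
  }
  dplyr::bind_cols(
    tibble::tibble(gene_id = gd$gene_ids, symbol = gd$symbols),
    gd$contrasts[[contrast]]
  )
}

#' @export
as_tibble.gene_dataset <- function(x, ...) {
  purrr::map_dfr(x$contrast_names, function(nm) {
    dplyr::mutate(contrast_table(x, nm), contrast = nm, .after = "symbol")
  })
}
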