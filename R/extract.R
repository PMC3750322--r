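#' Gene-set extraction parameters
#'
#' Thresholds controlling which genes of a contrast enter its UP / DN / AR
#' gene sets.
#'
#' @param p_threshold significance cutoff on P (p-value or FDR, whatever the
#'   dataset carries), in (0, 1]. Default 0.05.
#' @param m_threshold minimum |M| (effect size, e.g. log2 fold change);
#'   0 disables. Default 0.
#' @param a_threshold minimum A (average signal); `NULL` disables.
#' @param min_size sets smaller than this are not emitted (default 10).
#' @param max_size sets are truncated to their `max_size` most significant
#'   members (default 500).
#' @param fixed_size when set, UP and DN take exactly their top
#'   `fixed_size` genes by significance order, ignoring `p_threshold`
#'   (a desired size is an alternative to a significance cutoff).
#' @param skip when `TRUE` no sets are extracted for the contrast (e.g. an
#'   intercept coefficient).
#' @return an `extraction_params` list.
#' @export
extraction_params <- function(p_threshold = 0.05, m_threshold = 0,
                              a_threshold = NULL, min_size = 10,
                              max_size = 500, fixed_size = NULL,
                              skip = FALSE) {
  stopifnot(p_threshold > 0, p_threshold <= 1, m_threshold >= 0,
            is_count(min_size), is_count(max_size), min_size <= max_size,
            is.logical(skip), length(skip) == 1L)
  if (!is.null(fixed_size)) {
    stopifnot(is_count(fixed_size), fixed_size >= min_size, fixed_size <= max_size)
  }
  structure(list(p_threshold = p_threshold, m_threshold = m_threshold,
                 a_threshold = a_threshold, min_size = min_size,
                 max_size = max_size, fixed_size = fixed_size, skip = skip),
            class = "extraction_params")
}

merge_params <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  do.call(extraction_params, params[c("p_threshold", "m_threshold", "a_threshold",
                                      "min_size", "max_size", "fixed_size", "skip")])
}

new_gene_set <- function(name, suffix, members, description = "",
                         contrast_ref = NULL, params_used = NULL,
                         annotation_version = "", organism = "") {
  structure(list(
    name = name, suffix = suffix, description = description,
    members = members, contrast_ref = contrast_ref,
    params_used = params_used, annotation_version = annotation_version,
    organism = organism
  ), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (%s)%s\n", x$name, nrow(x$members),
              if (is.na(x$suffix)) "external" else x$suffix,
              if (nzchar(x$annotation_version)) paste0(" [", x$annotation_version, "]") else ""))
  invisible(x)
}

gene_set_name <- function(dataset, contrast, suffix) {
  sprintf("%s_[%s]_%s", dataset, contrast, suffix)
}

# significance order inside a set: ascending P (NA last), descending |S|,
# descending |M|, then gene_id -- fully deterministic
significance_order <- function(tb) {
  p <- if ("P" %in% names(tb)) tb$P else rep(NA_real_, nrow(tb))
  s <- if ("S" %in% names(tb)) abs(tb$S) else rep(0, nrow(tb))
  p[is.na(p)] <- Inf
  s[is.na(s)] <- -Inf
  order(p, -s, -abs(tb$M), tb$gene_id)
}

#' Extract UP / DN / AR gene sets from a contrast
#'
#' From a mapped, collapsed dataset, builds for each requested contrast the
#' sets of significantly up-regulated (UP, M > 0), down-regulated (DN,
#' M < 0) and all-regulated (AR = UP ∪ DN, the global response) genes.
#' Candidates satisfy `P <= p_threshold`, `|M| >= m_threshold` and, if set,
#' `A >= a_threshold`; genes with M = 0 or missing P never qualify. Members
#' are ranked by significance (ascending P, ties by descending |S|, then
#' |M|, then gene ID). Sets larger than `max_size` keep their top
#' `max_size`; sets smaller than `min_size` are recorded but not emitted;
#' with `fixed_size`, UP/DN/AR take exactly their top `fixed_size` genes
#' regardless of the significance cutoff. Per-contrast overrides declared
#' in the idMAPS header (and header-level skips) are honoured on top of
#' `params`. Set names follow `<dataset>_[<contrast>]_<suffix>`.
#'
#' @param gd a `gene_dataset` from [map_and_collapse()].
#' @param contrast a contrast name, or `NULL` for every contrast.
#' @param params default [extraction_params()].
#' @param annotation_version version stamp; defaults to the dataset's
#'   mapping version.
#' @return list of `gene_set` objects, with an attached `report` attribute
#'   (tibble: one row per dataset/contrast/suffix with the emitted-or-not
#'   outcome, sizes and thresholds).
#' @export
extract_gene_sets <- function(gd, contrast = NULL, params = extraction_params(),
                              annotation_version = gd$mapping_version) {
  stopifnot(inherits(gd, "gene_dataset"), inherits(params, "extraction_params"))
  contrasts <- contrast %||% gd$contrast_names
  bad <- setdiff(contrasts, gd$contrast_names)
  if (length(bad)) gsf_abort("unknown_contrast", sprintf("unknown contrast '%s'", bad[1L]))

  sets <- list()
  report <- list()
  for (cn in contrasts) {
    p_here <- merge_params(params, gd$extraction_overrides[[cn]])
    skipped <- p_here$skip || cn %in% gd$skip_gene_sets ||
      identical(gd$skip_gene_sets, "all")
    tb <- contrast_table(gd, cn)
    if (skipped) {
      report[[length(report) + 1L]] <- tibble::tibble(
        dataset = gd$dataset_name, contrast = cn, suffix = "-", emitted = FALSE,
        size = 0L, reason = "skipped")
      next
    }

    fixed <- !is.null(p_here$fixed_size)
    if (!fixed && !"P" %in% names(tb)) {
      gsf_abort("no_statistic_column",
        sprintf("contrast '%s' has no P column to threshold on (set fixed_size to extract by rank)", cn))
    }
    if (!is.null(p_here$a_threshold) && !"A" %in% names(tb)) {
      gsf_abort("no_statistic_column",
        sprintf("contrast '%s' has no A column to threshold on", cn))
    }

    keep <- tb$M != 0
    if (!fixed) keep <- keep & !is.na(tb$P) & tb$P <= p_here$p_threshold
    if (p_here$m_threshold > 0) keep <- keep & abs(tb$M) >= p_here$m_threshold
    if (!is.null(p_here$a_threshold)) {
      keep <- keep & !is.na(tb$A) & tb$A >= p_here$a_threshold
    }
    cand <- tb[keep, , drop = FALSE]
    cand <- cand[significance_order(cand), , drop = FALSE]

    members_of <- list(
      UP = cand[cand$M > 0, , drop = FALSE],
      DN = cand[cand$M < 0, , drop = FALSE]
    )
    cap <- if (fixed) p_here$fixed_size else p_here$max_size
    members_of$UP <- utils::head(members_of$UP, cap)
    members_of$DN <- utils::head(members_of$DN, cap)
    # AR = union of the UP/DN candidate pools, kept in global significance
    # order, under AR's own size cap
    members_of$AR <- utils::head(cand, cap)

    for (suffix in c("UP", "DN", "AR")) {
      m <- members_of[[suffix]]
      nm <- gene_set_name(gd$dataset_name, cn, suffix)
      if (nrow(m) < p_here$min_size) {
        report[[length(report) + 1L]] <- tibble::tibble(
          dataset = gd$dataset_name, contrast = cn, suffix = suffix,
          emitted = FALSE, size = nrow(m),
          reason = sprintf("below min_size %d", p_here$min_size))
        next
      }
      members <- tibble::tibble(rank = seq_len(nrow(m)), gene_id = m$gene_id,
                                symbol = m$symbol)
      sets[[nm]] <- new_gene_set(
        name = nm, suffix = suffix, members = members,
        description = sprintf("%s genes of contrast %s in %s", suffix, cn,
                              gd$dataset_name),
        contrast_ref = list(dataset = gd$dataset_name, contrast = cn),
        params_used = p_here, annotation_version = annotation_version,
        organism = gd$organism)
      report[[length(report) + 1L]] <- tibble::tibble(
        dataset = gd$dataset_name, contrast = cn, suffix = suffix,
        emitted = TRUE, size = nrow(m), reason = "")
    }
  }
  attr(sets, "report") <- dplyr::bind_rows(report)
  sets
}

#' Convert an imported ID list to an external gene set
#'
#' Maps each ID of an [read_idlist()] list through the mapping table
#' (official symbols before synonyms; a multi-mapping ID is resolved to its
#' best gene by RefSeq status via [select_best_gene()]), de-duplicates
#' genes keeping first occurrence, and returns a suffix-free external gene
#' set whose description comes from the list header. Unmapped IDs are
#' reported in the `unmapped` attribute.
#'
#' @param idlist an `id_list`.
#' @param table a [mapping_table()].
#' @param name set name; defaults to the description with non-word
#'   characters collapsed to `_`.
#' @return a `gene_set` with attribute `unmapped` (character).
#' @export
idlist_to_gene_set <- function(idlist, table, name = NULL) {
  stopifnot(inherits(idlist, "id_list"), inherits(table, "mapping_table"))
  name <- name %||% gsub("_+", "_", gsub("[^[:alnum:]]", "_", trimws(idlist$gene_set_desc)))
  hits <- lapply(idlist$ids, resolve_source_id, table = table,
                 id_type = idlist$id_type)
  unmapped <- idlist$ids[vapply(hits, nrow, 0L) == 0L]
  best <- dplyr::bind_rows(lapply(hits[vapply(hits, nrow, 0L) > 0L], select_best_gene))
  if (is.null(best) || nrow(best) == 0L) {
    gsf_abort("empty_after_mapping", "no ID of the list could be mapped to a gene")
  }
  best <- best[!duplicated(best$gene_id), , drop = FALSE]
  members <- tibble::tibble(rank = seq_len(nrow(best)), gene_id = best$gene_id,
                            symbol = best$official_symbol)
  out <- new_gene_set(name = name, suffix = NA_character_, members = members,
                      description = idlist$gene_set_desc,
                      annotation_version = table$version,
                      organism = idlist$organism)
  attr(out, "unmapped") <- unmapped
  out
}

#' @export
as_tibble.gene_set <- function(x, ...) {
  dplyr::mutate(x$members, set_name = x$name, .before = 1L)
}
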