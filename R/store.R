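#' On-disk contrast and gene-set knowledge base
#'
#' The store is a versioned directory holding, for every submitted dataset,
#' the raw idMAPS source, the mapped/collapsed gene-level data, the
#' processing reports and the extracted gene sets, plus externally imported
#' ID-list gene sets. Every record produced by one submission is stamped
#' with the mapping-table version (`annotation_version`), and reprocessing
#' supersedes old gene sets instead of deleting them so provenance chains
#' stay auditable.
#'
#' Layout: `gsforge-store.json` (index), `source/` (raw idMAPS),
#' `processed/` (gene-level TSV), `reports/` (JSON reports), `sets/`
#' (one JSON per gene-set record).
#'
#' @param path store directory.
#' @param overwrite replace an existing store at `path`.
#' @return a `gsf_store` handle.
#' @export
store_create <- function(path, overwrite = FALSE) {
  if (file.exists(store_index_path(path))) {
    if (!overwrite) gsf_abort("store_exists", sprintf("store already exists at %s", path))
    unlink(path, recursive = TRUE)
  }
  for (d in file.path(path, c("source", "processed", "reports", "sets"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  idx <- list(created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              next_set_id = 1L, datasets = list(), gene_sets = list())
  write_index(path, idx)
  store_open(path)
}

#' @rdname store_create
#' @export
store_open <- function(path) {
  if (!file.exists(store_index_path(path))) {
    gsf_abort("store_missing", sprintf("no store found at %s", path))
  }
  structure(list(path = path), class = "gsf_store")
}

store_index_path <- function(path) file.path(path, "gsforge-store.json")

read_index <- function(path) {
  jsonlite::read_json(store_index_path(path), simplifyVector = FALSE)
}

write_index <- function(path, idx) {
  jsonlite::write_json(idx, store_index_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

#' @export
print.gsf_store <- function(x, ...) {
  idx <- read_index(x$path)
  n_live <- sum(!vapply(idx$gene_sets, function(s) isTRUE(s$superseded), NA))
  cat(sprintf("<gsf_store> %s: %d dataset(s), %d gene set(s) (%d live)\n",
              x$path, length(idx$datasets), length(idx$gene_sets), n_live))
  invisible(x)
}

params_to_list <- function(p) {
  list(p_threshold = p$p_threshold, m_threshold = p$m_threshold,
       a_threshold = p$a_threshold, min_size = p$min_size,
       max_size = p$max_size, fixed_size = p$fixed_size, skip = p$skip)
}

params_from_list <- function(l) {
  do.call(extraction_params, l[!vapply(l, is.null, NA)])
}

#' Submit a contrast dataset to the store
#'
#' Runs the full ingestion pipeline — parse and validate the idMAPS input,
#' map and collapse to gene space, extract UP/DN/AR gene sets per contrast
#' — and persists the raw source, the processed gene-level data, the
#' mapping and extraction reports and the gene sets, all stamped with the
#' mapping table's version.
#'
#' @param store a `gsf_store`.
#' @param x idMAPS file path, idMAPS lines, or a `contrast_dataset`.
#' @param table a [mapping_table()].
#' @param strategy collapsing strategy for [map_and_collapse()].
#' @param params default [extraction_params()] (per-contrast header
#'   overrides still apply).
#' @param metadata free-text metadata; reserved keys `organism`,
#'   `tissue`, `stimulus` are used by selection filters.
#' @return invisibly, the dataset index record.
#' @export
submit_dataset <- function(store, x, table, strategy = "auto",
                           params = extraction_params(), metadata = list()) {
  stopifnot(inherits(store, "gsf_store"))
  ds <- if (inherits(x, "contrast_dataset")) x else parse_idmaps(read_text_lines(x))
  idx <- read_index(store$path)
  name <- ds$header$dataset_name
  if (name %in% vapply(idx$datasets, `[[`, "", "name")) {
    gsf_abort("duplicate_dataset_name",
      sprintf("dataset '%s' already exists in the store", name))
  }

  mc <- map_and_collapse(ds, table, strategy = strategy)
  sets <- extract_gene_sets(mc$dataset, params = params)

  writeLines(write_idmaps(ds), file.path(store$path, "source", paste0(name, ".idmaps")),
             useBytes = TRUE)
  write_processed_tsv(mc$dataset, file.path(store$path, "processed", paste0(name, ".tsv")))
  jsonlite::write_json(
    list(mapping = unclass(mc$report),
         extraction = attr(sets, "report")),
    file.path(store$path, "reports", paste0(name, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  organism <- metadata$organism %||% ds$header$organism
  rec <- list(name = name, kind = "dataset",
              description = ds$header$dataset_description,
              organism = organism, metadata = metadata,
              contrast_names = as.list(ds$header$contrast_names),
              source_id_type = ds$header$source_id_type,
              strategy = mc$report$strategy,
              params = params_to_list(params),
              annotation_version = table$version, created_at = created)
  idx$datasets[[length(idx$datasets) + 1L]] <- rec
  idx <- persist_gene_sets(store, idx, sets, dataset = name, organism = organism,
                           created = created)
  write_index(store$path, idx)
  invisible(rec)
}

persist_gene_sets <- function(store, idx, sets, dataset, organism, created) {
  for (s in sets) {
    uid <- sprintf("set%06d", idx$next_set_id)
    idx$next_set_id <- idx$next_set_id + 1L
    jsonlite::write_json(list(
      name = s$name, suffix = s$suffix, description = s$description,
      dataset = dataset, contrast = s$contrast_ref$contrast,
      organism = organism, annotation_version = s$annotation_version,
      created_at = created,
      members = s$members,
      params_used = if (!is.null(s$params_used)) params_to_list(s$params_used)
    ), file.path(store$path, "sets", paste0(uid, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    idx$gene_sets[[length(idx$gene_sets) + 1L]] <- list(
      uid = uid, name = s$name,
      suffix = if (is.na(s$suffix)) NULL else s$suffix,
      kind = if (is.na(s$suffix)) "id_list" else "contrast",
      dataset = dataset, contrast = s$contrast_ref$contrast,
      organism = organism, n_members = nrow(s$members),
      annotation_version = s$annotation_version, created_at = created,
      superseded = FALSE)
  }
  idx
}

#' Submit an ID list as an external gene set
#'
#' @param store a `gsf_store`.
#' @param x ID-list file path, its lines, or an `id_list`.
#' @inheritParams submit_dataset
#' @return invisibly, the `gene_set` (with `unmapped` attribute).
#' @export
submit_gene_set <- function(store, x, table, metadata = list()) {
  stopifnot(inherits(store, "gsf_store"))
  il <- if (inherits(x, "id_list")) x else parse_idlist(read_text_lines(x))
  set <- idlist_to_gene_set(il, table)
  idx <- read_index(store$path)
  if (set$name %in% vapply(idx$gene_sets, `[[`, "", "name")) {
    gsf_abort("duplicate_dataset_name",
      sprintf("gene set '%s' already exists in the store", set$name))
  }
  created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  idx <- persist_gene_sets(store, idx, stats::setNames(list(set), set$name),
                           dataset = NA_character_, organism = il$organism,
                           created = created)
  write_index(store$path, idx)
  invisible(set)
}

write_processed_tsv <- function(gd, path) {
  cols <- list(gene_id = gd$gene_ids, symbol = gd$symbols)
  for (cn in gd$contrast_names) {
    tb <- gd$contrasts[[cn]]
    for (letter in names(tb)) cols[[paste0(cn, "|", letter)]] <- num_to_chr(tb[[letter]])
  }
  lines <- c(
    paste0("#%mapping_version=", gd$mapping_version),
    paste(names(cols), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t"))
  )
  writeLines(lines, path, useBytes = TRUE)
}

#' Load a processed gene-level dataset back from the store
#'
#' @param store a `gsf_store`.
#' @param name dataset name.
#' @return a `gene_dataset`.
#' @export
store_gene_dataset <- function(store, name) {
  idx <- read_index(store$path)
  rec <- find_dataset(idx, name)
  path <- file.path(store$path, "processed", paste0(name, ".tsv"))
  if (!file.exists(path)) {
    gsf_abort("missing_source_data", sprintf("processed data for '%s' is missing", name))
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  mat <- matrix(unlist(cells, use.names = FALSE), ncol = length(header),
                byrow = TRUE, dimnames = list(NULL, header))
  contrast_names <- unlist(rec$contrast_names)
  contrasts <- list()
  for (cn in contrast_names) {
    pre <- paste0(cn, "|")
    letters_here <- sub(pre, "", header[startsWith(header, pre)], fixed = TRUE)
    contrasts[[cn]] <- tibble::as_tibble(
      stats::setNames(lapply(letters_here, function(l) {
        v <- mat[, paste0(pre, l)]
        out <- rep(NA_real_, length(v)); ok <- v != "NA"
        out[ok] <- as.numeric(v[ok]); out
      }), letters_here))
  }
  structure(list(
    dataset_name = name, dataset_description = rec$description,
    organism = rec$organism, contrast_names = contrast_names,
    extraction_overrides = list(), skip_gene_sets = character(0),
    gene_ids = as.integer(mat[, "gene_id"]), symbols = mat[, "symbol"],
    contrasts = contrasts, mapping_version = rec$annotation_version,
    strategy = rec$strategy
  ), class = "gene_dataset")
}

find_dataset <- function(idx, name) {
  for (rec in idx$datasets) if (identical(rec$name, name)) return(rec)
  gsf_abort("unknown_dataset", sprintf("no dataset '%s' in the store", name))
}

#' List and select store contents
#'
#' `store_datasets()` lists dataset records. `store_gene_sets()` loads the
#' gene sets matching the filters (live sets only unless
#' `include_superseded`), sorted by name for deterministic exports.
#'
#' @param store a `gsf_store`.
#' @param organism,dataset exact-match filters (`NULL` = no filter).
#' @param name glob filter on set names (`*`, `?`).
#' @param include_superseded include records superseded by a reprocessing run.
#' @return `store_datasets()`: a tibble; `store_gene_sets()`: named list of
#'   `gene_set` objects.
#' @export
store_datasets <- function(store) {
  idx <- read_index(store$path)
  purrr::map_dfr(idx$datasets, function(r) tibble::tibble(
    name = r$name, description = r$description, organism = r$organism,
    n_contrasts = length(r$contrast_names), strategy = r$strategy,
    annotation_version = r$annotation_version, created_at = r$created_at))
}

#' @rdname store_datasets
#' @export
store_gene_sets <- function(store, organism = NULL, name = NULL,
                            dataset = NULL, include_superseded = FALSE) {
  idx <- read_index(store$path)
  keep <- purrr::keep(idx$gene_sets, function(r) {
    (include_superseded || !isTRUE(r$superseded)) &&
      (is.null(organism) || identical(r$organism, organism)) &&
      (is.null(dataset) || identical(r$dataset, dataset)) &&
      (is.null(name) || grepl(glob_to_regex(name), r$name))
  })
  if (length(keep) == 0L) gsf_abort("empty_selection", "no gene sets match the selection")
  keep <- keep[order(vapply(keep, `[[`, "", "name"))]
  sets <- lapply(keep, function(r) load_gene_set(store, r$uid))
  stats::setNames(sets, vapply(keep, `[[`, "", "name"))
}

load_gene_set <- function(store, uid) {
  j <- jsonlite::read_json(file.path(store$path, "sets", paste0(uid, ".json")),
                           simplifyVector = TRUE)
  new_gene_set(
    name = j$name, suffix = j$suffix %||% NA_character_,
    members = tibble::as_tibble(j$members),
    description = j$description %||% "",
    contrast_ref = if (!is.null(j$contrast)) list(dataset = j$dataset, contrast = j$contrast),
    params_used = if (!is.null(j$params_used)) params_from_list(j$params_used),
    annotation_version = j$annotation_version %||% "",
    organism = j$organism %||% "")
}

#' Export store gene sets as GMT
#'
#' @inheritParams store_gene_sets
#' @param path optional output path.
#' @return GMT lines (see [write_gmt()]).
#' @export
store_export_gmt <- function(store, path = NULL, organism = NULL, name = NULL,
                             dataset = NULL, include_superseded = FALSE) {
  sets <- store_gene_sets(store, organism = organism, name = name,
                          dataset = dataset,
                          include_superseded = include_superseded)
  write_gmt(sets, path)
}

#' Delete a dataset and everything derived from it
#'
#' Removes the dataset record, its stored source/processed/report files and
#' all gene sets extracted from it (cascade — the store never keeps orphan
#' gene sets).
#'
#' @param store a `gsf_store`.
#' @param name dataset name.
#' @return invisibly, the number of gene-set records removed.
#' @export
delete_dataset <- function(store, name) {
  idx <- read_index(store$path)
  find_dataset(idx, name)  # errors if absent
  idx$datasets <- purrr::discard(idx$datasets, function(r) identical(r$name, name))
  drop <- vapply(idx$gene_sets, function(r) identical(r$dataset, name), NA)
  for (r in idx$gene_sets[drop]) {
    unlink(file.path(store$path, "sets", paste0(r$uid, ".json")))
  }
  idx$gene_sets <- idx$gene_sets[!drop]
  for (d in c("source", "processed")) {
    unlink(file.path(store$path, d, paste0(name, c(".idmaps", ".tsv")[match(d, c("source", "processed"))])))
  }
  unlink(file.path(store$path, "reports", paste0(name, ".json")))
  write_index(store$path, idx)
  invisible(sum(drop))
}

#' Reprocess every stored dataset with a new mapping table
#'
#' Re-runs the full pipeline (map/collapse + gene-set extraction) for every
#' dataset from its stored raw idMAPS source against `new_table`. All newly
#' produced records carry the new table's version tag; the previous gene
#' sets are marked superseded, never destroyed. Each dataset keeps its
#' originally chosen collapsing strategy and extraction parameters.
#'
#' @param store a `gsf_store`.
#' @param new_table a [mapping_table()].
#' @return tibble: one row per dataset with old/new version and set counts.
#' @export
reprocess_all <- function(store, new_table) {
  stopifnot(inherits(store, "gsf_store"), inherits(new_table, "mapping_table"))
  idx <- read_index(store$path)
  out <- list()
  for (di in seq_along(idx$datasets)) {
    rec <- idx$datasets[[di]]
    src <- file.path(store$path, "source", paste0(rec$name, ".idmaps"))
    if (!file.exists(src)) {
      gsf_abort("missing_source_data",
        sprintf("raw idMAPS source for '%s' is missing", rec$name))
    }
    ds <- read_idmaps(src)
    mc <- map_and_collapse(ds, new_table, strategy = rec$strategy)
    sets <- extract_gene_sets(mc$dataset, params = params_from_list(rec$params))

    write_processed_tsv(mc$dataset,
                        file.path(store$path, "processed", paste0(rec$name, ".tsv")))
    jsonlite::write_json(
      list(mapping = unclass(mc$report), extraction = attr(sets, "report")),
      file.path(store$path, "reports", paste0(rec$name, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

    n_old <- 0L
    for (si in seq_along(idx$gene_sets)) {
      r <- idx$gene_sets[[si]]
      if (identical(r$dataset, rec$name) && !isTRUE(r$superseded)) {
        idx$gene_sets[[si]]$superseded <- TRUE
        n_old <- n_old + 1L
      }
    }
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    idx <- persist_gene_sets(store, idx, sets, dataset = rec$name,
                             organism = rec$organism, created = created)
    out[[di]] <- tibble::tibble(
      dataset = rec$name, version_old = rec$annotation_version,
      version_new = new_table$version, n_sets_superseded = n_old,
      n_sets_new = length(sets))
    idx$datasets[[di]]$annotation_version <- new_table$version
  }
  write_index(store$path, idx)
  dplyr::bind_rows(out)
}
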