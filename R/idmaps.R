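#' idMAPS contrast-data files
#'
#' idMAPS is a tab-delimited interchange format for the results of a
#' differential statistical analysis (one file per analysis, one column
#' group per contrast). A metadata header of `#%key=value` lines precedes a
#' single column-header row; data columns then repeat, per contrast, a group
#' of statistic columns drawn from the letters
#' \describe{
#'   \item{M}{estimated effect of interest (e.g. log2 fold change) — required}
#'   \item{A}{average signal — optional}
#'   \item{P}{significance level (p-value or FDR), in \[0, 1\] — optional}
#'   \item{S}{statistic (e.g. moderated t) — optional}
#' }
#' Groups may use any internal order (`MAPS`, `SAPM`, ...) as long as every
#' contrast uses the same order. Columns whose header is not one of the four
#' letters are pass-through: preserved verbatim and ignored by all statistics.
#'
#' Recognised header keys: `dataset_name` (required), `dataset_description`,
#' `contrast_names` (required, comma-separated, one per column group),
#' `source_id_type` (required; `probe_set`, `gene_symbol` or `entrez`),
#' `organism`, `skip_gene_sets` (comma-separated contrast names, or `all`),
#' and per-contrast gene-set extraction overrides of the form
#' `gene_set.<contrast>.<param>=<value>` where `<param>` is one of
#' `p_threshold`, `m_threshold`, `a_threshold`, `min_size`, `max_size`,
#' `fixed_size`, `skip`.
#'
#' Missing values (`NA` or an empty cell) are allowed in A/P/S, never in M.
#' Duplicate source IDs are legal at parse time (microarrays repeat probes);
#' they are resolved during ID mapping/collapsing.
#'
#' @param file path to an idMAPS file, or a character vector of its lines.
#' @param text character scalar or vector holding idMAPS content.
#' @return A `contrast_dataset`: a list with `header` (metadata), `source_ids`,
#'   `contrasts` (named list of tibbles, one per contrast, columns among
#'   M/A/P/S), `extra` (pass-through columns, verbatim) and `layout`
#'   (original column order, used for faithful re-serialisation).
#' @examples
#' tab <- make_mapping_table(n_genes = 20, seed = 1)
#' ds <- make_contrast_dataset(tab, n_contrasts = 2, n_significant = 5, seed = 1)
#' lines <- write_idmaps(ds)
#' identical(parse_idmaps(lines), ds)
#' @seealso [write_idmaps()], [read_idlist()], [map_and_collapse()]
#' @export
read_idmaps <- function(file) {
  parse_idmaps(readLines(file, warn = FALSE, encoding = "UTF-8"))
}

#' @rdname read_idmaps
#' @export
parse_idmaps <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text
  n <- length(lines)
  is_meta <- grepl("^#%", lines)
  is_comment <- grepl("^#", lines) & !is_meta
  body_start <- which(!is_meta & !is_comment & nzchar(trimws(lines)))
  if (length(body_start) == 0L) {
    gsf_abort("malformed_header", "no column-header row found")
  }
  col_line <- body_start[1L]
  if (any(is_meta[col_line:n])) {
    bad <- col_line - 1L + which(is_meta[col_line:n])[1L]
    gsf_abort("malformed_header",
      sprintf("line %d: header line after the column-header row", bad))
  }

  header <- parse_idmaps_header(lines[is_meta], which(is_meta))

  tokens <- strsplit(lines[col_line], "\t", fixed = TRUE)[[1L]]
  if (length(tokens) < 2L) {
    gsf_abort("malformed_header",
      sprintf("line %d: column-header row needs an ID column plus data columns", col_line))
  }
  id_col <- tokens[1L]
  data_tokens <- tokens[-1L]
  is_maps <- data_tokens %in% c("M", "A", "P", "S")
  extra_names <- data_tokens[!is_maps]
  if (anyDuplicated(extra_names)) {
    gsf_abort("malformed_header",
      sprintf("line %d: duplicated pass-through column name '%s'",
              col_line, extra_names[duplicated(extra_names)][1L]))
  }

  groups <- split_maps_groups(data_tokens[is_maps], col_line)
  n_contrasts <- length(header$contrast_names)
  if (length(groups) != n_contrasts) {
    gsf_abort("malformed_header",
      sprintf("line %d: header declares %d contrast(s) but the column row holds %d statistic group(s)",
              col_line, n_contrasts, length(groups)))
  }
  group <- groups[[1L]]

  body <- lines[seq_len(n) > col_line]
  body_line_nos <- (col_line + 1L):n
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_line_nos <- body_line_nos[keep]
  if (length(body) == 0L) {
    gsf_abort("malformed_header", "file has no data rows")
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  width <- length(tokens)
  lens <- lengths(cells)
  # strsplit drops a trailing empty cell; restore it only when the line
  # really ends in a tab, so genuinely short rows still fail
  short <- lens == width - 1L & grepl("\t$", body)
  cells[short] <- lapply(cells[short], function(x) c(x, ""))
  lens[short] <- width
  if (any(lens != width)) {
    i <- which(lens != width)[1L]
    gsf_abort("row_length_mismatch",
      sprintf("line %d: %d fields, expected %d", body_line_nos[i], lens[i], width))
  }
  mat <- matrix(unlist(cells, use.names = FALSE), nrow = length(cells), byrow = TRUE)

  source_ids <- trimws(mat[, 1L])
  if (any(!nzchar(source_ids))) {
    i <- which(!nzchar(source_ids))[1L]
    gsf_abort("malformed_value", sprintf("line %d: empty source ID", body_line_nos[i]))
  }

  maps_cols <- which(c(FALSE, is_maps))   # column indices in mat
  extra_cols <- which(c(FALSE, !is_maps))
  contrasts <- vector("list", n_contrasts)
  names(contrasts) <- header$contrast_names
  pos <- 1L
  for (ci in seq_len(n_contrasts)) {
    cols <- list()
    for (letter in group) {
      raw <- mat[, maps_cols[pos]]
      vals <- parse_numeric_cells(raw, body_line_nos,
                                  sprintf("%s (contrast '%s')", letter, header$contrast_names[ci]),
                                  allow_na = letter != "M")
      if (letter == "P") {
        bad <- !is.na(vals) & (vals < 0 | vals > 1)
        if (any(bad)) {
          i <- which(bad)[1L]
          gsf_abort("bad_p_value",
            sprintf("line %d: P value %s outside [0, 1] in contrast '%s'",
                    body_line_nos[i], format(vals[i]), header$contrast_names[ci]))
        }
      }
      cols[[letter]] <- vals
      pos <- pos + 1L
    }
    contrasts[[ci]] <- tibble::as_tibble(cols)
  }

  extra <- if (length(extra_cols) == 0L) {
    tibble::tibble(.rows = nrow(mat))
  } else {
    tibble::as_tibble(
      stats::setNames(lapply(extra_cols, function(j) mat[, j]), extra_names),
      .name_repair = "minimal")
  }

  x <- structure(list(
    header = header,
    source_ids = source_ids,
    contrasts = contrasts,
    extra = extra,
    layout = list(id_col = id_col, tokens = data_tokens)
  ), class = "contrast_dataset")
  validate_contrast_dataset(x)
}

parse_idmaps_header <- function(meta_lines, line_nos) {
  kv <- list()
  for (i in seq_along(meta_lines)) {
    body <- sub("^#%", "", meta_lines[i])
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1L) {
      gsf_abort("malformed_header",
        sprintf("line %d: header line lacks '=': %s", line_nos[i], meta_lines[i]))
    }
    key <- trimws(substr(body, 1L, eq - 1L))
    val <- substr(body, eq + 1L, nchar(body))
    if (!nzchar(key)) {
      gsf_abort("malformed_header", sprintf("line %d: empty header key", line_nos[i]))
    }
    if (key %in% names(kv) && !startsWith(key, "gene_set.")) {
      gsf_abort("malformed_header", sprintf("line %d: duplicate header key '%s'", line_nos[i], key))
    }
    kv[[key]] <- val
  }
  need <- c("dataset_name", "contrast_names", "source_id_type")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    gsf_abort("malformed_header",
      sprintf("missing required header key(s): %s", paste(miss, collapse = ", ")))
  }
  dataset_name <- trimws(kv$dataset_name)
  if (!nzchar(dataset_name)) gsf_abort("malformed_header", "dataset_name is empty")
  contrast_names <- trimws(strsplit(kv$contrast_names, ",", fixed = TRUE)[[1L]])
  contrast_names <- contrast_names[nzchar(contrast_names)]
  if (length(contrast_names) == 0L) gsf_abort("malformed_header", "contrast_names is empty")
  if (anyDuplicated(contrast_names)) {
    gsf_abort("duplicate_contrast_name",
      sprintf("duplicate contrast name '%s'", contrast_names[duplicated(contrast_names)][1L]))
  }
  if (any(grepl("|", contrast_names, fixed = TRUE))) {
    gsf_abort("malformed_header", "contrast names may not contain '|'")
  }

  skip <- character(0)
  if (!is.null(kv$skip_gene_sets)) {
    skip <- trimws(strsplit(kv$skip_gene_sets, ",", fixed = TRUE)[[1L]])
    skip <- skip[nzchar(skip)]
    if (!identical(skip, "all")) {
      bad <- setdiff(skip, contrast_names)
      if (length(bad)) {
        gsf_abort("malformed_header",
          sprintf("skip_gene_sets names undeclared contrast '%s'", bad[1L]))
      }
    }
  }

  overrides <- list()
  ov_keys <- grep("^gene_set\\.", names(kv), value = TRUE)
  for (key in ov_keys) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      gsf_abort("malformed_header", sprintf("malformed override key '%s'", key))
    }
    contrast <- parts[2L]
    param <- parts[3L]
    if (!contrast %in% contrast_names) {
      gsf_abort("malformed_header",
        sprintf("override key '%s' names undeclared contrast '%s'", key, contrast))
    }
    allowed <- c("p_threshold", "m_threshold", "a_threshold",
                 "min_size", "max_size", "fixed_size", "skip")
    if (!param %in% allowed) {
      gsf_abort("malformed_header", sprintf("unknown extraction parameter '%s'", param))
    }
    val <- trimws(kv[[key]])
    parsed <- if (param == "skip") {
      if (!tolower(val) %in% c("true", "false")) {
        gsf_abort("malformed_header", sprintf("override '%s' must be true/false", key))
      }
      tolower(val) == "true"
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) gsf_abort("malformed_header", sprintf("override '%s' is not numeric", key))
      v
    }
    overrides[[contrast]][[param]] <- parsed
  }

  list(
    dataset_name = dataset_name,
    dataset_description = kv$dataset_description %||% "",
    contrast_names = contrast_names,
    source_id_type = trimws(kv$source_id_type),
    organism = trimws(kv$organism %||% ""),
    extraction_overrides = overrides,
    skip_gene_sets = skip
  )
}

# split the M/A/P/S letter sequence into per-contrast groups: a letter that
# repeats one already seen in the current group opens the next group
split_maps_groups <- function(letters_seq, col_line) {
  if (length(letters_seq) == 0L) {
    gsf_abort("missing_m", sprintf("line %d: no M/A/P/S data columns", col_line))
  }
  groups <- list()
  cur <- character(0)
  for (l in letters_seq) {
    if (l %in% cur) {
      groups[[length(groups) + 1L]] <- cur
      cur <- character(0)
    }
    cur <- c(cur, l)
  }
  groups[[length(groups) + 1L]] <- cur
  first <- groups[[1L]]
  for (g in groups[-1L]) {
    if (!identical(g, first)) {
      gsf_abort("inconsistent_group_order",
        sprintf("line %d: statistic group '%s' differs from first group '%s' (all contrasts must use one order)",
                col_line, paste(g, collapse = ""), paste(first, collapse = "")))
    }
  }
  for (g in groups) {
    if (!"M" %in% g) {
      gsf_abort("missing_m",
        sprintf("line %d: a statistic group lacks the required M column", col_line))
    }
  }
  groups
}

#' Validate a contrast dataset
#'
#' Checks the structural invariants of a `contrast_dataset` (non-empty IDs,
#' aligned column lengths, P in \[0,1\], declared contrasts present).
#' Duplicate source IDs are legal; retrieve them with
#' [duplicated_source_ids()].
#'
#' @param x a `contrast_dataset`.
#' @return `x`, invisibly-validated (errors of class `gsf_error_*` otherwise).
#' @export
validate_contrast_dataset <- function(x) {
  stopifnot(inherits(x, "contrast_dataset"))
  h <- x$header
  if (!nzchar(h$dataset_name)) gsf_abort("malformed_header", "dataset_name is empty")
  if (length(x$source_ids) == 0L) gsf_abort("malformed_value", "no source IDs")
  if (length(x$contrasts) != length(h$contrast_names) ||
      !identical(names(x$contrasts), h$contrast_names)) {
    gsf_abort("malformed_header", "contrasts do not match declared contrast_names")
  }
  n <- length(x$source_ids)
  letters1 <- names(x$contrasts[[1L]])
  for (nm in names(x$contrasts)) {
    tb <- x$contrasts[[nm]]
    if (!identical(names(tb), letters1)) {
      gsf_abort("inconsistent_group_order",
        sprintf("contrast '%s' has columns %s, expected %s", nm,
                paste(names(tb), collapse = ""), paste(letters1, collapse = "")))
    }
    if (nrow(tb) != n) {
      gsf_abort("row_length_mismatch",
        sprintf("contrast '%s' has %d rows, expected %d", nm, nrow(tb), n))
    }
    if (!"M" %in% names(tb)) gsf_abort("missing_m", sprintf("contrast '%s' lacks M", nm))
    if (anyNA(tb$M)) gsf_abort("missing_m", sprintf("contrast '%s' has missing M values", nm))
    if ("P" %in% names(tb)) {
      p <- tb$P
      if (any(!is.na(p) & (p < 0 | p > 1))) {
        gsf_abort("bad_p_value", sprintf("contrast '%s' has P outside [0, 1]", nm))
      }
    }
  }
  if (nrow(x$extra) && nrow(x$extra) != n) {
    gsf_abort("row_length_mismatch", "pass-through columns misaligned with source IDs")
  }
  invisible(x)
}

#' @rdname validate_contrast_dataset
#' @export
duplicated_source_ids <- function(x) {
  stopifnot(inherits(x, "contrast_dataset"))
  unique(x$source_ids[duplicated(x$source_ids)])
}

#' Serialise a contrast dataset to idMAPS
#'
#' Inverse of [parse_idmaps()]: `parse_idmaps(write_idmaps(x))` reproduces
#' `x` exactly, including pass-through columns (verbatim) and the original
#' column layout. Numbers are written in shortest round-trip decimal form.
#'
#' @param x a valid `contrast_dataset`.
#' @param file optional path; when `NULL` the lines are returned.
#' @return the idMAPS lines, invisibly when written to `file`.
#' @export
write_idmaps <- function(x, file = NULL) {
  validate_contrast_dataset(x)
  h <- x$header
  meta <- c(
    paste0("#%dataset_name=", h$dataset_name),
    if (nzchar(h$dataset_description)) paste0("#%dataset_description=", h$dataset_description),
    paste0("#%contrast_names=", paste(h$contrast_names, collapse = ",")),
    paste0("#%source_id_type=", h$source_id_type),
    if (nzchar(h$organism)) paste0("#%organism=", h$organism),
    if (length(h$skip_gene_sets)) paste0("#%skip_gene_sets=", paste(h$skip_gene_sets, collapse = ","))
  )
  for (contrast in names(h$extraction_overrides)) {
    ov <- h$extraction_overrides[[contrast]]
    for (param in names(ov)) {
      val <- ov[[param]]
      val <- if (is.logical(val)) tolower(as.character(val)) else num_to_chr(val)
      meta <- c(meta, sprintf("#%%gene_set.%s.%s=%s", contrast, param, val))
    }
  }
  tokens <- x$layout$tokens
  header_row <- paste(c(x$layout$id_col, tokens), collapse = "\t")

  n <- length(x$source_ids)
  cols <- vector("list", length(tokens))
  is_maps <- tokens %in% c("M", "A", "P", "S")
  group <- names(x$contrasts[[1L]])
  gsize <- length(group)
  pos <- 0L
  for (j in seq_along(tokens)) {
    if (is_maps[j]) {
      ci <- pos %/% gsize + 1L
      letter <- tokens[j]
      cols[[j]] <- num_to_chr(x$contrasts[[ci]][[letter]])
      pos <- pos + 1L
    } else {
      cols[[j]] <- as.character(x$extra[[tokens[j]]])
    }
  }
  body <- do.call(paste, c(list(x$source_ids), cols, sep = "\t"))
  lines <- c(meta, header_row, body)
  if (is.null(file)) return(lines)
  writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

#' Construct a contrast dataset in code
#'
#' Programmatic constructor used by the synthetic-data generators and by
#' users who already hold tidy statistics. `contrasts` is a named list of
#' data frames whose columns are a subset of M/A/P/S (same columns, same
#' order, for every contrast).
#'
#' @param dataset_name,dataset_description,source_id_type,organism header fields.
#' @param source_ids character vector of source IDs.
#' @param contrasts named list of per-contrast statistic tables.
#' @param extra optional pass-through data frame (kept verbatim).
#' @param extraction_overrides per-contrast gene-set parameter overrides.
#' @param skip_gene_sets contrast names to skip (or `"all"`).
#' @return a validated `contrast_dataset`.
#' @export
contrast_dataset <- function(dataset_name, source_ids, contrasts,
                             source_id_type = "entrez",
                             dataset_description = "", organism = "",
                             extra = NULL, extraction_overrides = list(),
                             skip_gene_sets = character(0)) {
  contrasts <- lapply(contrasts, tibble::as_tibble)
  extra <- if (is.null(extra)) tibble::tibble(.rows = length(source_ids)) else tibble::as_tibble(extra)
  group <- names(contrasts[[1L]])
  tokens <- c(rep(group, length(contrasts)), names(extra))
  x <- structure(list(
    header = list(
      dataset_name = dataset_name,
      dataset_description = dataset_description,
      contrast_names = names(contrasts),
      source_id_type = source_id_type,
      organism = organism,
      extraction_overrides = extraction_overrides,
      skip_gene_sets = skip_gene_sets
    ),
    source_ids = as.character(source_ids),
    contrasts = contrasts,
    extra = extra,
    layout = list(id_col = "ID", tokens = tokens)
  ), class = "contrast_dataset")
  validate_contrast_dataset(x)
  x
}

#' @export
print.contrast_dataset <- function(x, ...) {
  h <- x$header
  cat(sprintf("<contrast_dataset> %s (%s, %s IDs)\n", h$dataset_name,
              h$source_id_type, length(x$source_ids)))
  cat(sprintf("  contrasts [%d]: %s\n", length(h$contrast_names),
              paste(h$contrast_names, collapse = ", ")))
  cat(sprintf("  columns: %s", paste(names(x$contrasts[[1L]]), collapse = "")))
  if (ncol(x$extra)) cat(sprintf(" + pass-through: %s", paste(names(x$extra), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.contrast_dataset <- function(x, ...) {
  purrr::map_dfr(names(x$contrasts), function(nm) {
    dplyr::bind_cols(
      tibble::tibble(source_id = x$source_ids, contrast = nm),
      x$contrasts[[nm]]
    )
  })
}
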