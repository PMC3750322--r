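#' ID-list files
#'
#' An ID list is the second input format next to idMAPS: the same `#%`
#' metadata header followed by a single column of source IDs, one per line
#' (no column-header row). Imported lists become external gene sets after ID
#' mapping. Required header keys: `gene_set_desc`, `id_type`, `organism`.
#'
#' IDs are whitespace-trimmed and de-duplicated keeping the first
#' occurrence; the number of dropped duplicates is raised as a warning.
#'
#' @param file path to an ID-list file, or its lines.
#' @param text character scalar or vector holding ID-list content.
#' @return an `id_list`: list with `gene_set_desc`, `id_type`, `organism`,
#'   `ids` (character) and `n_duplicates`.
#' @seealso [idlist_to_gene_set()]
#' @export
read_idlist <- function(file) {
  parse_idlist(readLines(file, warn = FALSE, encoding = "UTF-8"))
}

#' @rdname read_idlist
#' @export
parse_idlist <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text
  is_meta <- grepl("^#%", lines)
  is_comment <- grepl("^#", lines) & !is_meta
  kv <- list()
  for (ln in lines[is_meta]) {
    body <- sub("^#%", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1L) gsf_abort("malformed_header", sprintf("header line lacks '=': %s", ln))
    kv[[trimws(substr(body, 1L, eq - 1L))]] <- substr(body, eq + 1L, nchar(body))
  }
  need <- c("gene_set_desc", "id_type", "organism")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    gsf_abort("missing_header_key",
      sprintf("missing required header key(s): %s", paste(miss, collapse = ", ")))
  }
  ids <- trimws(lines[!is_meta & !is_comment])
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) gsf_abort("empty_list", "ID list contains no IDs")
  dup <- duplicated(ids)
  if (any(dup)) {
    gsf_warn("duplicate_ids",
      sprintf("%d duplicate ID(s) dropped (first occurrence kept)", sum(dup)))
  }
  structure(list(
    gene_set_desc = trimws(kv$gene_set_desc),
    id_type = trimws(kv$id_type),
    organism = trimws(kv$organism),
    ids = ids[!dup],
    n_duplicates = sum(dup)
  ), class = "id_list")
}

#' @rdname read_idlist
#' @param x an `id_list`.
#' @export
write_idlist <- function(x, file = NULL) {
  stopifnot(inherits(x, "id_list"))
  lines <- c(
    paste0("#%gene_set_desc=", x$gene_set_desc),
    paste0("#%id_type=", x$id_type),
    paste0("#%organism=", x$organism),
    x$ids
  )
  if (is.null(file)) return(lines)
  writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

#' @export
print.id_list <- function(x, ...) {
  cat(sprintf("<id_list> %s (%s, %s): %d IDs\n",
              x$gene_set_desc, x$id_type, x$organism, length(x$ids)))
  invisible(x)
}
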