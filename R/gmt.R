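#' GMT gene-set collections
#'
#' Reads and writes the standard GMT dialect: one set per line,
#' `name<TAB>description<TAB>gene<TAB>gene...`. The reader keeps the
#' description field (needed by the knowledge base); members are kept in
#' file order with duplicates dropped.
#'
#' @param file path to a `.gmt` file, or its lines.
#' @return `read_gmt()`: a named list of `gene_set` objects.
#' @export
read_gmt <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      gsf_abort("malformed_gmt",
        sprintf("line %d: GMT lines need name, description and >= 1 gene", i))
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    ints <- suppressWarnings(as.integer(genes))
    members <- tibble::tibble(
      rank = seq_along(genes),
      gene_id = if (anyNA(ints)) rep(NA_integer_, length(genes)) else ints,
      symbol = genes)
    sets[[f[1L]]] <- new_gene_set(name = f[1L], suffix = NA_character_,
                                  members = members, description = f[2L])
  }
  sets
}

# member labels used for GMT/ORA/GSEA interop: numeric gene ids when
# available, otherwise symbols
set_member_labels <- function(set) {
  if (all(!is.na(set$members$gene_id))) as.character(set$members$gene_id)
  else set$members$symbol
}

#' @rdname read_gmt
#' @param sets list of `gene_set` objects (or a single one).
#' @param path optional output path.
#' @return `write_gmt()`: the GMT lines, invisibly when written to `path`.
#' @export
write_gmt <- function(sets, path = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(sets) == 0L) gsf_abort("empty_selection", "no gene sets to export")
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, set_member_labels(s)), collapse = "\t")
  }, "")
  if (is.null(path)) return(unname(lines))
  writeLines(unname(lines), path, useBytes = TRUE)
  invisible(unname(lines))
}

#' Gene set-to-gene membership matrix
#'
#' Boolean matrix with one row per gene in the union of the selected sets
#' and one column per set; `TRUE` where the gene belongs to the set.
#' Column sums therefore equal set sizes.
#'
#' @param sets list of `gene_set` objects.
#' @return logical matrix with gene labels as row names, set names as
#'   column names; rows sorted by gene label.
#' @export
membership_matrix <- function(sets) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(sets) == 0L) gsf_abort("empty_selection", "no gene sets selected")
  labels <- lapply(sets, set_member_labels)
  genes <- sort(unique(unlist(labels, use.names = FALSE)))
  m <- vapply(labels, function(l) genes %in% l, logical(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, vapply(sets, `[[`, "", "name")))
  m
}

#' Pairwise gene-set overlap matrix
#'
#' Square matrix of shared-gene counts or percentages between every pair of
#' selected sets. In `count` mode the diagonal holds set sizes; in
#' `percent` mode overlap is `100 * |A ∩ B| / min(|A|, |B|)` by default
#' (detects subset relations; the diagonal is 100), or the Jaccard form
#' `100 * |A ∩ B| / |A ∪ B|` with `denominator = "union"`.
#'
#' @param sets list of `gene_set` objects.
#' @param mode `"count"` or `"percent"`.
#' @param denominator for percent mode: `"min"` (default) or `"union"`.
#' @return numeric matrix, set names as dimnames.
#' @export
overlap_matrix <- function(sets, mode = c("count", "percent"),
                           denominator = c("min", "union")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(sets) == 0L) gsf_abort("empty_selection", "no gene sets selected")
  labels <- lapply(sets, set_member_labels)
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = rep(list(vapply(sets, `[[`, "", "name")), 2L))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      inter <- length(intersect(labels[[i]], labels[[j]]))
      m[i, j] <- if (mode == "count") inter else {
        den <- if (denominator == "min") {
          min(length(labels[[i]]), length(labels[[j]]))
        } else {
          length(union(labels[[i]], labels[[j]]))
        }
        100 * inter / den
      }
    }
  }
  m
}
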