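test_that("a MAPS-group file parses into the declared contrasts", {
  lines <- c(
    "#%dataset_name=EstroLike",
    "#%dataset_description=three contrasts",
    "#%contrast_names=T10,T48,Interaction",
    "#%source_id_type=probe_set",
    "#%organism=human",
    paste(c("ID", rep(c("M", "A", "P", "S"), 3)), collapse = "\t"),
    paste(c("p1", rep(c("1.5", "8.2", "0.01", "4.4"), 3)), collapse = "\t"),
    paste(c("p2", rep(c("-0.5", "7.1", "0.50", "-1.1"), 3)), collapse = "\t"))
  ds <- parse_idmaps(lines)
  expect_s3_class(ds, "contrast_dataset")
  expect_equal(ds$header$contrast_names, c("T10", "T48", "Interaction"))
  expect_length(ds$contrasts, 3)
  for (tb in ds$contrasts) expect_named(tb, c("M", "A", "P", "S"))
  expect_equal(ds$contrasts$T48$M, c(1.5, -0.5))
})

test_that("M alone is a sufficient column group", {
  lines <- c("#%dataset_name=D", "#%contrast_names=C", "#%source_id_type=entrez",
             "ID\tM", "7\t1.25", "9\t-0.5")
  ds <- parse_idmaps(lines)
  expect_named(ds$contrasts$C, "M")
  expect_equal(ds$contrasts$C$M, c(1.25, -0.5))
})

test_that("parser rejects malformed files with the right error class", {
  base <- function(colrow, rows) {
    c("#%dataset_name=D", "#%contrast_names=C1,C2", "#%source_id_type=entrez",
      colrow, rows)
  }
  # group order differs between contrasts
  expect_error(
    parse_idmaps(base("ID\tM\tA\tP\tS\tM\tP\tA\tS",
                      "1\t1\t2\t0.1\t3\t1\t0.1\t2\t3")),
    class = "gsf_error_inconsistent_group_order")
  # a group without M
  expect_error(
    parse_idmaps(base("ID\tA\tP\tA\tP", "1\t2\t0.1\t2\t0.1")),
    class = "gsf_error_missing_m")
  # wrong number of cells in a row, error names the line
  err <- expect_error(
    parse_idmaps(base("ID\tM\tM", c("1\t1\t2", "2\t4"))),
    class = "gsf_error_row_length_mismatch")
  expect_match(conditionMessage(err), "line 6")
  # P out of range
  expect_error(
    parse_idmaps(base("ID\tM\tP\tM\tP", "1\t1\t1.5\t1\t0.1")),
    class = "gsf_error_bad_p_value")
  # duplicated contrast names
  expect_error(
    parse_idmaps(c("#%dataset_name=D", "#%contrast_names=C,C",
                   "#%source_id_type=entrez", "ID\tM\tM", "1\t1\t2")),
    class = "gsf_error_duplicate_contrast_name")
  # missing required header key
  expect_error(
    parse_idmaps(c("#%dataset_name=D", "ID\tM", "1\t1")),
    class = "gsf_error_malformed_header")
  # missing M value
  expect_error(
    parse_idmaps(c("#%dataset_name=D", "#%contrast_names=C",
                   "#%source_id_type=entrez", "ID\tM", "1\tNA")),
    class = "gsf_error_missing_m")
  # thousands separators are not numbers
  expect_error(
    parse_idmaps(c("#%dataset_name=D", "#%contrast_names=C",
                   "#%source_id_type=entrez", "ID\tM", "1\t1,200")),
    class = "gsf_error_malformed_value")
})

test_that("write -> parse is the identity, pass-through columns verbatim", {
  ds <- tiny_dataset()
  expect_identical(parse_idmaps(write_idmaps(ds)), ds)

  with_extra <- contrast_dataset(
    dataset_name = "D", source_ids = c("a", "b"),
    contrasts = list(C = tibble::tibble(M = c(1, -2), P = c(0.5, 1e-8))),
    source_id_type = "probe_set",
    extra = tibble::tibble(B = c("keep me", "also me")))
  rt <- parse_idmaps(write_idmaps(with_extra))
  expect_identical(rt, with_extra)
  expect_equal(rt$extra$B, c("keep me", "also me"))

  # extra columns never alter the statistics
  without <- contrast_dataset(
    dataset_name = "D", source_ids = c("a", "b"),
    contrasts = list(C = tibble::tibble(M = c(1, -2), P = c(0.5, 1e-8))),
    source_id_type = "probe_set")
  expect_identical(rt$contrasts, without$contrasts)
})

test_that("header metadata (overrides, skips) survives the round trip", {
  ds <- tiny_dataset(skip_gene_sets = "C2",
                     extraction_overrides = list(C1 = list(p_threshold = 0.01,
                                                           skip = FALSE)))
  rt <- parse_idmaps(write_idmaps(ds))
  expect_identical(rt$header$extraction_overrides$C1$p_threshold, 0.01)
  expect_identical(rt$header$skip_gene_sets, "C2")
  expect_identical(rt, ds)
})

test_that("single-point mutations of a valid file are rejected", {
  ds <- tiny_dataset()
  lines <- write_idmaps(ds)
  col_row <- grep("^ID\t", lines)
  # drop one cell from a data row
  mut1 <- lines
  mut1[col_row + 2] <- sub("\t[^\t]*$", "", mut1[col_row + 2])
  expect_error(parse_idmaps(mut1), class = "gsf_error_row_length_mismatch")
  # shuffle the second group's order
  mut2 <- lines
  mut2[col_row] <- "ID\tM\tA\tP\tS\tM\tA\tS\tP"
  expect_error(parse_idmaps(mut2), class = "gsf_error_inconsistent_group_order")
  # corrupt a P value
  mut3 <- lines
  parts <- strsplit(mut3[col_row + 1], "\t")[[1]]
  parts[4] <- "1.5"
  mut3[col_row + 1] <- paste(parts, collapse = "\t")
  expect_error(parse_idmaps(mut3), class = "gsf_error_bad_p_value")
})

test_that("duplicate source IDs are tolerated and reported", {
  ds <- contrast_dataset(
    dataset_name = "D", source_ids = c("a", "b", "a"),
    contrasts = list(C = tibble::tibble(M = c(1, 2, 3))),
    source_id_type = "probe_set")
  expect_identical(duplicated_source_ids(ds), "a")
})

test_that("ID lists parse, de-duplicate and validate their header", {
  lines <- c("#%gene_set_desc=Inflammatory Response biological process",
             "#%id_type=gene_symbol", "#%organism=human",
             "TNF", "IL6", " TNF ", "CXCL8")
  expect_warning(il <- parse_idlist(lines), class = "gsf_warning_duplicate_ids")
  expect_equal(il$ids, c("TNF", "IL6", "CXCL8"))
  expect_equal(il$n_duplicates, 1)
  rt <- parse_idlist(write_idlist(il))   # writes the de-duplicated list
  expect_identical(rt$ids, il$ids)
  expect_identical(rt[c("gene_set_desc", "id_type", "organism")],
                   il[c("gene_set_desc", "id_type", "organism")])

  expect_error(parse_idlist(c("#%gene_set_desc=x", "#%organism=human", "TNF")),
               class = "gsf_error_missing_header_key")
  expect_error(parse_idlist(c("#%gene_set_desc=x", "#%id_type=gene_symbol",
                              "#%organism=human")),
               class = "gsf_error_empty_list")
})

test_that("the shipped example files parse", {
  ex <- system.file("extdata", "example.idmaps", package = "gsforge")
  ds <- read_idmaps(ex)
  expect_equal(ds$header$contrast_names, c("Early", "Late"))
  expect_equal(ds$header$extraction_overrides$Late$p_threshold, 0.01)
  expect_equal(length(ds$source_ids), 5)
  il <- read_idlist(system.file("extdata", "example_idlist.txt", package = "gsforge"))
  expect_equal(length(il$ids), 5)
})
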