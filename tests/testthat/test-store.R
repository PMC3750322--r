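new_store <- function() store_create(file.path(tempfile("store")))

test_that("submitting a dataset persists source, processed data, reports and sets", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 60, seed = 21)
  ds <- make_contrast_dataset(tab, n_contrasts = 3, n_significant = 25, seed = 22)
  rec <- submit_dataset(st, ds, tab)
  expect_equal(rec$annotation_version, tab$version)
  expect_equal(nrow(store_datasets(st)), 1)
  sets <- store_gene_sets(st)
  expect_gt(length(sets), 0)
  expect_lte(length(sets), 9)  # up to UP/DN/AR per contrast
  # all records of the submission share the annotation version
  expect_true(all(vapply(sets, `[[`, "", "annotation_version") == tab$version))
  # raw source round-trips
  rt <- read_idmaps(file.path(st$path, "source", paste0(rec$name, ".idmaps")))
  expect_identical(rt, ds)
  # processed data reloads with the same gene-level values
  gd <- store_gene_dataset(st, rec$name)
  direct <- map_and_collapse(ds, tab)$dataset
  expect_equal(gd$gene_ids, direct$gene_ids)
  expect_equal(contrast_table(gd, "C1")$S, contrast_table(direct, "C1")$S)
})

test_that("duplicate dataset names and header-level skips are handled", {
  st <- new_store()
  tab <- tiny_table()
  submit_dataset(st, tiny_dataset(), tab,
                 params = extraction_params(min_size = 1))
  expect_error(submit_dataset(st, tiny_dataset(), tab),
               class = "gsf_error_duplicate_dataset_name")

  st2 <- new_store()
  submit_dataset(st2, tiny_dataset(name = "SKIPALL", skip_gene_sets = "all"), tab)
  expect_equal(nrow(store_datasets(st2)), 1)
  expect_error(store_gene_sets(st2), class = "gsf_error_empty_selection")
})

test_that("external gene sets can be submitted and selected", {
  st <- new_store()
  tab <- tiny_table()
  il <- parse_idlist(c("#%gene_set_desc=external example",
                       "#%id_type=gene_symbol", "#%organism=human",
                       "SHARED", "GB", "GD"))
  submit_gene_set(st, il, tab)
  sets <- store_gene_sets(st, organism = "human")
  expect_length(sets, 1)
  expect_equal(nrow(sets[[1]]$members), 3)
})

test_that("GMT export round-trips and honours selection filters", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 60, seed = 31)
  submit_dataset(st, make_contrast_dataset(tab, seed = 32, organism = "human",
                                           dataset_name = "HUM"), tab)
  submit_dataset(st, make_contrast_dataset(tab, seed = 33, organism = "mouse",
                                           dataset_name = "MUS"), tab)
  gmt_path <- tempfile(fileext = ".gmt")
  store_export_gmt(st, gmt_path)
  rt <- read_gmt(gmt_path)
  sets <- store_gene_sets(st)
  expect_equal(names(rt), names(sets))
  for (nm in names(sets)) {
    expect_equal(rt[[nm]]$members$gene_id, sets[[nm]]$members$gene_id)
    # n genes -> n + 2 tab-separated fields
    lines <- readLines(gmt_path)
    line <- lines[startsWith(lines, paste0(nm, "\t"))]
    expect_length(strsplit(line, "\t")[[1]], nrow(sets[[nm]]$members) + 2)
  }
  human_only <- store_gene_sets(st, organism = "human")
  expect_true(all(grepl("^HUM", names(human_only))))
  expect_error(store_gene_sets(st, organism = "rat"),
               class = "gsf_error_empty_selection")
})

test_that("membership and overlap matrices satisfy their structural contracts", {
  s1 <- new_gene_set_for_test("S1", 1:10)
  s2 <- new_gene_set_for_test("S2", 6:15)
  s3 <- new_gene_set_for_test("S3", 21:25)
  m <- membership_matrix(list(s1, s2, s3))
  expect_equal(unname(colSums(m)), c(10, 10, 5))
  expect_true(all(rowSums(m[as.character(21:25), , drop = FALSE]) == 1))

  ov <- overlap_matrix(list(s1, s2, s3), "count")
  expect_true(isSymmetric(ov))
  expect_equal(unname(diag(ov)), c(10, 10, 5))
  expect_equal(ov["S1", "S2"], 5)
  expect_equal(ov["S1", "S3"], 0)

  pc <- overlap_matrix(list(s1, s2, s3), "percent")
  expect_equal(unname(diag(pc)), c(100, 100, 100))
  expect_equal(pc["S1", "S2"], 100 * 5 / 10)
  # subset relation reads 100% under the min denominator
  sub <- new_gene_set_for_test("SUB", 1:5)
  expect_equal(overlap_matrix(list(s1, sub), "percent")["S1", "SUB"], 100)
  expect_equal(overlap_matrix(list(s1, sub), "percent", "union")["S1", "SUB"], 50)

  # brute-force pairwise oracle on random sets
  sets <- withr::with_seed(77, lapply(1:6, function(i)
    new_gene_set_for_test(paste0("R", i), sample(1:40, sample(5:15, 1)))))
  got <- overlap_matrix(sets, "count")
  for (i in 1:6) for (j in 1:6) {
    expect_equal(got[i, j], length(intersect(sets[[i]]$members$gene_id,
                                             sets[[j]]$members$gene_id)))
  }
})

test_that("membership column sums match GMT line member counts", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 50, seed = 35)
  submit_dataset(st, make_contrast_dataset(tab, seed = 36), tab)
  sets <- store_gene_sets(st)
  m <- membership_matrix(sets)
  gmt <- write_gmt(sets)
  for (i in seq_along(gmt)) {
    fields <- strsplit(gmt[i], "\t")[[1]]
    expect_equal(unname(colSums(m)[fields[1]]), length(fields) - 2)
  }
})

test_that("deleting a dataset cascades to its gene sets", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 60, seed = 37)
  submit_dataset(st, make_contrast_dataset(tab, seed = 38, dataset_name = "A"), tab)
  submit_dataset(st, make_contrast_dataset(tab, seed = 39, dataset_name = "B"), tab)
  n_a <- length(store_gene_sets(st, dataset = "A"))
  expect_equal(delete_dataset(st, "A"), n_a)
  expect_error(store_gene_sets(st, dataset = "A"), class = "gsf_error_empty_selection")
  expect_equal(store_datasets(st)$name, "B")
  expect_error(delete_dataset(st, "A"), class = "gsf_error_unknown_dataset")
})

test_that("reprocessing with the identical table is idempotent, byte for byte", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 60, seed = 41)
  submit_dataset(st, make_contrast_dataset(tab, seed = 42), tab)
  before <- store_export_gmt(st)
  rep <- reprocess_all(st, tab)
  expect_equal(nrow(rep), 1)
  after <- store_export_gmt(st)
  expect_identical(after, before)
  # dataset count preserved; old sets retained as superseded
  expect_equal(nrow(store_datasets(st)), 1)
  all_sets <- store_gene_sets(st, include_superseded = TRUE)
  expect_equal(length(all_sets), 2 * length(store_gene_sets(st)))
})

test_that("reprocessing with a changed table propagates and supersedes", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 60, seed = 43)
  submit_dataset(st, make_contrast_dataset(tab, seed = 44), tab)
  live_before <- store_gene_sets(st)
  # drop one gene that currently appears in a set
  victim <- live_before[[1]]$members$gene_id[1]
  tab2 <- mapping_table(tab$records[tab$records$gene_id != victim, ],
                        version = "rebuild-v2")
  reprocess_all(st, tab2)
  live_after <- store_gene_sets(st)
  for (s in live_after) {
    expect_false(victim %in% s$members$gene_id)
    expect_equal(s$annotation_version, "rebuild-v2")
  }
  expect_equal(store_datasets(st)$annotation_version, "rebuild-v2")
  # superseded records keep the old version tag
  old <- store_gene_sets(st, include_superseded = TRUE)
  expect_true(any(vapply(old, `[[`, "", "annotation_version") != "rebuild-v2"))
})

test_that("reprocessing fails cleanly when raw source data is gone", {
  st <- new_store()
  tab <- make_mapping_table(n_genes = 30, seed = 45)
  rec <- submit_dataset(st, make_contrast_dataset(tab, n_significant = 10, seed = 46), tab)
  unlink(file.path(st$path, "source", paste0(rec$name, ".idmaps")))
  expect_error(reprocess_all(st, tab), class = "gsf_error_missing_source_data")
})
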