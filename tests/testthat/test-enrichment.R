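ranked_fixture <- function(seed = 50, n = 60) {
  withr::with_seed(seed, {
    structure(list(
      entries = tibble::tibble(gene_id = seq_len(n),
                               score = sort(stats::rnorm(n), decreasing = TRUE)),
      metric = "S", contrast_ref = list(dataset = "T", contrast = "C")),
      class = "ranked_list")
  })
}

test_that("ranked lists sort by the metric with deterministic ties and ignore row order", {
  tab <- make_mapping_table(n_genes = 40, seed = 51)
  ds <- make_contrast_dataset(tab, n_contrasts = 1, n_significant = 10, seed = 52)
  gd <- map_and_collapse(ds, tab)$dataset
  rl <- create_ranked_list(gd, "C1", "S")
  expect_true(all(diff(rl$entries$score) <= 0))
  expect_equal(nrow(rl$entries), length(gd$gene_ids))  # threshold-independent

  # permuting input rows changes nothing
  perm <- withr::with_seed(53, sample(length(ds$source_ids)))
  ds2 <- contrast_dataset(
    dataset_name = ds$header$dataset_name,
    source_ids = ds$source_ids[perm],
    contrasts = lapply(ds$contrasts, function(tb) tb[perm, ]),
    source_id_type = "probe_set", organism = "human")
  gd2 <- map_and_collapse(ds2, tab)$dataset
  expect_equal(create_ranked_list(gd2, "C1", "S"), rl)

  # M and S orders differ when signs disagree
  dsx <- contrast_dataset(
    dataset_name = "X", source_ids = c("1001", "1002", "1003"),
    contrasts = list(C = tibble::tibble(M = c(3, -1, 1), S = c(-0.5, 2, 1))),
    source_id_type = "entrez")
  tabx <- make_mapping_table(n_genes = 3, max_probes_per_gene = 1, seed = 54)
  gdx <- map_and_collapse(dsx, tabx, "mean")$dataset
  expect_false(identical(create_ranked_list(gdx, "C", "M")$entries$gene_id,
                         create_ranked_list(gdx, "C", "S")$entries$gene_id))
  expect_error(create_ranked_list(gdx, "C", "P"))
})

test_that("DEG lists apply the P threshold against the contrast universe", {
  tab <- make_mapping_table(n_genes = 40, max_probes_per_gene = 1, seed = 55)
  ds <- make_contrast_dataset(tab, n_contrasts = 1, n_significant = 0, seed = 56)
  gd <- map_and_collapse(ds, tab)$dataset
  deg_all <- create_deg_list(gd, "C1", p_threshold = 1)
  expect_setequal(deg_all$gene_ids, deg_all$universe)
  expect_error(create_deg_list(gd, "C1", p_threshold = 1e-300),
               class = "gsf_error_empty_deg_list")
  tb <- contrast_table(gd, "C1")
  thr <- sort(tb$P)[5]
  deg <- create_deg_list(gd, "C1", p_threshold = thr)
  expect_setequal(deg$gene_ids, tb$gene_id[tb$P <= thr])
})

test_that("enrichment score hits its closed-form extremes", {
  rl <- ranked_fixture()
  # singleton at rank 1, weight 0: running sum jumps to 1 before any miss
  top <- enrichment_score(rl, rl$entries$gene_id[1], weight = 0)
  expect_identical(top$es, 1)
  expect_identical(top$rank_at_max, 1L)
  # a set occupying exactly the top N_H ranks peaks at 1 for any weight
  for (w in c(0, 1, 2)) {
    blk <- enrichment_score(rl, rl$entries$gene_id[1:8], weight = w)
    expect_equal(blk$es, 1)
    expect_equal(blk$rank_at_max, 8L)
  }
  expect_error(enrichment_score(rl, 99999), class = "gsf_error_empty_intersection")
  expect_error(enrichment_score(rl, rl$entries$gene_id),
               class = "gsf_error_set_equals_universe")
})

test_that("enrichment score is bounded and anti-symmetric under list reversal", {
  for (seed in 1:30) {
    rl <- ranked_fixture(seed = 100 + seed, n = 50)
    members <- withr::with_seed(200 + seed, sample(rl$entries$gene_id, 8))
    es <- enrichment_score(rl, members, weight = 0)$es
    expect_gte(es, -1); expect_lte(es, 1)
    rev_rl <- structure(list(
      entries = rl$entries[rev(seq_len(nrow(rl$entries))), ],
      metric = "S", contrast_ref = rl$contrast_ref), class = "ranked_list")
    es_rev <- enrichment_score(rev_rl, members, weight = 0)$es
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("enrichment score matches the independent cumulative-walk oracle", {
  for (seed in 1:50) {
    rl <- ranked_fixture(seed = 300 + seed, n = 40 + seed %% 30)
    k <- 3 + seed %% 10
    members <- withr::with_seed(400 + seed, sample(rl$entries$gene_id, k))
    for (w in c(0, 1, 2)) {
      got <- enrichment_score(rl, members, weight = w)
      want <- oracle_es(rl$entries$score, members, rl$entries$gene_id, w)
      expect_equal(got$es, want$es, tolerance = 1e-12)
      expect_equal(got$rank_at_max, want$rank_at_max)
    }
  }
})

test_that("enrichment score agrees with fgsea's statistic on random cases", {
  for (seed in 1:10) {
    rl <- ranked_fixture(seed = 500 + seed, n = 80)
    members <- withr::with_seed(600 + seed, sample(rl$entries$gene_id, 12))
    stats_vec <- stats::setNames(rl$entries$score, rl$entries$gene_id)
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = which(rl$entries$gene_id %in% members),
                               gseaParam = 1)
    expect_equal(enrichment_score(rl, members, weight = 1)$es, ref,
                 tolerance = 1e-10)
  }
})

test_that("gsea_preranked is seed-deterministic and recovers planted signal", {
  fx <- make_ranked_fixture(n_genes = 500, set_size = 20, n_planted = 2,
                            n_null = 8, shift = 2, seed = 60)
  params <- gsea_params(seed = 61, n_permutations = 200)
  r1 <- gsea_preranked(fx$ranked, fx$collection, params)
  r2 <- gsea_preranked(fx$ranked, fx$collection, params)
  expect_identical(r1$results, r2$results)

  tb <- tidy(r1)
  expect_true(all(tb$fdr_q[tb$set_name %in% fx$planted] <= 0.05))
  expect_true(all(abs(tb$es) <= 1))
  expect_true(all(tb$p_value > 0 & tb$p_value <= 1))

  # leading edge: positive-ES members sit at ranks <= rank_at_max
  for (i in seq_len(nrow(tb))) {
    le <- tb$leading_edge[[i]]
    pos <- match(le, r1$ranked$entries$gene_id)
    if (tb$es[i] > 0) expect_true(all(pos <= tb$rank_at_max[i]))
    if (tb$es[i] < 0) expect_true(all(pos >= tb$rank_at_max[i]))
    expect_true(all(le %in% r1$ranked$entries$gene_id[r1$hits[[tb$set_name[i]]]]))
  }
})

test_that("gsea size filters apply to the list intersection", {
  fx <- make_ranked_fixture(n_genes = 200, set_size = 12, n_planted = 1,
                            n_null = 3, seed = 62)
  expect_error(
    gsea_preranked(fx$ranked, fx$collection,
                   gsea_params(seed = 1, min_size = 50, max_size = 60)),
    class = "gsf_error_no_sets_pass_size_filter")
  res <- gsea_preranked(fx$ranked, fx$collection,
                        gsea_params(seed = 1, n_permutations = 100, min_size = 10))
  expect_equal(nrow(res$results), 4)
})

test_that("gsea results serialise to JSON and back without loss", {
  fx <- make_ranked_fixture(n_genes = 200, set_size = 12, n_planted = 1,
                            n_null = 3, seed = 63)
  res <- gsea_preranked(fx$ranked, fx$collection,
                        gsea_params(seed = 2, n_permutations = 100))
  f <- tempfile(fileext = ".json")
  write_gsea_result(res, f)
  rt <- read_gsea_result(f)
  expect_equal(rt$results, res$results)
  expect_equal(rt$ranked$entries, res$ranked$entries)
  expect_equal(unname(rt$hits), unname(lapply(res$hits, as.integer)))
})

test_that("hypergeometric ORA matches enumeration and handles edge cases", {
  # planted structure: universe 1..20, DEG 1..6, set {1,2,3,16,17}
  deg <- structure(list(gene_ids = 1:6, p_threshold = 0.05, universe = 1:20,
                        contrast_ref = NULL), class = "deg_list")
  res <- ora_hypergeometric(deg, list(SET = c(1:3, 16:17)))
  expect_equal(res$results$overlap, 3)
  expect_equal(res$results$p_value, oracle_hyper_tail(20, 5, 6, 3),
               tolerance = 1e-12)

  # zero overlap -> p = 1
  res0 <- ora_hypergeometric(deg, list(S = 10:14))
  expect_equal(res0$results$p_value, 1)
  # DEG = universe -> overlap is certain, p = 1 for every set
  deg_all <- structure(list(gene_ids = 1:20, p_threshold = 1, universe = 1:20,
                            contrast_ref = NULL), class = "deg_list")
  resall <- ora_hypergeometric(deg_all, list(A = 1:4, B = 5:11))
  expect_equal(resall$results$p_value, c(1, 1))

  # collection universe policy restricts N to the union of members
  resu <- ora_hypergeometric(deg, list(A = c(1:3, 16:17), B = 4:10),
                             universe = "collection")
  expect_equal(resu$universe_size, length(union(c(1:3, 16:17), 4:10)))
  expect_equal(resu$universe_policy, "collection")
})

test_that("BH adjustment matches the textbook step-up and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  for (seed in 1:20) {
    p <- withr::with_seed(700 + seed, stats::runif(50)^2)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "gsf_error_value_out_of_range")
  expect_error(bh_adjust(c(0.1, NA)), class = "gsf_error_value_out_of_range")
  # q is monotone non-decreasing along the p-value ordering
  p <- withr::with_seed(720, stats::runif(30))
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= -1e-15))
})
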