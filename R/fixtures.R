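#' Synthetic mapping tables
#'
#' Generates a seed-deterministic mapping table for testing and
#' walkthroughs: `n_genes` genes with sequential IDs and symbols
#' `GENE0001...`, RefSeq statuses sampled over the full vocabulary, each
#' gene measured by one to `max_probes_per_gene` probe sets, and optional
#' planted name clashes where one gene's synonym equals another gene's
#' official symbol (exercising official-symbol precedence).
#'
#' @param n_genes number of genes.
#' @param max_probes_per_gene probes per gene are drawn uniformly from
#'   `1:max_probes_per_gene` (1 gives a bijective table).
#' @param n_synonym_collisions how many synonym/official-symbol clashes to
#'   plant.
#' @param version version tag of the generated table.
#' @param seed integer seed (mandatory: generators are study fixtures and
#'   must be reproducible).
#' @return a [mapping_table()].
#' @export
make_mapping_table <- function(n_genes = 100, max_probes_per_gene = 3,
                               n_synonym_collisions = 0,
                               version = sprintf("synthetic-%d", seed), seed) {
  if (missing(seed)) gsf_abort("seed_required", "make_mapping_table() needs a seed")
  stopifnot(is_count(n_genes), is_count(max_probes_per_gene))
  withr::with_seed(seed, {
    gene_id <- seq_len(n_genes) + 1000L
    symbol <- sprintf("GENE%04d", seq_len(n_genes))
    status <- sample(refseq_status_levels, n_genes, replace = TRUE)
    synonyms <- lapply(seq_len(n_genes), function(i) {
      n_syn <- sample(0:2, 1L)
      if (n_syn == 0L) character(0) else sprintf("SYN%04d_%d", i, seq_len(n_syn))
    })
    if (n_synonym_collisions > 0) {
      stopifnot(n_genes >= 2 * n_synonym_collisions)
      for (i in seq_len(n_synonym_collisions)) {
        # gene 2i's synonym list gains gene (2i-1)'s official symbol
        synonyms[[2L * i]] <- c(synonyms[[2L * i]], symbol[2L * i - 1L])
      }
    }
    n_probes <- sample.int(max_probes_per_gene, n_genes, replace = TRUE)
    records <- tibble::tibble(
      source_id = sprintf("PS%05d_at", seq_len(sum(n_probes))),
      gene_id = rep(gene_id, n_probes),
      official_symbol = rep(symbol, n_probes),
      refseq_status = rep(status, n_probes),
      synonyms = rep(synonyms, n_probes)
    )
    mapping_table(records, version = version)
  })
}

#' Synthetic contrast datasets with planted differential signal
#'
#' Emulates the output of a differential-expression analysis at the probe
#' level. Per gene and contrast the true effect is 0 except for
#' `n_significant` planted genes (alternating up/down) whose effect is
#' `+/- effect_size` (on the M scale, e.g. log2 fold change). Per probe:
#' a standard error `SE` is drawn from a scaled chi distribution (as a
#' moderated-variance analysis would estimate it; around 0.33);
#' `M` = true effect + Normal(0, SE) measurement error, so
#' `S = M / SE` is standard normal under the null; `P` is the BH-adjusted
#' two-sided normal tail of `S` — genuinely valid tail probabilities, so
#' FDR semantics downstream are meaningful; `A ~ Normal(8, 2)` (log2-scale
#' average signal). Source IDs are the probes of `table`, so the dataset
#' feeds straight into [map_and_collapse()].
#'
#' @param table a [mapping_table()] supplying probes and genes.
#' @param n_contrasts number of contrasts.
#' @param n_significant planted differential genes per contrast (the same
#'   genes in every contrast; noise is redrawn).
#' @param effect_size planted |M| shift in noise-SD units (default 2).
#' @param dataset_name,organism header fields.
#' @param seed integer seed (mandatory).
#' @return a `contrast_dataset` with columns M, A, P, S.
#' @export
make_contrast_dataset <- function(table, n_contrasts = 2, n_significant = 50,
                                  effect_size = 2,
                                  dataset_name = sprintf("SYNTH%d", seed),
                                  organism = "human", seed) {
  if (missing(seed)) gsf_abort("seed_required", "make_contrast_dataset() needs a seed")
  stopifnot(inherits(table, "mapping_table"), is_count(n_contrasts))
  withr::with_seed(seed, {
    probes <- table$records$source_id
    genes <- table$records$gene_id
    n <- length(probes)
    gene_levels <- sort(unique(genes))
    stopifnot(n_significant <= length(gene_levels))
    sig_genes <- if (n_significant > 0) gene_levels[seq_len(n_significant)] else integer(0)
    effect <- numeric(length(gene_levels))
    if (n_significant > 0) {
      half <- ceiling(n_significant / 2)
      effect[seq_len(n_significant)] <- rep(c(effect_size, -effect_size),
                                            c(half, n_significant - half))
    }
    mu <- effect[match(genes, gene_levels)]

    contrasts <- list()
    for (ci in seq_len(n_contrasts)) {
      se <- sqrt(stats::rchisq(n, df = 8) / 8) / sqrt(9)
      m <- mu + se * stats::rnorm(n)
      s <- m / se
      p <- bh_adjust(2 * stats::pnorm(-abs(s)))
      a <- stats::rnorm(n, mean = 8, sd = 2)
      contrasts[[sprintf("C%d", ci)]] <- tibble::tibble(M = m, A = a, P = p, S = s)
    }
    contrast_dataset(
      dataset_name = dataset_name, source_ids = probes, contrasts = contrasts,
      source_id_type = "probe_set", organism = organism,
      dataset_description = sprintf("synthetic contrasts, %d planted genes at |M| = %s",
                                    n_significant, format(effect_size)))
  })
}

#' Synthetic ranked lists with planted enriched sets
#'
#' Builds the calibration/power fixture for preranked enrichment: scores
#' are standard normal over `n_genes` genes; each of `n_planted` sets has
#' its members' scores shifted by `+shift` SD (a shift of 0 gives a pure
#' null fixture); `n_null` additional sets are drawn at random with no
#' shift. The list is re-sorted after shifting.
#'
#' @param n_genes universe size (default 1000).
#' @param set_size genes per set (default 25).
#' @param n_planted,n_null number of shifted and of null sets.
#' @param shift score shift of planted members, in SD units (default 2).
#' @param seed integer seed (mandatory).
#' @return list with `ranked` (a `ranked_list`), `collection` (named list
#'   of member-ID vectors) and `planted` (names of the shifted sets).
#' @export
make_ranked_fixture <- function(n_genes = 1000, set_size = 25, n_planted = 3,
                                n_null = 20, shift = 2, seed) {
  if (missing(seed)) gsf_abort("seed_required", "make_ranked_fixture() needs a seed")
  withr::with_seed(seed, {
    gene_id <- seq_len(n_genes)
    score <- stats::rnorm(n_genes)
    collection <- list()
    planted <- character(0)
    for (i in seq_len(n_planted)) {
      members <- sample(gene_id, set_size)
      score[members] <- score[members] + shift
      nm <- sprintf("PLANTED_%02d", i)
      collection[[nm]] <- members
      planted <- c(planted, nm)
    }
    for (i in seq_len(n_null)) {
      collection[[sprintf("NULL_%02d", i)]] <- sample(gene_id, set_size)
    }
    ord <- order(-score, gene_id)
    ranked <- structure(list(
      entries = tibble::tibble(gene_id = gene_id[ord], score = score[ord]),
      metric = "S",
      contrast_ref = list(dataset = sprintf("RANKFIX%d", seed), contrast = "C1")
    ), class = "ranked_list")
    list(ranked = ranked, collection = collection, planted = planted)
  })
}
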