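#' Build a ranked gene list from a contrast
#'
#' Orders all genes of a contrast by the chosen rank metric — the statistic
#' S (e.g. moderated t) or the effect M (e.g. log2 fold change) — for
#' preranked gene set enrichment analysis. The whole contrast enters the
#' list (no significance filtering: GSEA is threshold-independent). Ties
#' are broken by ascending gene ID so the order, and hence the
#' tie-sensitive enrichment score, is deterministic.
#'
#' @param gd a `gene_dataset` (see [map_and_collapse()]).
#' @param contrast contrast name.
#' @param metric `"S"` or `"M"`.
#' @return a `ranked_list`: `entries` tibble (`gene_id`, `score`, sorted by
#'   descending score), `metric`, `contrast_ref`.
#' @export
create_ranked_list <- function(gd, contrast, metric = c("S", "M")) {
  metric <- match.arg(metric)
  tb <- contrast_table(gd, contrast)
  if (!metric %in% names(tb)) {
    gsf_abort("missing_column",
      sprintf("contrast '%s' has no %s column to rank on", contrast, metric))
  }
  score <- tb[[metric]]
  if (anyNA(score)) {
    gsf_abort("missing_column",
      sprintf("rank metric %s has missing values in contrast '%s'", metric, contrast))
  }
  ord <- order(-score, tb$gene_id)
  structure(list(
    entries = tibble::tibble(gene_id = tb$gene_id[ord], score = score[ord]),
    metric = metric,
    contrast_ref = list(dataset = gd$dataset_name, contrast = contrast)
  ), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d genes by %s (%s / %s)\n", nrow(x$entries),
              x$metric, x$contrast_ref$dataset %||% "-", x$contrast_ref$contrast %||% "-"))
  invisible(x)
}

#' Build a differentially-expressed-gene (DEG) list from a contrast
#'
#' Genes with `P <= p_threshold`; the universe is every gene of the
#' contrast (the measured background the over-representation test
#' conditions on).
#'
#' @inheritParams create_ranked_list
#' @param p_threshold significance cutoff on P.
#' @return a `deg_list`: `gene_ids`, `p_threshold`, `universe`.
#' @export
create_deg_list <- function(gd, contrast, p_threshold = 0.05) {
  tb <- contrast_table(gd, contrast)
  if (!"P" %in% names(tb)) {
    gsf_abort("missing_column", sprintf("contrast '%s' has no P column", contrast))
  }
  hit <- !is.na(tb$P) & tb$P <= p_threshold
  if (!any(hit)) {
    gsf_abort("empty_deg_list",
      sprintf("no gene reaches P <= %s in contrast '%s'", format(p_threshold), contrast))
  }
  structure(list(gene_ids = tb$gene_id[hit], p_threshold = p_threshold,
                 universe = tb$gene_id,
                 contrast_ref = list(dataset = gd$dataset_name, contrast = contrast)),
            class = "deg_list")
}

#' @export
print.deg_list <- function(x, ...) {
  cat(sprintf("<deg_list> %d / %d genes at P <= %s\n", length(x$gene_ids),
              length(x$universe), format(x$p_threshold)))
  invisible(x)
}

# core weighted Kolmogorov-Smirnov running statistic. hits are positions in
# the ranked list; increments |r|^p / sum(|r|^p over hits) at hits,
# -1/(N - k) at misses. ES = running-sum value of greatest magnitude,
# earliest rank winning ties (which.max on |run| semantics).
es_stat <- function(absw, hits, N, want_running = FALSE) {
  k <- length(hits)
  sw <- sum(absw[hits])
  inc <- rep.int(-1 / (N - k), N)
  # all-zero hit weights (every hit score exactly 0): fall back to equal steps
  inc[hits] <- if (sw > 0) absw[hits] / sw else 1 / k
  run <- cumsum(inc)
  i <- which.max(abs(run))
  list(es = run[[i]], rank_at_max = i, running = if (want_running) run)
}

#' Weighted KS enrichment score of one gene set
#'
#' Walks the ranked list accumulating `|score|^weight / sum` at gene-set
#' hits and `-1/(N - N_H)` at misses; the enrichment score (ES) is the
#' running sum's signed maximum deviation from zero, in \[-1, 1\], and
#' `rank_at_max` the first 1-based rank where it is attained. `weight = 0`
#' gives the classic equal-step Kolmogorov-Smirnov form; `weight = 1`
#' (default) the standard score-weighted form.
#'
#' @param ranked a [create_ranked_list()] result.
#' @param genes gene-set members (vector of gene IDs, or a `gene_set`).
#' @param weight non-negative weight exponent on |score|.
#' @return list with `es`, `rank_at_max`, `running` (the full running sum)
#'   and `hits` (member positions in the list).
#' @export
enrichment_score <- function(ranked, genes, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"), weight >= 0)
  members <- member_ids(genes)
  hits <- which(as.character(ranked$entries$gene_id) %in% members)
  N <- nrow(ranked$entries)
  if (length(hits) == 0L) {
    gsf_abort("empty_intersection", "gene set does not intersect the ranked list")
  }
  if (length(hits) == N) {
    gsf_abort("set_equals_universe", "gene set covers the whole ranked list")
  }
  r <- es_stat(abs(ranked$entries$score)^weight, hits, N, want_running = TRUE)
  r$hits <- hits
  r
}

member_ids <- function(genes) {
  if (inherits(genes, "gene_set")) set_member_labels(genes)
  else as.character(genes)
}

#' GSEA-preranked parameters
#'
#' @param seed integer seed for the permutation null — required, so every
#'   analysis is reproducible.
#' @param weight_exponent weight on |score| in the running statistic
#'   (0 = classic KS, 1 = weighted, default 1).
#' @param n_permutations gene-label permutations for the null (>= 10,
#'   default 1000).
#' @param fdr_threshold reporting threshold used by downstream tools
#'   (default 0.05).
#' @param min_size,max_size set-size filter applied to the intersection
#'   with the ranked list (defaults 10 and 500).
#' @return a `gsea_params` list.
#' @export
gsea_params <- function(seed, weight_exponent = 1, n_permutations = 1000,
                        fdr_threshold = 0.05, min_size = 10, max_size = 500) {
  if (missing(seed) || is.null(seed)) {
    gsf_abort("seed_required", "an explicit integer seed is required for the permutation null")
  }
  stopifnot(weight_exponent >= 0, is_count(n_permutations), n_permutations >= 10,
            fdr_threshold > 0, fdr_threshold <= 1,
            is_count(min_size), is_count(max_size), min_size <= max_size)
  structure(list(seed = as.integer(seed), weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 fdr_threshold = fdr_threshold,
                 min_size = as.integer(min_size), max_size = as.integer(max_size)),
            class = "gsea_params")
}

#' Preranked gene set enrichment analysis
#'
#' For every gene set passing the size filter, computes the weighted KS
#' enrichment score against the ranked list, a gene-label-permutation null
#' (random member positions, the only null available for preranked input),
#' the normalized enrichment score `NES = ES / mean(|null ES| of matching
#' sign)`, a matching-sign nominal p-value
#' `(1 + #{|null| >= |ES|}) / (1 + #null)`, the FDR q-value by the
#' positive/negative pooled-NES ratio procedure (sign-stratified, monotone
#' over more-extreme NES, clipped to \[0, 1\]), and the leading edge: the
#' member genes at ranks up to `rank_at_max` for positive ES, or from
#' `rank_at_max` on for negative ES. A set whose sign has no null
#' realisations gets `NES = NA` (never fabricated).
#'
#' @param ranked a [create_ranked_list()] result.
#' @param collection gene sets: a named list of `gene_set` objects or of
#'   member-ID vectors, or a GMT file path.
#' @param params a [gsea_params()].
#' @return a `gsea_result`; `tidy()` it for the per-set table.
#' @export
gsea_preranked <- function(ranked, collection, params) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(params, "gsea_params"))
  collection <- as_collection(collection)
  uid <- as.character(ranked$entries$gene_id)
  N <- length(uid)
  hits_list <- lapply(collection, function(m) which(uid %in% m))
  sizes <- lengths(hits_list)
  keep <- sizes >= params$min_size & sizes <= params$max_size & sizes < N
  if (!any(keep)) {
    gsf_abort("no_sets_pass_size_filter",
      sprintf("no gene set has between %d and %d genes in the ranked list",
              params$min_size, params$max_size))
  }
  hits_list <- hits_list[keep]
  set_names <- names(collection)[keep]
  sizes <- sizes[keep]

  absw <- abs(ranked$entries$score)^params$weight_exponent
  obs <- lapply(hits_list, function(h) es_stat(absw, h, N, want_running = TRUE))
  es <- vapply(obs, `[[`, 0, "es")
  rank_at_max <- vapply(obs, `[[`, 0L, "rank_at_max")

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)
  B <- params$n_permutations
  null_es <- matrix(0, nrow = B, ncol = length(hits_list))
  for (si in seq_along(hits_list)) {
    k <- sizes[si]
    null_es[, si] <- vapply(seq_len(B), function(b) {
      es_stat(absw, sample.int(N, k), N)$es
    }, 0)
  }

  nes <- p_value <- rep(NA_real_, length(es))
  pos_mean <- neg_mean <- rep(NA_real_, length(es))
  for (si in seq_along(es)) {
    nl <- null_es[, si]
    pos <- nl[nl > 0]; neg <- nl[nl < 0]
    if (length(pos)) pos_mean[si] <- mean(pos)
    if (length(neg)) neg_mean[si] <- mean(abs(neg))
    if (es[si] >= 0) {
      if (length(pos)) {
        nes[si] <- es[si] / pos_mean[si]
        p_value[si] <- (1 + sum(pos >= es[si])) / (1 + length(pos))
      }
    } else {
      if (length(neg)) {
        nes[si] <- es[si] / neg_mean[si]
        p_value[si] <- (1 + sum(neg <= es[si])) / (1 + length(neg))
      }
    }
  }

  fdr_q <- gsea_fdr(es, nes, null_es, pos_mean, neg_mean)

  leading_edge <- lapply(seq_along(es), function(si) {
    h <- hits_list[[si]]
    le <- if (es[si] > 0) h[h <= rank_at_max[si]]
          else if (es[si] < 0) h[h >= rank_at_max[si]]
          else integer(0)
    ranked$entries$gene_id[le]
  })

  results <- tibble::tibble(
    set_name = set_names, size = unname(sizes), es = unname(es),
    nes = nes, p_value = p_value, fdr_q = fdr_q,
    rank_at_max = as.integer(unname(rank_at_max)),
    leading_edge = unname(leading_edge))
  structure(list(results = results, ranked = ranked, params = params,
                 hits = stats::setNames(hits_list, set_names),
                 collection_names = names(collection)),
            class = "gsea_result")
}

# FDR by the pooled normalized-null procedure: per-set nulls are rescaled
# by their sign's mean |null ES|, pooled over sets, and for each observed
# NES* the tail fractions of pooled null vs observed NES (same sign) form
# the ratio; q is then made monotone by taking the minimum over sets with
# more extreme NES.
gsea_fdr <- function(es, nes, null_es, pos_mean, neg_mean) {
  pool <- c()
  for (si in seq_along(es)) {
    nl <- null_es[, si]
    v <- c(if (!is.na(pos_mean[si])) nl[nl > 0] / pos_mean[si],
           if (!is.na(neg_mean[si])) nl[nl < 0] / neg_mean[si])
    pool <- c(pool, v)
  }
  obs <- nes[!is.na(nes)]
  q <- rep(NA_real_, length(nes))
  n_pool_pos <- sum(pool >= 0); n_pool_neg <- sum(pool <= 0)
  n_obs_pos <- sum(obs >= 0); n_obs_neg <- sum(obs <= 0)
  for (si in seq_along(nes)) {
    v <- nes[si]
    if (is.na(v)) next
    q[si] <- if (v >= 0) {
      if (n_pool_pos == 0L || n_obs_pos == 0L) NA_real_ else {
        num <- sum(pool >= v) / n_pool_pos
        den <- sum(obs >= v) / n_obs_pos
        min(1, num / den)
      }
    } else {
      if (n_pool_neg == 0L || n_obs_neg == 0L) NA_real_ else {
        num <- sum(pool <= v) / n_pool_neg
        den <- sum(obs <= v) / n_obs_neg
        min(1, num / den)
      }
    }
  }
  # monotone (step-up): each set's q may borrow the smallest q among sets
  # with less extreme NES, so q never decreases as NES moves toward 0
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(q) & ((sgn > 0 & nes >= 0) | (sgn < 0 & nes < 0)))
    if (length(idx)) {
      ord <- idx[order(-sgn * nes[idx])]  # most extreme first
      q[ord] <- rev(cummin(rev(q[ord])))
    }
  }
  q
}

as_collection <- function(collection) {
  if (is.character(collection) && length(collection) == 1L && file.exists(collection)) {
    collection <- read_gmt(collection)
  }
  if (inherits(collection, "gene_set")) collection <- list(collection)
  stopifnot(is.list(collection), length(collection) > 0L)
  out <- lapply(collection, member_ids)
  from_sets <- vapply(collection,
                      function(s) if (inherits(s, "gene_set")) s$name else NA_character_, "")
  nms <- names(collection) %||% from_sets
  blank <- is.na(nms) | !nzchar(nms)
  nms[blank] <- from_sets[blank]
  if (anyNA(nms) || any(!nzchar(nms))) {
    gsf_abort("malformed_collection", "every gene set in a collection needs a name")
  }
  stats::setNames(out, nms)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up control of the false discovery rate across a family of
#' p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    gsf_abort("value_out_of_range", "p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the DEG list overlaps it more than
#' expected when drawing `n = |DEG|` genes without replacement from the
#' universe of `N` genes containing `K = |set ∩ universe|` set members:
#' the upper-tail probability `P[X >= k]` with
#' `X ~ Hypergeometric(N, K, n)` and `k = |set ∩ DEG|`. P-values are
#' BH-adjusted across the collection. The universe defaults to all genes
#' of the originating contrast after collapsing (`"contrast"`); the
#' alternative `"collection"` uses the union of the collection's genes.
#' The chosen policy is recorded in the result.
#'
#' @param deg a [create_deg_list()] result.
#' @param collection gene sets (as in [gsea_preranked()]).
#' @param universe `"contrast"` or `"collection"`.
#' @return an `ora_result`; `tidy()` gives the four-column table
#'   (set name, overlap, p-value, FDR).
#' @export
ora_hypergeometric <- function(deg, collection, universe = c("contrast", "collection")) {
  stopifnot(inherits(deg, "deg_list"))
  universe <- match.arg(universe)
  collection <- as_collection(collection)
  univ <- if (universe == "contrast") {
    as.character(deg$universe)
  } else {
    unique(unlist(collection, use.names = FALSE))
  }
  if (length(univ) == 0L) gsf_abort("empty_universe", "the gene universe is empty")
  degs <- intersect(as.character(deg$gene_ids), univ)
  N <- length(univ)
  n <- length(degs)
  rows <- purrr::map2_dfr(collection, names(collection), function(m, nm) {
    mm <- intersect(m, univ)
    K <- length(mm)
    k <- length(intersect(mm, degs))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, overlap = k, set_size = K, p_value = p)
  })
  rows$fdr <- bh_adjust(rows$p_value)
  structure(list(results = rows, universe_policy = universe,
                 universe_size = N, n_deg = n,
                 p_threshold = deg$p_threshold,
                 contrast_ref = deg$contrast_ref),
            class = "ora_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  sig <- sum(x$results$fdr_q <= x$params$fdr_threshold, na.rm = TRUE)
  cat(sprintf("<gsea_result> %d set(s), %d permutations (seed %d): %d at FDR <= %s\n",
              nrow(x$results), x$params$n_permutations, x$params$seed, sig,
              format(x$params$fdr_threshold)))
  invisible(x)
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("<ora_result> %d set(s), universe '%s' (N = %d), %d DEGs: %d at FDR <= 0.05\n",
              nrow(x$results), x$universe_policy, x$universe_size, x$n_deg,
              sum(x$results$fdr <= 0.05)))
  invisible(x)
}

#' Persist and reload a GSEA result
#'
#' JSON serialisation so results can be passed between command-line steps
#' (results-matrix and leading-edge extraction) without loss: the per-set
#' table, the ranked list, the member positions and the parameters all
#' round-trip.
#'
#' @param x a `gsea_result`.
#' @param path JSON file path.
#' @return `read_gsea_result()`: the restored `gsea_result`.
#' @export
write_gsea_result <- function(x, path) {
  stopifnot(inherits(x, "gsea_result"))
  res <- x$results
  jsonlite::write_json(list(
    results = dplyr::select(res, -"leading_edge"),
    leading_edge = res$leading_edge,
    hits = unname(x$hits),
    ranked = list(entries = x$ranked$entries, metric = x$ranked$metric,
                  contrast_ref = x$ranked$contrast_ref),
    params = unclass(x$params)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gsea_result
#' @export
read_gsea_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  rows <- j$results
  results <- tibble::tibble(
    set_name = vapply(rows, function(r) r$set_name, ""),
    size = vapply(rows, function(r) as.integer(r$size), 0L),
    es = vapply(rows, function(r) as.numeric(r$es), 0),
    nes = vapply(rows, function(r) num_or_na(r$nes), 0),
    p_value = vapply(rows, function(r) num_or_na(r$p_value), 0),
    fdr_q = vapply(rows, function(r) num_or_na(r$fdr_q), 0),
    rank_at_max = vapply(rows, function(r) as.integer(r$rank_at_max), 0L),
    leading_edge = lapply(j$leading_edge, function(v) as.integer(unlist(v))))
  entries <- tibble::tibble(
    gene_id = vapply(j$ranked$entries, function(r) as.integer(r$gene_id), 0L),
    score = vapply(j$ranked$entries, function(r) as.numeric(r$score), 0))
  ranked <- structure(list(entries = entries, metric = j$ranked$metric,
                           contrast_ref = j$ranked$contrast_ref),
                      class = "ranked_list")
  hits <- lapply(j$hits, function(v) as.integer(unlist(v)))
  structure(list(results = results, ranked = ranked,
                 params = do.call(gsea_params, j$params[c(
                   "seed", "weight_exponent", "n_permutations",
                   "fdr_threshold", "min_size", "max_size")]),
                 hits = stats::setNames(hits, results$set_name),
                 collection_names = results$set_name),
            class = "gsea_result")
}
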