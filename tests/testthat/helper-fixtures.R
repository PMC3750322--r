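# Shared in-code fixtures and independent oracles.

# a tiny hand-written mapping table exercising status ranks, synonyms and
# multi-mapping: probe PS_MULTI maps to genes 9 (Provisional) and 44
# (Reviewed); SHARED is gene 7's official symbol and a synonym of gene 9.
tiny_table <- function(version = "tiny-v1") {
  mapping_table(tibble::tibble(
    source_id = c("PS_A1", "PS_A2", "PS_B", "PS_MULTI", "PS_MULTI", "PS_C"),
    gene_id = c(7L, 7L, 9L, 9L, 44L, 101L),
    official_symbol = c("SHARED", "SHARED", "GB", "GB", "GD", "GC"),
    refseq_status = c("Validated", "Validated", "Provisional", "Provisional",
                      "Reviewed", "Unknown"),
    synonyms = list(character(0), character(0), c("SHARED", "ALT9"),
                    c("SHARED", "ALT9"), character(0), "ALT101")
  ), version = version)
}

# small deterministic probe-level dataset against tiny_table()
tiny_dataset <- function(name = "TINY", skip_gene_sets = character(0),
                         extraction_overrides = list()) {
  contrast_dataset(
    dataset_name = name,
    source_ids = c("PS_A1", "PS_A2", "PS_B", "PS_MULTI", "PS_C", "PS_NOPE"),
    contrasts = list(
      C1 = tibble::tibble(
        M = c(1.5, 1.2, -2.0, 0.8, 3.0, 0.5),
        A = c(8, 9, 7, 6, 10, 5),
        P = c(0.01, 0.20, 0.001, 0.04, 0.0005, 0.9),
        S = c(4.1, 1.1, -6.2, 2.5, 8.0, 0.3)),
      C2 = tibble::tibble(
        M = c(-0.5, -0.7, 1.1, -1.3, 0.2, 0.9),
        A = c(8, 9, 7, 6, 10, 5),
        P = c(0.30, 0.02, 0.06, 0.01, 0.70, 0.10),
        S = c(-1.0, -2.8, 2.0, -3.3, 0.4, 1.8))),
    source_id_type = "probe_set", organism = "human",
    skip_gene_sets = skip_gene_sets,
    extraction_overrides = extraction_overrides)
}

# random dataset builder covering parser paths: random group order, random
# optional columns, pass-through columns, NAs in A/P/S
random_dataset <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:30, 1)
    n_contrasts <- sample(1:3, 1)
    letters_set <- c("M", sample(c("A", "P", "S"), sample(0:3, 1)))
    letters_set <- sample(letters_set)  # random in-group order
    contrasts <- list()
    for (ci in seq_len(n_contrasts)) {
      cols <- list()
      for (l in letters_set) {
        v <- switch(l,
          M = round(stats::rnorm(n), 4),
          A = stats::rnorm(n, 8),
          P = stats::runif(n),
          S = stats::rnorm(n, sd = 3))
        if (l != "M" && stats::runif(1) < 0.3) v[sample(n, 1)] <- NA
        cols[[l]] <- v
      }
      contrasts[[paste0("K", ci)]] <- tibble::as_tibble(cols)
    }
    extra <- if (stats::runif(1) < 0.5) {
      tibble::tibble(note = sample(letters, n, replace = TRUE))
    } else NULL
    contrast_dataset(
      dataset_name = paste0("RND", seed),
      source_ids = sprintf("P%03d_%d", seq_len(n), seed),
      contrasts = contrasts, source_id_type = "probe_set",
      organism = "human", extra = extra)
  })
}

# --- independent oracles -------------------------------------------------

# naive group-by collapse: resolve ids by scanning the records table,
# fan out, pick per-gene representative by looping over rows
oracle_collapse <- function(dataset, table, strategy) {
  first <- dataset$contrasts[[1L]]
  rows <- list()
  for (i in seq_along(dataset$source_ids)) {
    id <- dataset$source_ids[i]
    genes <- switch(dataset$header$source_id_type,
      probe_set = unique(table$records$gene_id[table$records$source_id == id]),
      entrez = {
        g <- suppressWarnings(as.integer(id))
        if (!is.na(g) && g %in% table$genes$gene_id) g else integer(0)
      },
      gene_symbol = {
        hit <- table$genes$gene_id[tolower(table$genes$official_symbol) == tolower(id)]
        if (length(hit) == 0) {
          hit <- unlist(lapply(seq_len(nrow(table$genes)), function(j)
            if (tolower(id) %in% tolower(table$genes$synonyms[[j]]))
              table$genes$gene_id[j]))
        }
        sort(unique(hit))
      })
    for (g in genes) rows[[length(rows) + 1L]] <- list(row = i, gene = g)
  }
  if (length(rows) == 0) return(NULL)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  out <- list()
  for (g in sort(unique(df$gene))) {
    cand <- df$row[df$gene == g]
    pick <- switch(strategy,
      best_p = {
        p <- first$P[cand]; p[is.na(p)] <- Inf
        s <- if ("S" %in% names(first)) abs(first$S[cand]) else rep(0, length(cand))
        s[is.na(s)] <- -Inf
        best <- cand[p == min(p)]
        sb <- s[p == min(p)]
        best <- best[sb == max(sb)]
        min(best)
      },
      max_abs_s = {
        s <- abs(first$S[cand]); s[is.na(s)] <- -Inf
        min(cand[s == max(s)])
      },
      max_a = {
        a <- first$A[cand]; a[is.na(a)] <- -Inf
        min(cand[a == max(a)])
      })
    out[[as.character(g)]] <- pick
  }
  out
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# cumulative-walk ES oracle, written straight from the definition
oracle_es <- function(scores, member_ids, gene_ids, p) {
  N <- length(scores)
  hit <- gene_ids %in% member_ids
  nh <- sum(hit)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (j in seq_len(N)) {
    cur <- if (hit[j]) cur + (if (denom > 0) w[j] / denom else 1 / nh)
           else cur - 1 / (N - nh)
    run[j] <- cur
  }
  i <- which.max(abs(run))
  list(es = run[i], rank_at_max = i, run = run)
}

gene_set_name_for <- function(gd, contrast, suffix) {
  sprintf("%s_[%s]_%s", gd$dataset_name, contrast, suffix)
}

new_gene_set_for_test <- function(name, gene_ids) {
  gsforge:::new_gene_set(
    name = name, suffix = NA_character_,
    members = tibble::tibble(rank = seq_along(gene_ids),
                             gene_id = as.integer(gene_ids),
                             symbol = paste0("G", gene_ids)),
    description = "test set")
}
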