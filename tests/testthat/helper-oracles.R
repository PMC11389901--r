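# Independent oracles used by the property and acceptance tests. These are
# deliberately written in plain base R, separate from the package's code
# paths (which use utils::adist and dplyr), so the two routes can disagree.

# Textbook Levenshtein dynamic program, full (n+1) x (m+1) table.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0L:n
  d[1L, ] <- 0L:m
  if (n > 0 && m > 0) {
    for (i in 1:n) {
      for (j in 1:m) {
        d[i + 1L, j + 1L] <- min(
          d[i, j + 1L] + 1L,
          d[i + 1L, j] + 1L,
          d[i, j] + as.integer(x[i] != y[j])
        )
      }
    }
  }
  d[n + 1L, m + 1L]
}

# Brute-force fuzzy linking of one query against a dictionary: best score
# and the set of top-scoring surfaces' concepts, via lev_dp.
brute_link <- function(query, dict, cutoff = 70) {
  scores <- vapply(dict$surface, function(s) {
    100 * (1 - lev_dp(query, s) / max(nchar(query), nchar(s)))
  }, numeric(1), USE.NAMES = FALSE)
  best <- max(scores)
  winners <- unique(dict$concept_id[scores == best])
  status <- if (best < cutoff) "unlinked"
            else if (length(winners) > 1) "ambiguous" else "linked"
  list(best = best, winners = sort(winners), status = status,
       concept = if (status == "linked") winners else NA_character_)
}

# Brute-force recount of every frequency-report field from a long entity
# list, using only base R loops over split().
oracle_report <- function(lists) {
  key <- paste(lists$source, lists$entity_type)
  out <- list()
  for (k in sort(unique(key))) {
    sub <- lists[key == k, ]
    by_event <- split(seq_len(nrow(sub)), sub$event_id)
    n_ent <- vapply(by_event, length, integer(1))
    n_norm <- vapply(by_event, function(i) sum(sub$linked[i]), integer(1))
    n_con <- vapply(by_event, function(i) {
      length(unique(sub$concept_id[i][sub$linked[i]]))
    }, integer(1))
    pop_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
    out[[k]] <- data.frame(
      source = sub$source[1], entity_type = sub$entity_type[1],
      total_events_with_entities = length(by_event),
      total_entities = nrow(sub),
      vocabulary_size = length(unique(sub$surface)),
      total_normalized = sum(sub$linked),
      normalized_rate = sum(sub$linked) / nrow(sub),
      total_concepts = length(unique(sub$concept_id[sub$linked])),
      entities_median = median(n_ent), entities_mean = mean(n_ent),
      entities_sd = pop_sd(n_ent),
      normalized_median = median(n_norm), normalized_mean = mean(n_norm),
      normalized_sd = pop_sd(n_norm),
      concepts_median = median(n_con), concepts_mean = mean(n_con),
      concepts_sd = pop_sd(n_con)
    )
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Exhaustive Venn region counting by membership enumeration.
oracle_venn <- function(a, b, c) {
  u <- unique(c(a, b, c))
  counts <- integer(7)
  names(counts) <- c("100", "010", "001", "110", "101", "011", "111")
  for (el in u) {
    p <- paste0(as.integer(el %in% a), as.integer(el %in% b),
                as.integer(el %in% c))
    counts[p] <- counts[p] + 1L
  }
  c(counts, union = length(u))
}

# Small in-memory pipeline: simulate, tag, negate, filter, normalize, link
# orders, assemble entity lists. Used wherever a test needs a full corpus.
run_mini <- function(cfg, cutoff = 70) {
  sim <- simulate_ehr(cfg)
  dicts <- list(disease = sim$disease_dict, drug = sim$drug_dict)
  m <- tag_entities(sim$documents, dicts)
  m <- detect_negation(sim$documents, m, cues = cfg$negation_cues)
  pos <- filter_negated(m)
  nc <- normalize_corpus(pos, dicts, cutoff = cutoff)
  linked_mo <- link_mo_products(sim$mo, sim$drug_dict, cutoff = cutoff)
  lists <- build_entity_lists(sim$dpc, linked_mo, nc$mentions)
  list(sim = sim, dicts = dicts, mentions = m, positives = pos,
       normalized = nc, linked_mo = linked_mo, lists = lists)
}

# Random lowercase string, for oracle test instances.
rnd_str <- function(min_len = 3, max_len = 12) {
  paste(sample(letters[1:6], sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

mention_key <- function(x) {
  sort(paste(x$doc_id, x$start, x$end, x$surface, x$entity_type, x$factuality))
}
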