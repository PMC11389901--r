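#' Normalized Levenshtein score
#'
#' Scores string similarity on a 0-100 scale as
#' `100 * (1 - lev(a, b) / max(nchar(a), nchar(b)))`, where `lev` is the
#' Levenshtein edit distance. The score is symmetric, equals 100 iff the
#' strings are identical, and 0 when every character must change. Inputs
#' are NFKC-normalized, trimmed, and Latin-case-folded before comparison.
#' A score of 70 is the conventional cutoff for accepting a concept link.
#'
#' @param a,b Character vectors (recycled to common length); must be
#'   non-empty after normalization.
#' @return Numeric vector of scores in `[0, 100]`.
#' @examples
#' nls_score("stomatitis", "stomatitis")  # 100
#' nls_score("abcd", "abce")              # 75
#' @export
nls_score <- function(a, b) {
  a <- canonicalize(a)
  b <- canonicalize(b)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort_bad("normalized Levenshtein score is undefined for empty strings")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d <- mapply(function(x, y) utils::adist(x, y), a, b, USE.NAMES = FALSE)
  100 * (1 - d / pmax(nchar(a), nchar(b)))
}

# Core fuzzy linker over canonicalized query surfaces. Returns one row per
# query: best score, winning concept (NA when unlinked/ambiguous), status,
# and the best-matching dictionary surface. Cross-concept top-score ties
# are excluded as ambiguous; ties among surfaces of a single concept are
# harmless and resolved to the lexicographically smallest surface.
link_surfaces <- function(queries, dictionary, cutoff = 70) {
  if (is.null(dictionary) || nrow(dictionary) == 0) {
    abort_bad("cannot link against an empty dictionary")
  }
  dict_surface <- canonicalize(dictionary$surface)
  dict_concept <- dictionary$concept_id
  uq <- unique(canonicalize(queries))
  if (any(!nzchar(uq))) abort_bad("cannot link an empty surface")

  d <- utils::adist(uq, dict_surface)
  len_max <- outer(nchar(uq), nchar(dict_surface), pmax)
  score <- 100 * (1 - d / len_max)

  res <- lapply(seq_along(uq), function(i) {
    s <- score[i, ]
    best <- max(s)
    if (best < cutoff) {
      return(list(score = best, concept_id = NA_character_,
                  status = "unlinked", matched_surface = NA_character_))
    }
    top <- which(s == best)
    concepts <- unique(dict_concept[top])
    if (length(concepts) > 1) {
      list(score = best, concept_id = NA_character_,
           status = "ambiguous", matched_surface = NA_character_)
    } else {
      list(score = best, concept_id = concepts,
           status = "linked",
           matched_surface = min(dictionary$surface[top]))
    }
  })
  lk <- tibble::tibble(
    query = uq,
    score = vapply(res, `[[`, numeric(1), "score"),
    concept_id = vapply(res, `[[`, character(1), "concept_id"),
    status = vapply(res, `[[`, character(1), "status"),
    matched_surface = vapply(res, `[[`, character(1), "matched_surface")
  )
  lk[match(canonicalize(queries), lk$query), -1, drop = FALSE]
}

#' Link mentions to medical concepts by fuzzy matching
#'
#' Scores every dictionary surface against each mention surface with the
#' normalized Levenshtein score ([nls_score()]) and links the mention to the
#' best-scoring concept. A best score below `cutoff` leaves the mention
#' `unlinked`; a top score shared by surfaces of two or more distinct
#' concepts marks it `ambiguous` (excluded from analysis, concept `NA`).
#' Disease mentions are linked against the disease dictionary, drug
#' mentions against the drug dictionary.
#'
#' @param mentions Tibble of mentions (`surface`, `entity_type`, ...).
#' @param dictionaries List with `disease` and `drug` dictionary tibbles.
#' @param cutoff Minimum accepted score (inclusive), default 70.
#' @return `mentions` with added columns `concept_id`, `score`, `status`,
#'   `matched_surface`.
#' @export
link_mention <- function(mentions, dictionaries, cutoff = 70) {
  if (nrow(mentions) == 0) {
    mentions$concept_id <- character(0)
    mentions$score <- numeric(0)
    mentions$status <- character(0)
    mentions$matched_surface <- character(0)
    return(mentions)
  }
  out <- vector("list", 2)
  types <- c("disease", "drug")
  for (k in seq_along(types)) {
    sub <- mentions[mentions$entity_type == types[k], , drop = FALSE]
    if (nrow(sub) == 0) next
    lk <- link_surfaces(sub$surface, dictionaries[[types[k]]], cutoff)
    out[[k]] <- dplyr::bind_cols(sub, lk)
  }
  res <- dplyr::bind_rows(out)
  res[order(match(
    paste(res$doc_id, res$start, res$entity_type),
    paste(mentions$doc_id, mentions$start, mentions$entity_type)
  )), , drop = FALSE]
}

#' Normalize a mention corpus and report link rates
#'
#' Runs [link_mention()] over positive mentions and summarises, per entity
#' type, the total number of entities, the number successfully normalized
#' (linked to a concept), and the normalized-entity rate
#' `total_normalized / total_entities` (reported as `NA` when there are no
#' entities of a type).
#'
#' @param mentions Tibble of positive mentions (run [filter_negated()]
#'   first).
#' @param dictionaries List with `disease` and `drug` dictionary tibbles.
#' @param cutoff Minimum accepted score, default 70.
#' @return A list of class `normalized_corpus`: `mentions` (with link
#'   columns) and `report` (tibble with `source`, `entity_type`,
#'   `total_entities`, `total_normalized`, `normalized_rate`).
#' @export
normalize_corpus <- function(mentions, dictionaries, cutoff = 70) {
  linked <- link_mention(mentions, dictionaries, cutoff)
  report <- tibble::tibble(entity_type = c("disease", "drug")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      total_entities = sum(linked$entity_type == .data$entity_type),
      total_normalized = sum(linked$entity_type == .data$entity_type &
                               linked$status == "linked")
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      source = "TEXT",
      normalized_rate = ifelse(.data$total_entities > 0,
                               .data$total_normalized / .data$total_entities,
                               NA_real_)
    ) |>
    dplyr::select("source", "entity_type", "total_entities",
                  "total_normalized", "normalized_rate")
  structure(list(mentions = linked, report = report),
            class = "normalized_corpus")
}

#' Link medication-order product names to pharmaceutical ingredients
#'
#' Applies the same fuzzy-matching contract as [link_mention()] to the
#' `product_name` column of medication orders: spelled variants of one
#' product link to its ingredient when the normalized Levenshtein score
#' reaches `cutoff`; unlinked and ambiguous names are counted in the
#' `"link_report"` attribute.
#'
#' @param mo Tibble of medication orders with a `product_name` column.
#' @param drug_dictionary Drug dictionary tibble (`surface`, `concept_id`).
#' @param cutoff Minimum accepted score, default 70.
#' @return `mo` with added columns `ingredient` (concept or `NA`), `score`,
#'   `status`; attribute `link_report` holds the status counts.
#' @export
link_mo_products <- function(mo, drug_dictionary, cutoff = 70) {
  if (nrow(mo) == 0) {
    mo$ingredient <- character(0)
    mo$score <- numeric(0)
    mo$status <- character(0)
    return(mo)
  }
  lk <- link_surfaces(mo$product_name, drug_dictionary, cutoff)
  mo$ingredient <- lk$concept_id
  mo$score <- lk$score
  mo$status <- lk$status
  attr(mo, "link_report") <- c(
    linked = sum(lk$status == "linked"),
    unlinked = sum(lk$status == "unlinked"),
    ambiguous = sum(lk$status == "ambiguous")
  )
  mo
}

#' Read a term dictionary from TSV
#'
#' Columns: `surface`, `concept_id`, `concept_name`, and binary adverse-
#' effect relevance flags `flag_1`, `flag_2`, ... (any number; 7 by
#' convention).
#'
#' @param path Path to a UTF-8 TSV with a header row.
#' @return A dictionary tibble.
#' @export
read_dictionary <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    surface = "c", concept_id = "c", concept_name = "c", .default = "i"
  ), progress = FALSE)
  need <- c("surface", "concept_id")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort_bad("dictionary lacks column(s): %s", paste(miss, collapse = ", "))
  }
  flags <- grep("^flag_", names(d), value = TRUE)
  for (f in flags) {
    if (any(!d[[f]] %in% c(0L, 1L))) {
      abort_bad("dictionary flag column `%s` must be binary", f)
    }
  }
  d
}
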