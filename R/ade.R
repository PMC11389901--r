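#' Define a target symptom for adverse-effect screening
#'
#' A symptom is detected in text either via the dictionary's binary
#' adverse-effect relevance flags (`mode = "ade_flag"`: a mention counts
#' when its best-matching dictionary entry carries a 1 in flag column
#' `flag_index`) or via ICD prefixes on the linked concept
#' (`mode = "icd_prefix"`).
#'
#' @param name Symptom name.
#' @param mode `"ade_flag"` or `"icd_prefix"`.
#' @param flag_index Flag column number (1-7 by convention) when
#'   `mode = "ade_flag"`.
#' @param icd_prefixes ICD prefixes when `mode = "icd_prefix"`.
#' @return A list of class `symptom_spec`.
#' @export
symptom_spec <- function(name, mode = c("ade_flag", "icd_prefix"),
                         flag_index = NULL, icd_prefixes = NULL) {
  mode <- match.arg(mode)
  if (mode == "ade_flag") {
    if (is.null(flag_index)) abort_bad("ade_flag mode requires `flag_index`")
    if (!is.null(icd_prefixes)) abort_bad("set exactly one of flag_index / icd_prefixes")
  } else {
    if (is.null(icd_prefixes)) abort_bad("icd_prefix mode requires `icd_prefixes`")
    if (!is.null(flag_index)) abort_bad("set exactly one of flag_index / icd_prefixes")
  }
  structure(list(name = name, mode = mode,
                 flag_index = flag_index,
                 icd_prefixes = icd_prefixes),
            class = "symptom_spec")
}

#' Events whose text records the target symptom
#'
#' An event qualifies when any of its positive, concept-linked disease
#' mentions matches the symptom spec. Only text evidence counts: symptoms
#' live in the narrative, not in billing codes.
#'
#' @param text_mentions Normalized positive mentions (with
#'   `matched_surface`).
#' @param spec A [symptom_spec()].
#' @param disease_dict Disease dictionary (needed for `ade_flag` mode).
#' @return Character vector of event IDs.
#' @export
symptom_events <- function(text_mentions, spec, disease_dict = NULL) {
  m <- text_mentions[text_mentions$entity_type == "disease" &
                       text_mentions$status == "linked", , drop = FALSE]
  if (nrow(m) == 0) return(character(0))
  hit <- if (spec$mode == "icd_prefix") {
    starts_with_any(m$concept_id, spec$icd_prefixes)
  } else {
    if (is.null(disease_dict)) abort_bad("ade_flag mode needs `disease_dict`")
    flag_col <- paste0("flag_", spec$flag_index)
    if (!flag_col %in% names(disease_dict)) {
      abort_bad("dictionary has no column `%s`", flag_col)
    }
    key_dict <- paste(disease_dict$surface, disease_dict$concept_id)
    key_m <- paste(m$matched_surface, m$concept_id)
    disease_dict[[flag_col]][match(key_m, key_dict)] == 1
  }
  unique(m$event_id[hit %in% TRUE])
}

#' Per-event sets of ordered category drugs
#'
#' Restricts linked medication orders to a drug category (e.g. the
#' anticancer ingredients) and returns, per event that ordered at least
#' one of them, the deduplicated set of category ingredients given during
#' that hospitalization.
#'
#' @param linked_mo Tibble from [link_mo_products()].
#' @param drug_category Character vector of ingredient names.
#' @return A tibble with `event_id` and list-column `drugs`.
#' @export
select_events_with_drugs <- function(linked_mo, drug_category) {
  if (length(drug_category) == 0) abort_bad("empty drug category")
  sub <- linked_mo[linked_mo$status == "linked" &
                     linked_mo$ingredient %in% drug_category, , drop = FALSE]
  sub |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(drugs = list(sort(unique(.data$ingredient))),
                     .groups = "drop")
}

# events x drugs incidence matrix; the cross-product gives pair counts
# with single-drug counts on the diagonal.
incidence_matrix <- function(event_drug_sets, drugs) {
  X <- matrix(0L, nrow = nrow(event_drug_sets), ncol = length(drugs),
              dimnames = list(event_drug_sets$event_id, drugs))
  for (i in seq_len(nrow(event_drug_sets))) {
    X[i, intersect(event_drug_sets$drugs[[i]], drugs)] <- 1L
  }
  X
}

#' Drug-pair event-count matrix
#'
#' `M[i, j]` (i != j) is the number of events in which both drug i and
#' drug j were ordered; the diagonal `M[i, i]` counts events with drug i.
#' Symmetric by construction.
#'
#' @param event_drug_sets Tibble from [select_events_with_drugs()].
#' @param drugs Ordered character vector of ingredient names (the matrix
#'   axes); defaults to all drugs seen.
#' @return An integer matrix with drug names as dimnames.
#' @export
build_M <- function(event_drug_sets,
                    drugs = sort(unique(unlist(event_drug_sets$drugs)))) {
  X <- incidence_matrix(event_drug_sets, drugs)
  M <- crossprod(X)
  storage.mode(M) <- "integer"
  M
}

#' Symptomatic drug-pair event-count matrix
#'
#' `D[i, j]` counts the events counted in `M[i, j]` whose text records the
#' target symptom; elementwise `D <= M` always holds.
#'
#' @param event_drug_sets Tibble from [select_events_with_drugs()].
#' @param symptom_event_ids Event IDs from [symptom_events()].
#' @param drugs Drug axis, as in [build_M()].
#' @return An integer matrix, same shape as the M matrix.
#' @export
build_D <- function(event_drug_sets, symptom_event_ids,
                    drugs = sort(unique(unlist(event_drug_sets$drugs)))) {
  sub <- event_drug_sets[event_drug_sets$event_id %in% symptom_event_ids, ,
                         drop = FALSE]
  X <- incidence_matrix(sub, drugs)
  D <- crossprod(X)
  storage.mode(D) <- "integer"
  D
}

#' Co-frequency ratio matrix D/M
#'
#' Elementwise division of the symptomatic pair counts by the pair counts:
#' among events exposed to a drug pair, the fraction whose text mentions
#' the target symptom. Cells with `M < max(1, min_events)` are masked
#' (`NA`) rather than reported as 0 — an unobserved pair has no ratio.
#'
#' @param M,D Matrices from [build_M()] and [build_D()].
#' @param min_events Minimum pair-event count for a cell to be displayed.
#' @param drugs Optional drug axis (defaults to `rownames(M)`).
#' @return An object of class `pair_matrix` holding `drugs`, `M`, `D`,
#'   `ratio`, `min_events`.
#' @export
ratio_heatmap <- function(M, D, min_events = 0, drugs = rownames(M)) {
  if (!all(dim(M) == dim(D))) abort_bad("M and D shapes differ")
  if (any(D > M)) abort_bad("D exceeds M: symptomatic events outnumber pair events")
  ratio <- D / M
  ratio[M < max(1, min_events)] <- NA_real_
  structure(list(drugs = drugs, M = M, D = D, ratio = ratio,
                 min_events = min_events),
            class = "pair_matrix")
}

#' Full ADE co-frequency analysis
#'
#' Convenience wrapper: selects category events, builds M and D, and
#' returns the co-frequency ratio object.
#'
#' @param linked_mo Tibble from [link_mo_products()].
#' @param text_mentions Normalized positive mentions.
#' @param drug_category Character vector of ingredient names.
#' @param symptom A [symptom_spec()].
#' @param disease_dict Disease dictionary (for `ade_flag` mode).
#' @param min_events Display cutoff for [ratio_heatmap()].
#' @return A `pair_matrix`.
#' @export
ade_analysis <- function(linked_mo, text_mentions, drug_category, symptom,
                         disease_dict = NULL, min_events = 0) {
  sets <- select_events_with_drugs(linked_mo, drug_category)
  drugs <- sort(intersect(drug_category, unique(unlist(sets$drugs))))
  sev <- symptom_events(text_mentions, symptom, disease_dict)
  M <- build_M(sets, drugs)
  D <- build_D(sets, sev, drugs)
  ratio_heatmap(M, D, min_events)
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("<pair_matrix> ", length(x$drugs), " drugs, ",
      sum(diag(x$M)), " drug-event exposures\n", sep = "")
  cat("co-frequency ratio range: ",
      paste(round(range(x$ratio, na.rm = TRUE), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Long-format view of a pair matrix
#'
#' @param x A `pair_matrix`.
#' @param ... Unused.
#' @return Tibble with `drug_a`, `drug_b`, `m`, `d`, `ratio` (upper
#'   triangle including the diagonal).
#' @export
tidy.pair_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$M, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    drug_a = x$drugs[idx[, 1]],
    drug_b = x$drugs[idx[, 2]],
    m = x$M[idx],
    d = x$D[idx],
    ratio = x$ratio[idx]
  )
}

#' Heatmap of the co-frequency ratios
#'
#' @param object A `pair_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (masked cells blank).
#' @export
autoplot.pair_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(
    drug_a = factor(object$drugs, levels = object$drugs),
    drug_b = factor(object$drugs, levels = object$drugs)
  )
  df$ratio <- as.vector(t(object$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_b, y = .data$drug_a,
                                   fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "D/M") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a pair matrix to CSV files
#'
#' Writes `M.csv`, `D.csv` and `ratio.csv` (drugs as header row and first
#' column; masked ratio cells empty).
#'
#' @param x A `pair_matrix`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pair_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(mat, name) {
    df <- tibble::as_tibble(mat, rownames = "drug")
    readr::write_csv(df, file.path(dir, name), na = "")
  }
  dump(x$M, "M.csv")
  dump(x$D, "D.csv")
  dump(x$ratio, "ratio.csv")
  invisible(dir)
}

#' Odds ratios for symptom given pair exposure
#'
#' Optional finer-grained screen: for each drug pair, the 2x2 odds ratio
#' of symptom occurrence against pair exposure over all category events
#' (with the Haldane-Anscombe 0.5 correction when any cell is zero).
#'
#' @param x A `pair_matrix`.
#' @param n_events Total number of category events (events in the
#'   selection underlying M).
#' @param n_symptom_events Number of those events with the symptom.
#' @return Tibble `drug_a`, `drug_b`, `odds_ratio`.
#' @export
pair_odds_ratio <- function(x, n_events, n_symptom_events) {
  td <- tidy(x)
  or <- mapply(function(m, d) {
    a <- d                       # exposed, symptom
    b <- m - d                   # exposed, no symptom
    c <- n_symptom_events - d    # unexposed, symptom
    dd <- (n_events - m) - c     # unexposed, no symptom
    if (min(a, b, c, dd) < 0) return(NA_real_)
    if (min(a, b, c, dd) == 0) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; dd <- dd + 0.5
    }
    (a * dd) / (b * c)
  }, td$m, td$d)
  dplyr::mutate(dplyr::select(td, "drug_a", "drug_b"), odds_ratio = or)
}
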