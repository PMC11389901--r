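#' Build per-event entity lists for every source
#'
#' Assembles the long per-event entity table the frequency comparison is
#' based on: diagnosis-record entities (the filled ICD columns, which are
#' concept-level by construction and count as 100% normalized), linked
#' medication-order entities, and normalized text mentions (positives
#' only). One row per entity occurrence.
#'
#' @param dpc Tibble from [read_dpc()] / the generator, with `icd_codes`
#'   list-column or `icd_01`..`icd_24` columns.
#' @param linked_mo Tibble from [link_mo_products()].
#' @param text_mentions Tibble of normalized positive mentions (the
#'   `mentions` element of [normalize_corpus()]).
#' @return A tibble with columns `event_id`, `source` (`TABLE_DPC`,
#'   `TABLE_MO`, `TEXT`), `entity_type`, `surface`, `concept_id`, `linked`.
#' @export
build_entity_lists <- function(dpc = NULL, linked_mo = NULL,
                               text_mentions = NULL) {
  parts <- list()
  if (!is.null(dpc) && nrow(dpc) > 0) {
    if (!"icd_codes" %in% names(dpc)) dpc <- dpc_from_wide(dpc)
    parts$dpc <- tidyr::unnest(
      dplyr::select(dpc, "event_id", "icd_codes"),
      "icd_codes"
    ) |>
      dplyr::transmute(
        event_id = .data$event_id, source = "TABLE_DPC",
        entity_type = "disease", surface = .data$icd_codes,
        concept_id = .data$icd_codes, linked = TRUE
      )
  }
  if (!is.null(linked_mo) && nrow(linked_mo) > 0) {
    parts$mo <- dplyr::transmute(
      linked_mo,
      event_id = .data$event_id, source = "TABLE_MO", entity_type = "drug",
      surface = .data$product_name, concept_id = .data$ingredient,
      linked = .data$status == "linked"
    )
  }
  if (!is.null(text_mentions) && nrow(text_mentions) > 0) {
    parts$text <- dplyr::transmute(
      text_mentions,
      event_id = .data$event_id, source = "TEXT",
      entity_type = .data$entity_type, surface = .data$surface,
      concept_id = .data$concept_id, linked = .data$status == "linked"
    )
  }
  if (length(parts) == 0) {
    return(tibble::tibble(event_id = character(0), source = character(0),
                          entity_type = character(0), surface = character(0),
                          concept_id = character(0), linked = logical(0)))
  }
  dplyr::bind_rows(parts)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarise entity lists into a per-source frequency report
#'
#' For every (source, entity type) pair computes the retrieval statistics:
#' number of events containing at least one entity of that type, total
#' entity occurrences, vocabulary size (unique NFKC surfaces), total
#' normalized entities (those linked to a concept), the normalized-entity
#' rate, total distinct concepts, and per-event median/mean/population-sd
#' of entity, normalized-entity, and distinct-concept counts. Events with
#' no entity of a type are excluded from that type's per-event statistics.
#'
#' @param lists Tibble from [build_entity_lists()].
#' @return A tibble with one row per (source, entity_type).
#' @export
summarize_frequency <- function(lists) {
  if (nrow(lists) == 0) {
    abort_bad("no entities to summarise")
  }
  per_event <- lists |>
    dplyr::group_by(.data$source, .data$entity_type, .data$event_id) |>
    dplyr::summarise(
      n_entities = dplyr::n(),
      n_normalized = sum(.data$linked),
      n_concepts = dplyr::n_distinct(.data$concept_id[.data$linked]),
      .groups = "drop"
    )
  totals <- lists |>
    dplyr::group_by(.data$source, .data$entity_type) |>
    dplyr::summarise(
      total_entities = dplyr::n(),
      vocabulary_size = dplyr::n_distinct(canonicalize(.data$surface)),
      total_normalized = sum(.data$linked),
      total_concepts = dplyr::n_distinct(.data$concept_id[.data$linked]),
      .groups = "drop"
    )
  stats <- per_event |>
    dplyr::group_by(.data$source, .data$entity_type) |>
    dplyr::summarise(
      total_events_with_entities = dplyr::n(),
      entities_median = stats::median(.data$n_entities),
      entities_mean = mean(.data$n_entities),
      entities_sd = sd_pop(.data$n_entities),
      normalized_median = stats::median(.data$n_normalized),
      normalized_mean = mean(.data$n_normalized),
      normalized_sd = sd_pop(.data$n_normalized),
      concepts_median = stats::median(.data$n_concepts),
      concepts_mean = mean(.data$n_concepts),
      concepts_sd = sd_pop(.data$n_concepts),
      .groups = "drop"
    )
  dplyr::left_join(totals, stats, by = c("source", "entity_type")) |>
    dplyr::mutate(
      normalized_rate = ifelse(.data$total_entities > 0,
                               .data$total_normalized / .data$total_entities,
                               NA_real_)
    ) |>
    dplyr::relocate("source", "entity_type", "total_events_with_entities",
                    "total_entities", "vocabulary_size", "total_normalized",
                    "normalized_rate", "total_concepts")
}

#' Count entities and concepts shared between two sources
#'
#' Intersects the surface vocabularies (NFKC-normalized) and the concept
#' sets of two sources for one entity type — how much of the same
#' information is retrievable from both.
#'
#' @param lists Tibble from [build_entity_lists()].
#' @param source_a,source_b Source labels to compare.
#' @param entity_type `"disease"` or `"drug"`.
#' @return A tibble with `common_entities` and `common_concepts`.
#' @export
common_counts <- function(lists, source_a, source_b, entity_type) {
  pick <- function(src) lists[lists$source == src &
                                lists$entity_type == entity_type, ]
  a <- pick(source_a)
  b <- pick(source_b)
  tibble::tibble(
    entity_type = entity_type,
    common_entities = length(intersect(canonicalize(a$surface),
                                       canonicalize(b$surface))),
    common_concepts = length(intersect(a$concept_id[a$linked],
                                       b$concept_id[b$linked]))
  )
}

#' Top concepts by normalized-entity frequency
#'
#' Ranks the concepts of one source and entity type by how many normalized
#' entities link to them, descending; ties are broken by concept ID so the
#' ranking is deterministic.
#'
#' @param lists Tibble from [build_entity_lists()].
#' @param source Source label.
#' @param entity_type `"disease"` or `"drug"`.
#' @param k Number of rows to keep (default 20); fewer if the source has
#'   fewer concepts.
#' @param dictionary Optional dictionary tibble supplying `concept_name`
#'   descriptions.
#' @return A tibble with `rank`, `concept_id`, `description`, `frequency`.
#' @export
top_concepts <- function(lists, source, entity_type, k = 20,
                         dictionary = NULL) {
  sub <- lists[lists$source == source & lists$entity_type == entity_type &
                 lists$linked, ]
  out <- sub |>
    dplyr::count(.data$concept_id, name = "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$concept_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  out$description <- if (!is.null(dictionary)) {
    dictionary$concept_name[match(out$concept_id, dictionary$concept_id)]
  } else {
    NA_character_
  }
  dplyr::relocate(out, "rank", "concept_id", "description", "frequency")
}

#' Per-concept frequency pairs for the text-versus-table scatter
#'
#' For every drug concept with normalized entities in both TEXT and the
#' medication orders, returns the two frequencies plus the concept's
#' predominant route of administration (majority vote over its orders;
#' ties resolve to `"injection"`).
#'
#' @param lists Tibble from [build_entity_lists()].
#' @param linked_mo Tibble from [link_mo_products()] (for routes).
#' @return A tibble with `concept_id`, `x` (TEXT frequency), `y` (table
#'   frequency), `route`.
#' @export
freq_scatter <- function(lists, linked_mo) {
  cnt <- function(src) {
    lists[lists$source == src & lists$entity_type == "drug" & lists$linked, ] |>
      dplyr::count(.data$concept_id)
  }
  tx <- cnt("TEXT")
  tb <- cnt("TABLE_MO")
  routes <- linked_mo[linked_mo$status == "linked", ] |>
    dplyr::count(.data$ingredient, .data$route) |>
    dplyr::group_by(.data$ingredient) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$route, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()
  dplyr::inner_join(tx, tb, by = "concept_id", suffix = c("_text", "_table")) |>
    dplyr::transmute(
      concept_id = .data$concept_id,
      x = .data$n_text, y = .data$n_table,
      route = routes$route[match(.data$concept_id, routes$ingredient)]
    )
}

#' Origin-constrained linear regression of table on text frequencies
#'
#' Fits `y = beta * x` through the origin by least squares on the raw
#' counts, per group (typically route of administration). Because the
#' no-intercept model admits two conventions for the coefficient of
#' determination, both are reported: the uncentered form
#' `1 - SS_res / sum(y^2)` (standard for through-origin fits) and the
#' centered form `1 - SS_res / sum((y - mean(y))^2)` (which can leave
#' `[0, 1]` for such fits). Log scaling belongs to the display only.
#'
#' @param data Tibble with numeric columns `x` and `y` (both positive) and
#'   optionally a `group` column (e.g. route).
#' @return An object of class `origin_fit`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods, and
#'   [autoplot.origin_fit()].
#' @examples
#' fit <- origin_regression(data.frame(x = c(1, 2, 3), y = c(2, 4, 6)))
#' glance(fit)  # slope 2, both R-squared 1
#' @export
origin_regression <- function(data) {
  if (!all(c("x", "y") %in% names(data))) abort_bad("`data` needs columns x, y")
  if (!"group" %in% names(data)) data$group <- "all"
  if (any(data$x <= 0 | data$y <= 0)) {
    abort_bad("origin regression expects positive frequencies (log display)")
  }
  fits <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) {
        abort_bad("group `%s` has fewer than 2 points", key$group)
      }
      slope <- sum(d$x * d$y) / sum(d$x^2)
      res <- d$y - slope * d$x
      ss_res <- sum(res^2)
      tibble::tibble(
        group = key$group,
        slope = slope,
        r2_uncentered = 1 - ss_res / sum(d$y^2),
        r2_centered = 1 - ss_res / sum((d$y - mean(d$y))^2),
        nobs = nrow(d)
      )
    }) |>
    dplyr::bind_rows()
  structure(list(coefficients = fits, data = tibble::as_tibble(data)),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("Through-origin regression y = beta * x\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a through-origin regression
#'
#' @param x An `origin_fit`.
#' @param ... Unused.
#' @return One row per group and term (the slope).
#' @export
tidy.origin_fit <- function(x, ...) {
  dplyr::transmute(x$coefficients, group = .data$group, term = "slope",
                   estimate = .data$slope)
}

#' One-row-per-group fit summary of a through-origin regression
#'
#' @param x An `origin_fit`.
#' @param ... Unused.
#' @return Tibble with `group`, `slope`, `r2_uncentered`, `r2_centered`,
#'   `nobs`.
#' @export
glance.origin_fit <- function(x, ...) {
  x$coefficients
}

#' Log-log scatter of the through-origin fit
#'
#' @param object An `origin_fit`.
#' @param ... Unused.
#' @return A ggplot: frequencies on log axes with the fitted lines.
#' @export
autoplot.origin_fit <- function(object, ...) {
  grid <- purrr::pmap_dfr(
    object$coefficients[, c("group", "slope")],
    function(group, slope) {
      d <- object$data[object$data$group == group, ]
      xs <- exp(seq(log(min(d$x)), log(max(d$x)), length.out = 50))
      tibble::tibble(group = group, x = xs, y = slope * xs)
    }
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency in text", y = "frequency in table",
                  colour = NULL)
}
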