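#' Define a target disease for cohort identification
#'
#' A disease is specified by the ICD-10 code prefixes that identify it in
#' coded diagnosis columns and text-derived concepts (prefix semantics
#' cover subcategory codes: prefix `C50` matches `C509`), plus an optional
#' list of ingredient names of medications used only or mainly for that
#' disease (the medication-order route into the cohort). Range notation
#' such as `"E10-14"` expands to `E10, E11, E12, E13, E14` at load time.
#'
#' @param name Disease name.
#' @param icd Character vector of ICD prefixes, ranges allowed.
#' @param drugs Character vector of ingredient names (may be empty, in
#'   which case the medication-order source yields no patients).
#' @return A list of class `disease_spec`.
#' @examples
#' disease_spec("Diabetes", "E10-14")$icd_prefixes
#' @export
disease_spec <- function(name, icd, drugs = character(0)) {
  prefixes <- unlist(lapply(icd, expand_icd_range), use.names = FALSE)
  bad <- !stringr::str_detect(prefixes, "^[A-Z][0-9]{2,4}$")
  if (any(bad)) {
    abort_bad("invalid ICD prefix(es) for %s: %s", name,
              paste(prefixes[bad], collapse = ", "))
  }
  structure(list(name = name, icd_prefixes = prefixes,
                 drug_concepts = as.character(drugs)),
            class = "disease_spec")
}

# "E10-14" -> E10..E14; "I10-15" -> I10..I15. Plain codes pass through.
expand_icd_range <- function(code) {
  code <- stringr::str_trim(code)
  m <- stringr::str_match(code, "^([A-Z])([0-9]+)-([0-9]+)$")
  if (is.na(m[1, 1])) return(code)
  lo <- as.integer(m[1, 3])
  hi <- as.integer(m[1, 4])
  width <- nchar(m[1, 3])
  if (hi < lo) abort_bad("descending ICD range: %s", code)
  paste0(m[1, 2], formatC(lo:hi, width = width, flag = "0"))
}

#' Load disease specifications from a YAML config
#'
#' The file holds a list of entries with fields `name`, `icd` (list of
#' prefixes, ranges allowed) and optional `drugs`. The package bundles a
#' reference config of eight diseases commonly used for cross-source
#' cohort benchmarking at `system.file("extdata", "disease_specs.yaml",
#' package = "rwdminer")` (drug lists empty there — medication lists are
#' site-specific and user-supplied).
#'
#' @param path YAML file path.
#' @return A named list of [disease_spec()] objects.
#' @export
load_disease_specs <- function(path = system.file("extdata", "disease_specs.yaml",
                                                  package = "rwdminer")) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(x) {
    disease_spec(x$name, unlist(x$icd), unlist(x$drugs) %||% character(0))
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

starts_with_any <- function(x, prefixes) {
  if (length(prefixes) == 0 || length(x) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (p in prefixes) hit <- hit | stringr::str_starts(x, stringr::fixed(p))
  hit
}

#' Patients identified from coded diagnosis columns
#'
#' A patient belongs to the cohort iff any ICD code in any of their events'
#' 24 diagnosis columns starts with one of the spec's prefixes.
#'
#' @param dpc Tibble from [read_dpc()] (with `icd_codes` list-column).
#' @param spec A [disease_spec()].
#' @param unit `"patient"` (default) or `"event"` — the identifier
#'   collected.
#' @return Character vector of patient (or event) IDs.
#' @export
patients_from_dpc <- function(dpc, spec, unit = c("patient", "event")) {
  unit <- match.arg(unit)
  if (!"icd_codes" %in% names(dpc)) dpc <- dpc_from_wide(dpc)
  hit <- vapply(dpc$icd_codes, function(v) any(starts_with_any(v, spec$icd_prefixes)),
                logical(1))
  id <- if (unit == "patient") dpc$patient_id else dpc$event_id
  unique(id[hit])
}

#' Patients identified from medication orders
#'
#' A patient belongs to the cohort iff any of their events has an order
#' whose linked ingredient is in the spec's drug list.
#'
#' @param linked_mo Tibble from [link_mo_products()].
#' @param spec A [disease_spec()].
#' @param unit `"patient"` or `"event"`.
#' @return Character vector of IDs.
#' @export
patients_from_mo <- function(linked_mo, spec, unit = c("patient", "event")) {
  unit <- match.arg(unit)
  if (length(spec$drug_concepts) == 0 || nrow(linked_mo) == 0) return(character(0))
  hit <- linked_mo$status == "linked" &
    linked_mo$ingredient %in% spec$drug_concepts
  id <- if (unit == "patient") linked_mo$patient_id else linked_mo$event_id
  unique(id[hit])
}

#' Patients identified from text mentions
#'
#' A patient belongs to the cohort iff any of their events' documents
#' contains a positive disease mention normalized to a concept starting
#' with one of the spec's ICD prefixes. Unlinked and ambiguous mentions
#' never qualify; negated mentions must already have been filtered out.
#'
#' @param text_mentions Tibble of normalized positive mentions with
#'   `patient_id` (join the documents' `patient_id` beforehand if absent).
#' @param spec A [disease_spec()].
#' @param unit `"patient"` or `"event"`.
#' @return Character vector of IDs.
#' @export
patients_from_text <- function(text_mentions, spec,
                               unit = c("patient", "event")) {
  unit <- match.arg(unit)
  if (nrow(text_mentions) == 0) return(character(0))
  hit <- text_mentions$entity_type == "disease" &
    text_mentions$status == "linked" &
    starts_with_any(dplyr::coalesce(text_mentions$concept_id, ""),
                    spec$icd_prefixes)
  id <- if (unit == "patient") text_mentions$patient_id else text_mentions$event_id
  unique(id[hit])
}

#' Exclusive Venn region counts of three sets
#'
#' Computes the cardinality of the seven exclusive regions of a
#' three-circle Venn diagram plus the union size. The regions partition
#' the union, so the seven counts always sum to it.
#'
#' @param a,b,c Vectors (coerced to sets).
#' @param labels Names of the three sets in the output.
#' @return A tibble with `region` (e.g. `"dpc"`, `"dpc&text"`,
#'   `"dpc&mo&text"`, `"union"`) and `n`.
#' @examples
#' venn_counts(c(1, 2), c(2, 3), 3)
#' @export
venn_counts <- function(a, b, c, labels = c("dpc", "mo", "text")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  member <- cbind(u %in% a, u %in% b, u %in% c)
  pat <- c("100", "010", "001", "110", "101", "011", "111")
  region_name <- c(labels[1], labels[2], labels[3],
                   paste(labels[1], labels[2], sep = "&"),
                   paste(labels[1], labels[3], sep = "&"),
                   paste(labels[2], labels[3], sep = "&"),
                   paste(labels, collapse = "&"))
  key <- paste0(member[, 1] + 0L, member[, 2] + 0L, member[, 3] + 0L)
  n <- vapply(pat, function(p) sum(key == p), integer(1))
  tibble::tibble(region = c(region_name, "union"),
                 n = c(unname(n), length(u)))
}

#' Identify a disease cohort from all three sources
#'
#' Runs [patients_from_dpc()], [patients_from_mo()] and
#' [patients_from_text()] for one disease and summarises the overlap as
#' Venn region counts.
#'
#' @param dpc,linked_mo,text_mentions The three aligned, linked sources.
#' @param spec A [disease_spec()].
#' @param unit Counting unit, `"patient"` (default) or `"event"`.
#' @return A list of class `cohort_result` with the three ID sets and the
#'   `venn` tibble.
#' @export
identify_cohort <- function(dpc, linked_mo, text_mentions, spec,
                            unit = c("patient", "event")) {
  unit <- match.arg(unit)
  sets <- list(
    dpc = patients_from_dpc(dpc, spec, unit),
    mo = patients_from_mo(linked_mo, spec, unit),
    text = patients_from_text(text_mentions, spec, unit)
  )
  structure(
    list(name = spec$name, unit = unit, sets = sets,
         venn = venn_counts(sets$dpc, sets$mo, sets$text)),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$name, " (unit: ", x$unit, ")\n", sep = "")
  print(x$venn)
  invisible(x)
}

#' Tidy Venn regions of a cohort result
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return The `venn` tibble with the disease name prepended.
#' @export
tidy.cohort_result <- function(x, ...) {
  dplyr::mutate(x$venn, disease = x$name, .before = 1)
}
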