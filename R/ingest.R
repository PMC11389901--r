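#' Read diagnosis (DPC-style) records
#'
#' Parses a tab-separated table with one row per hospitalization event:
#' `event_id`, `patient_id`, and 24 ICD columns `icd_01` .. `icd_24` filled
#' left to right (blank cells allowed). Codes must be ICD-10-shaped (a
#' letter, 2-3 digits, optional subcategory digit).
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble with columns `event_id`, `patient_id`, `icd_codes`
#'   (list-column of character vectors, blank cells dropped, order
#'   preserved) plus any extra columns passed through.
#' @export
read_dpc <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  dpc_from_wide(raw)
}

# Shared by read_dpc() and the in-memory pipeline: wide 24-column layout to
# a list-column of codes, with row-level validation.
dpc_from_wide <- function(raw) {
  raw <- tibble::as_tibble(raw)
  icd_cols <- grep("^icd_[0-9]{2}$", names(raw), value = TRUE)
  if (!"event_id" %in% names(raw)) abort_bad("DPC table lacks an `event_id` column")
  if (length(icd_cols) == 0) abort_bad("DPC table lacks icd_01..icd_24 columns")
  if (anyNA(raw$event_id) || any(!nzchar(raw$event_id))) {
    abort_bad("missing event_id in DPC rows: %s",
              paste(which(is.na(raw$event_id) | !nzchar(raw$event_id)),
                    collapse = ", "))
  }
  codes <- lapply(seq_len(nrow(raw)), function(i) {
    v <- as.character(raw[i, icd_cols])
    v[!is.na(v) & nzchar(v)]
  })
  bad <- which(vapply(codes, function(v) any(!is_icd_shaped(v)), logical(1)))
  if (length(bad) > 0) {
    abort_bad("malformed ICD code(s) in DPC rows: %s",
              paste(bad, collapse = ", "))
  }
  out <- raw[setdiff(names(raw), icd_cols)]
  out$icd_codes <- codes
  dplyr::relocate(out, "event_id", "icd_codes")
}

#' Read medication-order records
#'
#' Parses a tab-separated table with one row per order: `event_id`,
#' `product_name`, and `route` (`"oral"` or `"injection"`); other columns
#' (amount, dates, patient IDs) are passed through untouched.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble of orders.
#' @export
read_mo <- function(path) {
  mo <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("event_id", "product_name", "route")
  miss <- setdiff(need, names(mo))
  if (length(miss) > 0) {
    abort_bad("MO table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(mo$route), c("oral", "injection"))
  if (length(bad) > 0) {
    abort_bad("unknown route value(s): %s (expected \"oral\" or \"injection\")",
              paste(bad, collapse = ", "))
  }
  if (anyNA(mo$event_id) || any(!nzchar(mo$event_id))) {
    abort_bad("missing event_id in MO rows: %s",
              paste(which(is.na(mo$event_id) | !nzchar(mo$event_id)),
                    collapse = ", "))
  }
  mo
}

#' Read discharge-summary documents
#'
#' Parses a JSONL file (one object per line) with fields `doc_id`,
#' `event_id`, `patient_id` and `text`.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return A tibble of documents; zero rows for an empty file.
#' @export
read_documents <- function(path) {
  docs <- read_jsonl(path)
  if (nrow(docs) == 0) {
    return(tibble::tibble(doc_id = character(0), event_id = character(0),
                          patient_id = character(0), text = character(0)))
  }
  need <- c("doc_id", "event_id", "text")
  miss <- setdiff(need, names(docs))
  if (length(miss) > 0) {
    abort_bad("documents lack field(s): %s", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(docs$event_id))) abort_bad("document with empty event_id")
  if (!"patient_id" %in% names(docs)) docs$patient_id <- NA_character_
  docs
}

#' Align structured tables and documents on event IDs
#'
#' Retains only events that have both a diagnosis record and a document
#' (intersection semantics); medication orders outside retained events are
#' dropped. When an event carries several documents they are concatenated
#' in `doc_id` order (separated by a newline) and flagged. Patient IDs are
#' taken from the diagnosis side on conflict (the administrative source of
#' record), and conflicts are reported.
#'
#' @param dpc Tibble from [read_dpc()] (one row per event).
#' @param mo Tibble from [read_mo()].
#' @param docs Tibble from [read_documents()].
#' @return A list of class `aligned_corpus`: `events` (character vector of
#'   retained event IDs), `dpc`, `mo`, `documents` (restricted to retained
#'   events), `patients` (retained patient IDs), and `drop_report` (counts
#'   of events and orders dropped on each side).
#' @export
align_corpus <- function(dpc, mo, docs) {
  if (anyDuplicated(dpc$event_id)) {
    abort_bad("duplicate event_id in DPC (one diagnosis record = one event): %s",
              paste(unique(dpc$event_id[duplicated(dpc$event_id)]), collapse = ", "))
  }
  table_events <- unique(dpc$event_id)
  text_events <- unique(docs$event_id)
  events <- intersect(table_events, text_events)
  if (length(events) == 0) {
    warning("no events shared between tables and documents; corpus is empty",
            call. = FALSE)
  }

  multi <- FALSE
  docs_kept <- docs[docs$event_id %in% events, , drop = FALSE]
  if (anyDuplicated(docs_kept$event_id)) {
    multi <- TRUE
    docs_kept <- docs_kept |>
      dplyr::arrange(.data$doc_id) |>
      dplyr::group_by(.data$event_id) |>
      dplyr::summarise(
        doc_id = dplyr::first(.data$doc_id),
        patient_id = dplyr::first(.data$patient_id),
        text = paste(.data$text, collapse = "\n"),
        n_docs = dplyr::n(),
        .groups = "drop"
      )
  } else {
    docs_kept$n_docs <- 1L
  }

  dpc_kept <- dpc[dpc$event_id %in% events, , drop = FALSE]
  mo_kept <- mo[mo$event_id %in% events, , drop = FALSE]

  # DPC is authoritative for the patient; document disagreements are logged.
  pat_map <- stats::setNames(dpc_kept$patient_id, dpc_kept$event_id)
  doc_pat <- docs_kept$patient_id
  dpc_pat <- unname(pat_map[docs_kept$event_id])
  n_conflict <- sum(!is.na(doc_pat) & doc_pat != dpc_pat)
  if (n_conflict > 0) {
    message(n_conflict, " document(s) disagreed with DPC on patient_id; ",
            "DPC side kept")
  }
  docs_kept$patient_id <- dpc_pat

  structure(
    list(
      events = events,
      dpc = dpc_kept,
      mo = mo_kept,
      documents = docs_kept[order(docs_kept$event_id), , drop = FALSE],
      patients = unique(dpc_kept$patient_id),
      drop_report = list(
        table_events = length(table_events),
        text_events = length(text_events),
        aligned_events = length(events),
        dropped_table_events = length(setdiff(table_events, events)),
        dropped_text_events = length(setdiff(text_events, events)),
        dropped_mo_orders = nrow(mo) - nrow(mo_kept),
        patient_id_conflicts = n_conflict,
        multi_document_events = multi
      )
    ),
    class = "aligned_corpus"
  )
}

#' @export
print.aligned_corpus <- function(x, ...) {
  r <- x$drop_report
  cat("<aligned_corpus>\n")
  cat("  events:  ", r$aligned_events, " (table ", r$table_events,
      ", text ", r$text_events, ")\n", sep = "")
  cat("  patients:", length(x$patients), "\n")
  cat("  orders:  ", nrow(x$mo), " (", r$dropped_mo_orders, " dropped)\n",
      sep = "")
  invisible(x)
}
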