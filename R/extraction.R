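# Tagging operates in NFKC space: full-width/half-width variants unify and
# Latin letters are case-folded, so spans refer to the normalized text.
nfkc_fold <- function(x) {
  chartr(paste(LETTERS, collapse = ""), paste(letters, collapse = ""),
         stringi::stri_trans_nfkc(x))
}

empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(0), event_id = character(0),
    start = integer(0), end = integer(0), surface = character(0),
    entity_type = character(0), factuality = character(0)
  )
}

#' Tag disease and drug mentions with a dictionary scanner
#'
#' Deterministic reference tagger: scans each document's NFKC-normalized
#' text left to right against the union of dictionary surfaces, keeping
#' non-overlapping longest matches. Ties on length are broken by leftmost
#' start, then disease before drug. Every mention starts out `positive`;
#' run [detect_negation()] to assign factuality. Spans are 0-based
#' half-open character intervals into the NFKC-normalized text.
#'
#' In production the tagger is typically replaced by the output of an
#' external clinical NER model via [import_annotations()]; this scanner
#' keeps the pipeline runnable and exactly testable without model weights.
#'
#' @param docs Tibble of documents (`doc_id`, `event_id`, `text`).
#' @param dictionaries List with tibbles `disease` and `drug`, each with a
#'   `surface` column (as from [generate_dictionaries()] or
#'   [read_dictionary()]).
#' @return A tibble of mentions: `doc_id`, `event_id`, `start`, `end`,
#'   `surface`, `entity_type`, `factuality`.
#' @export
tag_entities <- function(docs, dictionaries) {
  surf_tbl <- dplyr::bind_rows(
    tibble::tibble(surface = unique(nfkc_fold(dictionaries$disease$surface)),
                   entity_type = "disease"),
    tibble::tibble(surface = unique(nfkc_fold(dictionaries$drug$surface)),
                   entity_type = "drug")
  ) |> dplyr::distinct(.data$surface, .data$entity_type)

  out <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    text <- nfkc_fold(docs$text[i])
    hits <- stringi::stri_locate_all_fixed(text, surf_tbl$surface)
    n_hit <- vapply(hits, function(m) sum(!is.na(m[, 1])), integer(1))
    if (sum(n_hit) == 0) next
    idx <- rep(seq_along(hits), n_hit)
    loc <- do.call(rbind, hits[n_hit > 0])
    cand <- tibble::tibble(
      start = loc[, 1] - 1L,           # to 0-based half-open
      end = loc[, 2],
      surface = surf_tbl$surface[idx],
      entity_type = surf_tbl$entity_type[idx]
    )
    # left-to-right greedy: leftmost start, longest span, disease first
    cand <- cand[order(cand$start, -(cand$end - cand$start),
                       cand$entity_type != "disease"), , drop = FALSE]
    keep <- logical(nrow(cand))
    cur_end <- 0L
    for (j in seq_len(nrow(cand))) {
      if (cand$start[j] >= cur_end) {
        keep[j] <- TRUE
        cur_end <- cand$end[j]
      }
    }
    sel <- cand[keep, , drop = FALSE]
    out[[i]] <- tibble::tibble(
      doc_id = docs$doc_id[i], event_id = docs$event_id[i],
      start = as.integer(sel$start), end = as.integer(sel$end),
      surface = sel$surface, entity_type = sel$entity_type,
      factuality = "positive"
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_mentions() else res
}

#' Assign factuality to mentions with a cue-window negation rule
#'
#' A mention is `negated` iff a cue string starts within `window` characters
#' after the mention's end, or ends immediately before its start (at most
#' one separator character); otherwise it is `positive`. This deterministic
#' convention mirrors clinical negation scoping ("<disease> was not found")
#' closely enough for retrieval comparison while staying exactly testable.
#'
#' @param docs Tibble of documents the mentions point into.
#' @param mentions Tibble from [tag_entities()] or [import_annotations()].
#' @param cues Character vector of negation cue strings.
#' @param window Maximum distance (characters) between a mention's end and
#'   a following cue's start for the cue to scope over the mention.
#' @return `mentions` with `factuality` set.
#' @export
detect_negation <- function(docs, mentions,
                            cues = c("NEGNOTFOUND", "NEGDENIED", "NEGRULEDOUT"),
                            window = 12L) {
  if (nrow(mentions) == 0) return(mentions)
  cues <- nfkc_fold(cues)
  cue_locs <- lapply(seq_len(nrow(docs)), function(i) {
    text <- nfkc_fold(docs$text[i])
    loc <- stringi::stri_locate_all_fixed(text, cues)
    loc <- do.call(rbind, loc)
    loc <- loc[!is.na(loc[, 1]), , drop = FALSE]
    cbind(start = loc[, 1] - 1L, end = loc[, 2])  # 0-based half-open
  })
  names(cue_locs) <- docs$doc_id

  fact <- vapply(seq_len(nrow(mentions)), function(j) {
    cl <- cue_locs[[mentions$doc_id[j]]]
    if (is.null(cl) || nrow(cl) == 0) return("positive")
    s <- mentions$start[j]; e <- mentions$end[j]
    after <- cl[, "start"] >= e & (cl[, "start"] - e) <= window
    before <- cl[, "end"] <= s & (s - cl[, "end"]) <= 1L
    if (any(after | before)) "negated" else "positive"
  }, character(1))
  mentions$factuality <- fact
  mentions
}

#' Drop negated mentions
#'
#' Keeps exactly the positive mentions. The number of removed mentions per
#' entity type is attached as the `"removed"` attribute, so the partition
#' positive + negated = all is auditable.
#'
#' @param mentions Tibble with a `factuality` column.
#' @return The positive mentions, with attribute `removed` (named integer
#'   vector of negated counts per entity type).
#' @export
filter_negated <- function(mentions) {
  neg <- mentions[mentions$factuality == "negated", , drop = FALSE]
  pos <- mentions[mentions$factuality == "positive", , drop = FALSE]
  removed <- table(factor(neg$entity_type, levels = c("disease", "drug")))
  attr(pos, "removed") <- stats::setNames(as.integer(removed), names(removed))
  pos
}

#' Import externally produced mention annotations
#'
#' Adapter for clinical NER output: reads a JSONL file with fields
#' `doc_id`, `start`, `end`, `type` (or `entity_type`) and `factuality`
#' (optional fields `event_id`, `surface`). When `docs` is supplied, spans
#' are bounds-checked against the documents and `surface`/`event_id` are
#' filled in from the text.
#'
#' @param path JSONL file of annotations.
#' @param docs Optional tibble of documents for span validation.
#' @return A tibble of mentions in the same shape as [tag_entities()].
#' @export
import_annotations <- function(path, docs = NULL) {
  ann <- read_jsonl(path)
  if (nrow(ann) == 0) return(empty_mentions())
  if ("type" %in% names(ann) && !"entity_type" %in% names(ann)) {
    ann <- dplyr::rename(ann, entity_type = "type")
  }
  need <- c("doc_id", "start", "end", "entity_type")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    abort_bad("annotations lack field(s): %s", paste(miss, collapse = ", "))
  }
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  bad <- ann$start < 0 | ann$start >= ann$end
  if (any(bad)) {
    abort_bad("invalid span (start >= end or negative) at line(s): %s",
              paste(which(bad), collapse = ", "))
  }
  known <- ann$entity_type %in% c("disease", "drug")
  if (any(!known)) {
    warning(sum(!known), " annotation(s) with unknown entity type skipped: ",
            paste(unique(ann$entity_type[!known]), collapse = ", "),
            call. = FALSE)
    ann <- ann[known, , drop = FALSE]
  }
  if (!"factuality" %in% names(ann)) ann$factuality <- "positive"
  if (!is.null(docs)) {
    m <- match(ann$doc_id, docs$doc_id)
    if (anyNA(m)) {
      abort_bad("annotation references unknown doc_id: %s",
                paste(unique(ann$doc_id[is.na(m)]), collapse = ", "))
    }
    text <- nfkc_fold(docs$text)[m]
    oob <- ann$end > nchar(text)
    if (any(oob)) {
      abort_bad("span out of bounds in doc(s): %s",
                paste(unique(ann$doc_id[oob]), collapse = ", "))
    }
    ann$event_id <- docs$event_id[m]
    ann$surface <- substr(text, ann$start + 1L, ann$end)
  }
  if (!"event_id" %in% names(ann)) ann$event_id <- NA_character_
  if (!"surface" %in% names(ann)) ann$surface <- NA_character_
  dplyr::select(ann, "doc_id", "event_id", "start", "end", "surface",
                "entity_type", "factuality")
}

#' Write mentions to a JSONL file
#'
#' One object per line with fields `doc_id`, `event_id`, `start`, `end`,
#' `surface`, `type`, `factuality` — the same layout [import_annotations()]
#' reads, so export followed by import is the identity.
#'
#' @param mentions Tibble of mentions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  out <- dplyr::select(mentions, "doc_id", "event_id", "start", "end",
                       "surface", type = "entity_type", "factuality")
  write_jsonl(out, path)
}
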