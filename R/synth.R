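#' Configuration for the synthetic EHR generator
#'
#' Bundles every knob of the synthetic electronic-health-record corpus:
#' patient/event counts, dictionary sizes, and the probabilities that shape
#' the planted text mentions. Identical configurations (including `seed`)
#' always regenerate byte-identical corpora.
#'
#' @param seed Integer RNG seed; the generator derives one sub-seed per
#'   stage from it so the stages can also be called individually.
#' @param n_patients Number of patients (>= 1).
#' @param events_per_patient_mean Mean of the zero-truncated Poisson draw of
#'   hospitalization events per patient (every patient has at least one
#'   discharge).
#' @param n_disease_concepts,n_drug_concepts Number of distinct disease
#'   concepts (ICD-10-shaped codes) and drug ingredients.
#' @param surfaces_per_concept Dictionary surface forms per concept (>= 1).
#' @param p_negated Probability a planted mention is negated (wrapped with a
#'   negation cue immediately after its surface).
#' @param p_surface_perturb Probability a planted in-dictionary surface
#'   receives exactly one random character edit
#'   (insertion/deletion/substitution).
#' @param p_out_of_dictionary Probability a planted mention uses a surface
#'   absent from every dictionary (no true concept).
#' @param mentions_per_doc_mean Poisson mean of planted mentions per
#'   document.
#' @param orders_per_event_mean Poisson mean of medication orders per event
#'   (may be 0).
#' @param p_injection Probability an order's route is `"injection"`
#'   (otherwise `"oral"`).
#' @param ade_flag_density Per-flag Bernoulli probability that a disease
#'   dictionary entry is marked relevant to one of the 7 tracked adverse
#'   drug effects.
#' @param dx_per_event_mean Zero-truncated Poisson mean of filled ICD
#'   columns per diagnosis record (capped at the 24 available columns).
#' @param p_ambiguous Fraction of dictionary surfaces additionally mapped to
#'   a second concept, to exercise the ambiguity-exclusion rule of the
#'   normalizer.
#' @param p_echo Probability a planted mention's concept is drawn from the
#'   event's own structured record (diagnosis codes / ordered ingredients)
#'   rather than uniformly, which creates realistic overlap between the
#'   three sources.
#' @param negation_cues Character vector of cue strings the generator
#'   appends after negated mentions; the extraction stage must be run with
#'   the same list.
#' @param n_ade_flags Number of binary adverse-effect relevance flags per
#'   dictionary entry.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 100L,
                         events_per_patient_mean = 3.12,
                         n_disease_concepts = 50L,
                         n_drug_concepts = 30L,
                         surfaces_per_concept = 3L,
                         p_negated = 0.1,
                         p_surface_perturb = 0.1,
                         p_out_of_dictionary = 0.1,
                         mentions_per_doc_mean = 20,
                         orders_per_event_mean = 8,
                         p_injection = 0.5,
                         ade_flag_density = 0.1,
                         dx_per_event_mean = 4,
                         p_ambiguous = 0,
                         p_echo = 0.5,
                         negation_cues = c("NEGNOTFOUND", "NEGDENIED", "NEGRULEDOUT"),
                         n_ade_flags = 7L) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    events_per_patient_mean = events_per_patient_mean,
    n_disease_concepts = as.integer(n_disease_concepts),
    n_drug_concepts = as.integer(n_drug_concepts),
    surfaces_per_concept = as.integer(surfaces_per_concept),
    p_negated = p_negated,
    p_surface_perturb = p_surface_perturb,
    p_out_of_dictionary = p_out_of_dictionary,
    mentions_per_doc_mean = mentions_per_doc_mean,
    orders_per_event_mean = orders_per_event_mean,
    p_injection = p_injection,
    ade_flag_density = ade_flag_density,
    dx_per_event_mean = dx_per_event_mean,
    p_ambiguous = p_ambiguous,
    p_echo = p_echo,
    negation_cues = as.character(negation_cues),
    n_ade_flags = as.integer(n_ade_flags)
  )
  probs <- c("p_negated", "p_surface_perturb", "p_out_of_dictionary",
             "p_injection", "ade_flag_density", "p_ambiguous", "p_echo")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort_bad("`%s` must be a probability in [0, 1], got %s", p, cfg[[p]])
    }
  }
  counts <- c("n_patients", "n_disease_concepts", "n_drug_concepts",
              "surfaces_per_concept", "n_ade_flags")
  for (k in counts) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L) {
      abort_bad("`%s` must be an integer >= 1", k)
    }
  }
  if (cfg$events_per_patient_mean <= 0) {
    abort_bad("`events_per_patient_mean` must be positive")
  }
  if (cfg$dx_per_event_mean <= 0) abort_bad("`dx_per_event_mean` must be positive")
  if (cfg$mentions_per_doc_mean < 0) abort_bad("`mentions_per_doc_mean` must be >= 0")
  if (cfg$orders_per_event_mean < 0) abort_bad("`orders_per_event_mean` must be >= 0")
  if (length(cfg$negation_cues) < 1) abort_bad("at least one negation cue is required")
  structure(cfg, class = "synth_config")
}

# Stage-specific sub-seed, kept well below .Machine$integer.max.
stage_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

# Unique ICD-10-shaped codes: a letter, two digits, and (for half of them) a
# subcategory digit — the prefix structure cohort identification relies on.
make_icd_codes <- function(n) {
  codes <- character(0)
  while (length(codes) < n) {
    base <- paste0(
      sample(LETTERS, n, replace = TRUE),
      sprintf("%02d", sample(0:99, n, replace = TRUE))
    )
    sub <- stats::runif(n) < 0.5
    cand <- ifelse(sub, paste0(base, sample(0:9, n, replace = TRUE)), base)
    codes <- unique(c(codes, cand))
  }
  codes[seq_len(n)]
}

# Surfaces that neither contain nor are contained in any already accepted
# surface, so the longest-match tagger recovers plants exactly.
make_surfaces <- function(n, existing = character(0)) {
  out <- character(0)
  pool <- c(existing)
  while (length(out) < n) {
    cand <- unique(rand_lower(n - length(out)))
    for (s in cand) {
      if (length(pool) == 0 ||
          (!any(stringi::stri_detect_fixed(s, pool)) &&
           !any(stringi::stri_detect_fixed(pool, s)))) {
        out <- c(out, s)
        pool <- c(pool, s)
      }
    }
  }
  out
}

#' Generate synthetic disease and drug dictionaries
#'
#' Disease entries map surface forms to ICD-10-shaped concept codes and
#' carry binary adverse-effect relevance flags; drug entries map product
#' names to pharmaceutical ingredient concepts (flags all zero). A fraction
#' `p_ambiguous` of surfaces is additionally attached to a second concept to
#' exercise the normalizer's ambiguity exclusion.
#'
#' @param cfg A [synth_config()].
#' @return A list with tibbles `disease` and `drug`, each with columns
#'   `surface`, `concept_id`, `concept_name`, `flag_1` .. `flag_<n>`.
#' @export
generate_dictionaries <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 0L))

  build <- function(concept_ids, concept_names, existing, flag_density) {
    n_surf <- length(concept_ids) * cfg$surfaces_per_concept
    surfaces <- make_surfaces(n_surf, existing)
    d <- tibble::tibble(
      surface = surfaces,
      concept_id = rep(concept_ids, each = cfg$surfaces_per_concept),
      concept_name = rep(concept_names, each = cfg$surfaces_per_concept)
    )
    n_amb <- floor(cfg$p_ambiguous * nrow(d))
    if (n_amb > 0 && length(concept_ids) > 1) {
      idx <- sample(nrow(d), n_amb)
      extra <- d[idx, ]
      shift <- vapply(extra$concept_id, function(cid) {
        sample(setdiff(concept_ids, cid), 1)
      }, character(1))
      extra$concept_id <- shift
      extra$concept_name <- concept_names[match(shift, concept_ids)]
      d <- dplyr::bind_rows(d, extra)
    }
    flags <- matrix(
      stats::rbinom(nrow(d) * cfg$n_ade_flags, 1L, flag_density),
      nrow = nrow(d)
    )
    colnames(flags) <- paste0("flag_", seq_len(cfg$n_ade_flags))
    dplyr::bind_cols(d, tibble::as_tibble(flags))
  }

  icd <- make_icd_codes(cfg$n_disease_concepts)
  disease <- build(icd, paste0("disease ", icd), character(0), cfg$ade_flag_density)

  ingredients <- paste0("ing-", make_surfaces(cfg$n_drug_concepts, disease$surface))
  drug <- build(ingredients, ingredients,
                c(disease$surface, sub("^ing-", "", ingredients)), 0)
  list(disease = disease, drug = drug)
}

#' Generate synthetic structured tables (diagnosis records and orders)
#'
#' One diagnosis (DPC-style) row per hospitalization event, with up to 24
#' ICD columns filled left to right, and zero or more medication-order rows
#' per event with a product name drawn from the drug dictionary and a route.
#'
#' @param cfg A [synth_config()].
#' @param dictionaries Output of [generate_dictionaries()].
#' @return A list with tibbles `dpc` (`event_id`, `patient_id`,
#'   `icd_01`..`icd_24`) and `mo` (`event_id`, `patient_id`,
#'   `product_name`, `route`, `amount`).
#' @export
generate_tables <- function(cfg, dictionaries) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(dictionaries$disease) == 0 || nrow(dictionaries$drug) == 0) {
    abort_bad("dictionaries must be non-empty")
  }
  set.seed(stage_seed(cfg, 1L))

  n_ev_per_pat <- rtpois(cfg$n_patients, cfg$events_per_patient_mean)
  patient_id <- rep(sprintf("P%05d", seq_len(cfg$n_patients)), n_ev_per_pat)
  n_events <- length(patient_id)
  event_id <- sprintf("E%06d", seq_len(n_events))

  disease_concepts <- unique(dictionaries$disease$concept_id)
  drug_concepts <- unique(dictionaries$drug$concept_id)

  n_dx <- pmin(rtpois(n_events, cfg$dx_per_event_mean), 24L,
               length(disease_concepts))
  icd_mat <- matrix("", nrow = n_events, ncol = 24L,
                    dimnames = list(NULL, sprintf("icd_%02d", 1:24)))
  for (i in seq_len(n_events)) {
    icd_mat[i, seq_len(n_dx[i])] <- sample(disease_concepts, n_dx[i])
  }
  dpc <- dplyr::bind_cols(
    tibble::tibble(event_id = event_id, patient_id = patient_id),
    tibble::as_tibble(icd_mat)
  )

  n_ord <- stats::rpois(n_events, cfg$orders_per_event_mean)
  ev_rep <- rep(seq_len(n_events), n_ord)
  n_mo <- length(ev_rep)
  if (n_mo > 0) {
    concept <- sample(drug_concepts, n_mo, replace = TRUE)
    product_name <- vapply(concept, function(cid) {
      surf <- dictionaries$drug$surface[dictionaries$drug$concept_id == cid]
      if (length(surf) == 1) surf else sample(surf, 1)
    }, character(1), USE.NAMES = FALSE)
    mo <- tibble::tibble(
      event_id = event_id[ev_rep],
      patient_id = patient_id[ev_rep],
      product_name = product_name,
      route = ifelse(stats::runif(n_mo) < cfg$p_injection, "injection", "oral"),
      amount = sample(1:5, n_mo, replace = TRUE)
    )
  } else {
    mo <- tibble::tibble(
      event_id = character(0), patient_id = character(0),
      product_name = character(0), route = character(0), amount = integer(0)
    )
  }
  list(dpc = dpc, mo = mo)
}

# One random character edit (insert/delete/substitute) on a lowercase
# string; always returns a string different from the input.
perturb_surface <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  op <- sample(c("ins", "del", "sub"), 1)
  if (op == "del" && n > 2) {
    ch <- ch[-sample(n, 1)]
  } else if (op == "ins") {
    pos <- sample(0:n, 1)
    ch <- append(ch, sample(letters, 1), after = pos)
  } else {
    pos <- sample(n, 1)
    old <- ch[pos]
    ch[pos] <- sample(setdiff(letters, old), 1)
  }
  out <- paste(ch, collapse = "")
  if (identical(out, s)) perturb_surface(s) else out
}

#' Generate synthetic discharge-summary documents with exact ground truth
#'
#' Emits one document per event: digit-string filler tokens interleaved
#' with planted disease/drug mention surfaces. Negated mentions carry a
#' negation cue token immediately after the surface; perturbed surfaces
#' receive exactly one character edit; out-of-dictionary mentions use
#' surfaces absent from every dictionary. Ground truth records every plant
#' with its character span, factuality and true concept.
#'
#' @param cfg A [synth_config()].
#' @param dictionaries Output of [generate_dictionaries()].
#' @param tables Output of [generate_tables()].
#' @return A list with tibbles `documents` (`doc_id`, `event_id`,
#'   `patient_id`, `text`) and `ground_truth` (`doc_id`, `event_id`,
#'   `patient_id`, `start`, `end`, `surface`, `entity_type`, `factuality`,
#'   `true_concept_id`; spans are 0-based half-open).
#' @export
generate_documents <- function(cfg, dictionaries, tables) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg, 2L))

  dpc <- tables$dpc
  mo <- tables$mo
  all_surfaces <- c(dictionaries$disease$surface, dictionaries$drug$surface)
  disease_concepts <- unique(dictionaries$disease$concept_id)
  drug_concepts <- unique(dictionaries$drug$concept_id)
  mo_by_event <- split(mo$product_name, mo$event_id)

  surf_of <- function(dict, cid) {
    s <- dict$surface[dict$concept_id == cid]
    if (length(s) == 1) s else sample(s, 1)
  }

  docs <- vector("list", nrow(dpc))
  gts <- vector("list", nrow(dpc))
  icd_cols <- as.matrix(dpc[, sprintf("icd_%02d", 1:24)])

  for (i in seq_len(nrow(dpc))) {
    ev <- dpc$event_id[i]
    pat <- dpc$patient_id[i]
    n_m <- stats::rpois(1, cfg$mentions_per_doc_mean)

    tokens <- rand_filler(1)
    pos <- nchar(tokens)  # running length of text built so far
    text <- tokens
    gt_rows <- list()

    ev_dx <- unname(icd_cols[i, ])
    ev_dx <- ev_dx[nzchar(ev_dx)]
    ev_drugs <- mo_by_event[[ev]]
    ev_ing <- if (is.null(ev_drugs)) character(0) else {
      unique(dictionaries$drug$concept_id[
        match(ev_drugs, dictionaries$drug$surface)])
    }

    for (m in seq_len(n_m)) {
      type <- if (stats::runif(1) < 0.6) "disease" else "drug"
      ood <- stats::runif(1) < cfg$p_out_of_dictionary
      if (ood) {
        surface <- make_surfaces(1, all_surfaces)
        concept <- NA_character_
      } else {
        own <- if (type == "disease") ev_dx else ev_ing
        concept <- if (length(own) > 0 && stats::runif(1) < cfg$p_echo) {
          if (length(own) == 1) own else sample(own, 1)
        } else {
          pool <- if (type == "disease") disease_concepts else drug_concepts
          if (length(pool) == 1) pool else sample(pool, 1)
        }
        dict <- if (type == "disease") dictionaries$disease else dictionaries$drug
        surface <- surf_of(dict, concept)
        if (stats::runif(1) < cfg$p_surface_perturb) {
          surface <- perturb_surface(surface)
        }
      }
      negated <- stats::runif(1) < cfg$p_negated

      start <- pos + 1L  # the joining space
      text <- paste(text, surface)
      pos <- pos + 1L + nchar(surface)
      gt_rows[[m]] <- tibble::tibble(
        doc_id = paste0("N", ev), event_id = ev, patient_id = pat,
        start = start, end = pos, surface = surface, entity_type = type,
        factuality = if (negated) "negated" else "positive",
        true_concept_id = concept
      )
      if (negated) {
        cue <- if (length(cfg$negation_cues) == 1) cfg$negation_cues else {
          sample(cfg$negation_cues, 1)
        }
        text <- paste(text, cue)
        pos <- pos + 1L + nchar(cue)
      }
      filler <- rand_filler(1)
      text <- paste(text, filler)
      pos <- pos + 1L + nchar(filler)
    }

    docs[[i]] <- tibble::tibble(
      doc_id = paste0("N", ev), event_id = ev, patient_id = pat, text = text
    )
    if (n_m > 0) gts[[i]] <- dplyr::bind_rows(gt_rows)
  }

  documents <- dplyr::bind_rows(docs)
  ground_truth <- dplyr::bind_rows(gts)
  if (nrow(ground_truth) == 0) {
    ground_truth <- tibble::tibble(
      doc_id = character(0), event_id = character(0), patient_id = character(0),
      start = integer(0), end = integer(0), surface = character(0),
      entity_type = character(0), factuality = character(0),
      true_concept_id = character(0)
    )
  }
  list(documents = documents, ground_truth = ground_truth)
}

#' Simulate a complete synthetic EHR corpus
#'
#' Runs the three generator stages (dictionaries, structured tables,
#' documents + ground truth) under the configuration's seed.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `ehr_sim` with elements `config`, `disease_dict`,
#'   `drug_dict`, `dpc`, `mo`, `documents`, `ground_truth`.
#' @examples
#' sim <- simulate_ehr(synth_config(seed = 7, n_patients = 5))
#' nrow(sim$dpc)  # one row per hospitalization event
#' @export
simulate_ehr <- function(cfg = synth_config()) {
  dicts <- generate_dictionaries(cfg)
  tables <- generate_tables(cfg, dicts)
  docs <- generate_documents(cfg, dicts, tables)
  structure(
    list(config = cfg,
         disease_dict = dicts$disease, drug_dict = dicts$drug,
         dpc = tables$dpc, mo = tables$mo,
         documents = docs$documents, ground_truth = docs$ground_truth),
    class = "ehr_sim"
  )
}

#' Write a simulated corpus to disk
#'
#' Writes `dpc.tsv`, `mo.tsv`, `docs.jsonl`, `disease_dict.tsv`,
#' `drug_dict.tsv` and `ground_truth.jsonl` (UTF-8, tab-separated tables
#' with a header row; one JSON object per line for the JSONL files).
#'
#' @param sim An `ehr_sim` from [simulate_ehr()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ehr_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ehr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$dpc, file.path(dir, "dpc.tsv"))
  readr::write_tsv(sim$mo, file.path(dir, "mo.tsv"))
  readr::write_tsv(sim$disease_dict, file.path(dir, "disease_dict.tsv"))
  readr::write_tsv(sim$drug_dict, file.path(dir, "drug_dict.tsv"))
  write_jsonl(sim$documents, file.path(dir, "docs.jsonl"))
  write_jsonl(sim$ground_truth, file.path(dir, "ground_truth.jsonl"))
  invisible(dir)
}

# One JSON object per line (NDJSON), stable key order, no rounding.
write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df) > 0) {
    jsonlite::stream_out(as.data.frame(df), con, verbose = FALSE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

read_jsonl <- function(path) {
  if (file.size(path) == 0) return(tibble::tibble())
  con <- file(path, open = "rb")
  on.exit(close(con))
  tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
}
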