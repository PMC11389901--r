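# Stage orchestration: each run_* function reads its inputs from `dir`,
# writes its artifacts back into `dir`, and appends a stage entry to
# manifest.json so a run directory is self-describing and reproducible.

#' Assemble a pipeline run configuration
#'
#' Collects every parameter that affects pipeline outputs in one list:
#' the seed, generator settings, normalization cutoff, negation cues and
#' window, cohort and ADE settings. Accepts a YAML file path or a list;
#' unset fields fall back to package defaults.
#'
#' @param config Path to a YAML file, or a named list (possibly partial).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L,
    synth = list(),
    cutoff = 70,
    negation = list(cues = c("NEGNOTFOUND", "NEGDENIED", "NEGRULEDOUT"),
                    window = 12L),
    cohort = list(specs = NULL, unit = "patient"),
    ade = list(drug_category = NULL, symptom_flag = 1L, min_events = 0L)
  ), config)
  cfg$seed <- suppressWarnings(as.integer(cfg$seed))
  if (is.na(cfg$seed)) abort_bad("`seed` must be an integer")
  if (cfg$cutoff < 0 || cfg$cutoff > 100) abort_bad("`cutoff` must be in [0, 100]")
  structure(cfg, class = "run_config")
}

append_manifest <- function(dir, stage, params, counts) {
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path)
  } else {
    list(package = "rwdminer",
         version = as.character(utils::packageVersion("rwdminer")),
         stages = list())
  }
  manifest$stages[[stage]] <- list(params = params, counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic corpus into a run directory
#'
#' @param config A [run_config()] (its `synth` sub-list overrides
#'   [synth_config()] defaults; the run seed is always used).
#' @param dir Run directory.
#' @return The `ehr_sim`, invisibly.
#' @export
run_simulate <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  scfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
  sim <- simulate_ehr(scfg)
  write_ehr_sim(sim, dir)
  append_manifest(dir, "simulate",
                  params = unclass(scfg),
                  counts = list(events = nrow(sim$dpc), orders = nrow(sim$mo),
                                documents = nrow(sim$documents),
                                planted_mentions = nrow(sim$ground_truth)))
  invisible(sim)
}

load_dictionaries <- function(dir) {
  list(disease = read_dictionary(file.path(dir, "disease_dict.tsv")),
       drug = read_dictionary(file.path(dir, "drug_dict.tsv")))
}

#' Extract entity mentions from the run directory's documents
#'
#' Tags the documents with the dictionary scanner, assigns factuality with
#' the cue-window rule, and writes `mentions.jsonl`.
#'
#' @param config A [run_config()].
#' @param dir Run directory containing `docs.jsonl` and the dictionaries.
#' @return The mention tibble, invisibly.
#' @export
run_extract <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  docs <- read_documents(file.path(dir, "docs.jsonl"))
  dicts <- load_dictionaries(dir)
  mentions <- tag_entities(docs, dicts)
  mentions <- detect_negation(docs, mentions,
                              cues = config$negation$cues,
                              window = config$negation$window)
  write_mentions(mentions, file.path(dir, "mentions.jsonl"))
  append_manifest(dir, "extract",
                  params = config$negation,
                  counts = list(mentions = nrow(mentions),
                                negated = sum(mentions$factuality == "negated")))
  invisible(mentions)
}

#' Normalize mentions and medication orders in a run directory
#'
#' Drops negated mentions, links the survivors to concepts, links order
#' product names to ingredients, and writes `normalized_mentions.jsonl`,
#' `linked_mo.tsv` and `link_report.json`.
#'
#' @param config A [run_config()].
#' @param dir Run directory.
#' @return A list with `mentions` (normalized positives) and `linked_mo`,
#'   invisibly.
#' @export
run_normalize <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  docs <- read_documents(file.path(dir, "docs.jsonl"))
  dicts <- load_dictionaries(dir)
  mentions <- import_annotations(file.path(dir, "mentions.jsonl"), docs)
  positives <- filter_negated(mentions)
  nc <- normalize_corpus(positives, dicts, cutoff = config$cutoff)
  norm <- nc$mentions
  norm$patient_id <- docs$patient_id[match(norm$doc_id, docs$doc_id)]
  write_jsonl(norm, file.path(dir, "normalized_mentions.jsonl"))

  mo <- read_mo(file.path(dir, "mo.tsv"))
  linked_mo <- link_mo_products(mo, dicts$drug, cutoff = config$cutoff)
  readr::write_tsv(linked_mo, file.path(dir, "linked_mo.tsv"))

  jsonlite::write_json(
    list(text = nc$report,
         mo = as.list(attr(linked_mo, "link_report"))),
    file.path(dir, "link_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  append_manifest(dir, "normalize",
                  params = list(cutoff = config$cutoff),
                  counts = list(positive_mentions = nrow(norm),
                                linked = sum(norm$status == "linked"),
                                mo_orders = nrow(linked_mo)))
  invisible(list(mentions = norm, linked_mo = linked_mo))
}

read_normalized <- function(dir) {
  norm <- read_jsonl(file.path(dir, "normalized_mentions.jsonl"))
  linked_mo <- readr::read_tsv(
    file.path(dir, "linked_mo.tsv"),
    col_types = readr::cols(score = "d", amount = "d", .default = "c"),
    progress = FALSE
  )
  list(mentions = norm, linked_mo = linked_mo)
}

#' Frequency comparison of the three sources in a run directory
#'
#' Builds the per-event entity lists, writes the frequency report
#' (`frequency_report.tsv` + `.json`), top concepts per source
#' (`top_concepts.tsv`), cross-source common counts, the drug frequency
#' scatter (`freq_scatter.csv`), and through-origin regression results
#' (`origin_fit.json`) when both routes have at least two concepts.
#'
#' @param config A [run_config()].
#' @param dir Run directory.
#' @return The frequency report tibble, invisibly.
#' @export
run_stats <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  dpc <- read_dpc(file.path(dir, "dpc.tsv"))
  nl <- read_normalized(dir)
  lists <- build_entity_lists(dpc, nl$linked_mo, nl$mentions)
  report <- summarize_frequency(lists)
  readr::write_tsv(report, file.path(dir, "frequency_report.tsv"))
  jsonlite::write_json(report, file.path(dir, "frequency_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  dicts <- load_dictionaries(dir)
  dict_all <- dplyr::bind_rows(dicts$disease, dicts$drug)
  tops <- dplyr::bind_rows(lapply(
    unique(lists[, c("source", "entity_type")]) |> purrr::transpose(),
    function(g) {
      dplyr::mutate(
        top_concepts(lists, g$source, g$entity_type, k = 20, dict_all),
        source = g$source, entity_type = g$entity_type, .before = 1
      )
    }
  ))
  readr::write_tsv(tops, file.path(dir, "top_concepts.tsv"))

  commons <- dplyr::bind_rows(
    dplyr::mutate(common_counts(lists, "TABLE_DPC", "TEXT", "disease"),
                  pair = "TABLE_DPC/TEXT", .before = 1),
    dplyr::mutate(common_counts(lists, "TABLE_MO", "TEXT", "drug"),
                  pair = "TABLE_MO/TEXT", .before = 1)
  )
  readr::write_tsv(commons, file.path(dir, "common_counts.tsv"))

  scatter <- freq_scatter(lists, nl$linked_mo)
  readr::write_csv(scatter, file.path(dir, "freq_scatter.csv"))
  fit_ok <- nrow(scatter) > 0 &&
    all(table(factor(scatter$route, levels = unique(scatter$route))) >= 2)
  if (fit_ok) {
    fit <- origin_regression(dplyr::rename(scatter, group = "route"))
    jsonlite::write_json(glance(fit), file.path(dir, "origin_fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  append_manifest(dir, "stats", params = list(),
                  counts = list(report_rows = nrow(report),
                                scatter_concepts = nrow(scatter)))
  invisible(report)
}

#' Cohort identification over a run directory
#'
#' Loads disease specs (the bundled reference config unless the run config
#' names another), identifies each cohort from the three sources, and
#' writes the Venn region counts to `cohorts.json`.
#'
#' @param config A [run_config()].
#' @param dir Run directory.
#' @return A named list of `cohort_result`s, invisibly.
#' @export
run_cohort <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  specs <- load_disease_specs(config$cohort$specs %||%
                                system.file("extdata", "disease_specs.yaml",
                                            package = "rwdminer"))
  dpc <- read_dpc(file.path(dir, "dpc.tsv"))
  nl <- read_normalized(dir)
  results <- lapply(specs, function(sp) {
    identify_cohort(dpc, nl$linked_mo, nl$mentions, sp,
                    unit = config$cohort$unit)
  })
  jsonlite::write_json(
    lapply(results, function(r) {
      stats::setNames(as.list(r$venn$n), r$venn$region)
    }),
    file.path(dir, "cohorts.json"), auto_unbox = TRUE, pretty = TRUE
  )
  append_manifest(dir, "cohort",
                  params = list(unit = config$cohort$unit,
                                diseases = names(results)),
                  counts = list(diseases = length(results)))
  invisible(results)
}

#' ADE co-frequency screen over a run directory
#'
#' Selects the drug category (all linked ingredients unless the config
#' restricts it), detects the target symptom (dictionary flag mode by
#' default), builds the pair matrices, and writes `M.csv`, `D.csv`,
#' `ratio.csv`.
#'
#' @param config A [run_config()].
#' @param dir Run directory.
#' @return The `pair_matrix`, invisibly.
#' @export
run_ade <- function(config = run_config(), dir) {
  config <- run_config(unclass(config))
  nl <- read_normalized(dir)
  dicts <- load_dictionaries(dir)
  category <- config$ade$drug_category %||%
    sort(unique(nl$linked_mo$ingredient[nl$linked_mo$status == "linked"]))
  spec <- if (!is.null(config$ade$symptom_icd)) {
    symptom_spec("target", "icd_prefix", icd_prefixes = config$ade$symptom_icd)
  } else {
    symptom_spec("target", "ade_flag", flag_index = config$ade$symptom_flag)
  }
  pm <- ade_analysis(nl$linked_mo, nl$mentions, category, spec,
                     disease_dict = dicts$disease,
                     min_events = config$ade$min_events)
  write_pair_matrix(pm, dir)
  append_manifest(dir, "ade",
                  params = list(drugs = pm$drugs,
                                min_events = config$ade$min_events,
                                symptom = unclass(spec)),
                  counts = list(pair_events = sum(diag(pm$M)),
                                symptom_pair_events = sum(diag(pm$D))))
  invisible(pm)
}

#' Run the full pipeline end to end
#'
#' `simulate -> extract -> normalize -> stats -> cohort -> ade` into one
#' run directory. Two runs with the same configuration (seed included)
#' produce byte-identical artifacts.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @param dir Run directory (created if absent).
#' @return Invisibly, a list with the stage outputs.
#' @export
run_pipeline <- function(config = run_config(), dir) {
  config <- run_config(if (is.character(config)) config else unclass(config))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(config, dir)
  mentions <- run_extract(config, dir)
  norm <- run_normalize(config, dir)
  report <- run_stats(config, dir)
  cohorts <- run_cohort(config, dir)
  pm <- run_ade(config, dir)
  invisible(list(sim = sim, mentions = mentions, normalized = norm,
                 report = report, cohorts = cohorts, pair_matrix = pm))
}
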