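toy_mo <- function() {
  tibble::tibble(
    event_id = c("e1", "e1", "e1", "e2", "e2", "e3", "e4"),
    patient_id = "p",
    product_name = "x", route = "oral",
    ingredient = c("A", "B", "A", "A", "B", "A", "C"),
    status = c(rep("linked", 6), "unlinked")
  )
}

test_that("event drug sets deduplicate and exclude non-category events", {
  sets <- select_events_with_drugs(toy_mo(), c("A", "B"))
  expect_equal(sets$drugs[sets$event_id == "e1"][[1]], c("A", "B"))
  expect_equal(sets$drugs[sets$event_id == "e3"][[1]], "A")
  expect_false("e4" %in% sets$event_id)  # C not in category, and unlinked
  expect_error(select_events_with_drugs(toy_mo(), character(0)), "empty")
})

test_that("pair matrix counts events per unordered pair with diagonal exposure", {
  # events {A,B}, {A,B}, {A}
  sets <- select_events_with_drugs(toy_mo(), c("A", "B"))
  M <- build_M(sets)
  expect_equal(M["A", "B"], 2L)
  expect_equal(M["A", "A"], 3L)
  expect_equal(M["B", "B"], 2L)
  expect_identical(M, t(M))

  none <- sets[0, ]
  M0 <- build_M(none, drugs = c("A", "B"))
  expect_true(all(M0 == 0))
})

test_that("symptomatic counts are bounded by pair counts", {
  sets <- select_events_with_drugs(toy_mo(), c("A", "B"))
  D0 <- build_D(sets, character(0), drugs = c("A", "B"))
  expect_true(all(D0 == 0))

  Dall <- build_D(sets, sets$event_id, drugs = c("A", "B"))
  expect_identical(Dall, build_M(sets, drugs = c("A", "B")))

  D1 <- build_D(sets, "e1", drugs = c("A", "B"))
  expect_equal(D1["A", "B"], 1L)
  expect_true(all(D1 <= build_M(sets, drugs = c("A", "B"))))
})

test_that("co-frequency ratio divides elementwise and masks undefined cells", {
  M <- matrix(c(3L, 3L, 3L, 0L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  D <- matrix(c(1L, 1L, 1L, 0L), 2, dimnames = dimnames(M))
  pm <- ratio_heatmap(M, D)
  expect_equal(pm$ratio["A", "A"], 1 / 3)
  expect_true(is.na(pm$ratio["B", "B"]))  # M = 0 is masked, not 0

  pm5 <- ratio_heatmap(M, D, min_events = 5)
  expect_true(all(is.na(pm5$ratio)))

  expect_error(ratio_heatmap(M, D[1, 1, drop = FALSE]), "shapes differ")
  expect_error(ratio_heatmap(D, M), "exceeds")
})

test_that("ratios are invariant under drug relabeling", {
  mini <- run_mini(synth_config(seed = 71, n_patients = 20))
  category <- sort(unique(mini$linked_mo$ingredient[
    mini$linked_mo$status == "linked"]))[1:5]
  sets <- select_events_with_drugs(mini$linked_mo, category)
  sev <- sets$event_id[seq_len(min(3, nrow(sets)))]
  M <- build_M(sets, category)
  D <- build_D(sets, sev, category)
  pm <- ratio_heatmap(M, D)
  perm <- rev(category)
  pm2 <- ratio_heatmap(build_M(sets, perm), build_D(sets, sev, perm))
  expect_identical(pm2$ratio[category, category], pm$ratio)
  expect_true(all(pm$D <= pm$M))
})

test_that("symptom events honour flag and ICD-prefix modes", {
  dict <- tibble::tibble(
    surface = c("sore mouth", "tingling"),
    concept_id = c("K121", "R208"), concept_name = c("stomatitis", "neuropathy"),
    flag_1 = c(1L, 0L), flag_2 = c(0L, 1L)
  )
  mentions <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"), event_id = c("e1", "e2", "e3"),
    entity_type = "disease", factuality = "positive",
    surface = c("sore mouth", "tingling", "sore mouth"),
    start = 0L, end = 1L,
    concept_id = c("K121", "R208", NA),
    status = c("linked", "linked", "unlinked"),
    matched_surface = c("sore mouth", "tingling", NA)
  )
  stom <- symptom_spec("stomatitis", "ade_flag", flag_index = 1)
  expect_equal(symptom_events(mentions, stom, dict), "e1")
  neuro <- symptom_spec("neuropathy", "icd_prefix", icd_prefixes = "R20")
  expect_equal(symptom_events(mentions, neuro), "e2")
  expect_error(symptom_spec("x", "ade_flag"), "flag_index")
  expect_error(symptom_spec("x", "ade_flag", flag_index = 1,
                            icd_prefixes = "R20"), "exactly one")
})

test_that("full ADE analysis recovers a planted symptom rate", {
  set.seed(72)
  n_ev <- 250
  p <- 0.4
  dicts <- list(
    disease = tibble::tibble(
      surface = "mucosalsorenessx", concept_id = "K121",
      concept_name = "stomatitis", flag_1 = 1L
    ),
    drug = tibble::tibble(
      surface = c("drugalphaa", "drugbetaa"),
      concept_id = c("ALPHA", "BETA"),
      concept_name = c("ALPHA", "BETA")
    )
  )
  mo <- tibble::tibble(
    event_id = rep(sprintf("e%03d", 1:n_ev), each = 2),
    product_name = rep(c("drugalphaa", "drugbetaa"), n_ev),
    route = "injection"
  )
  has_sym <- stats::rbinom(n_ev, 1, p) == 1
  docs <- tibble::tibble(
    doc_id = sprintf("d%03d", 1:n_ev), event_id = sprintf("e%03d", 1:n_ev),
    patient_id = sprintf("p%03d", 1:n_ev),
    text = ifelse(has_sym, "note 1111 mucosalsorenessx 2222", "note 1111 2222")
  )
  m <- tag_entities(docs, dicts)
  m <- detect_negation(docs, m)
  nc <- normalize_corpus(filter_negated(m), dicts)
  linked_mo <- link_mo_products(mo, dicts$drug)
  pm <- ade_analysis(linked_mo, nc$mentions, c("ALPHA", "BETA"),
                     symptom_spec("stomatitis", "ade_flag", flag_index = 1),
                     disease_dict = dicts$disease)
  se <- sqrt(p * (1 - p) / n_ev)
  expect_lt(abs(pm$ratio["ALPHA", "BETA"] - p), 3 * se + 1e-9)
  expect_equal(pm$M["ALPHA", "BETA"], n_ev)
  expect_equal(pm$D["ALPHA", "BETA"], sum(has_sym))
})

test_that("pair matrices export, tidy, plot, and yield odds ratios", {
  M <- matrix(c(10L, 4L, 4L, 8L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  D <- matrix(c(5L, 2L, 2L, 2L), 2, dimnames = dimnames(M))
  pm <- ratio_heatmap(M, D)
  td <- tidy(pm)
  expect_equal(nrow(td), 3)
  expect_equal(td$ratio[td$drug_a == "A" & td$drug_b == "B"], 0.5)

  dir <- withr::local_tempdir()
  write_pair_matrix(pm, dir)
  back <- readr::read_csv(file.path(dir, "ratio.csv"),
                          show_col_types = FALSE)
  expect_equal(back$A, unname(pm$ratio[, "A"]))

  expect_s3_class(autoplot(pm), "ggplot")

  # hand-computed 2x2: pair (A,B): m=4, d=2, of 12 events, 6 symptomatic
  or <- pair_odds_ratio(pm, n_events = 12, n_symptom_events = 6)
  manual <- (2 * 4) / (2 * 4)
  expect_equal(or$odds_ratio[or$drug_a == "A" & or$drug_b == "B"], manual)
})
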