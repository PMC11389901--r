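mini_dict <- function(surfaces, concepts) {
  tibble::tibble(surface = surfaces, concept_id = concepts,
                 concept_name = concepts)
}

mention_row <- function(surface, type = "disease") {
  tibble::tibble(doc_id = "d1", event_id = "e1", start = 0L,
                 end = nchar(surface), surface = surface,
                 entity_type = type, factuality = "positive")
}

test_that("normalized Levenshtein score matches its closed forms", {
  expect_equal(nls_score("stomatitis", "stomatitis"), 100)
  expect_equal(nls_score("abcd", "abce"), 75)
  expect_equal(nls_score("ab", "cd"), 0)
  expect_equal(nls_score("stomatits", "stomatitis"), 90)
  expect_error(nls_score("", "abc"), "empty")
})

test_that("score is symmetric, bounded, and agrees with the textbook DP", {
  set.seed(41)
  for (i in 1:60) {
    a <- rnd_str()
    b <- rnd_str()
    s <- nls_score(a, b)
    expect_equal(s, nls_score(b, a))
    expect_gte(s, 0)
    expect_lte(s, 100)
    expect_equal(s, 100 * (1 - lev_dp(a, b) / max(nchar(a), nchar(b))))
  }
  expect_equal(nls_score("abcabc", "abcabc"), 100)
})

test_that("exact and one-edit surfaces link; sub-cutoff stays unlinked", {
  dict <- list(disease = mini_dict(c("stomatitis", "neuropathy"),
                                   c("K121", "R208")),
               drug = mini_dict("docetaxel", "DOCETAXEL"))
  exact <- link_mention(mention_row("stomatitis"), dict)
  expect_equal(exact$status, "linked")
  expect_equal(exact$score, 100)
  expect_equal(exact$concept_id, "K121")

  fuzzy <- link_mention(mention_row("stomatits"), dict)
  expect_equal(fuzzy$score, 90)
  expect_equal(fuzzy$status, "linked")

  off <- link_mention(mention_row("zzzzzzzzzz"), dict)
  expect_equal(off$status, "unlinked")
  expect_true(is.na(off$concept_id))
})

test_that("cross-concept top-score ties are excluded as ambiguous", {
  dict <- list(disease = mini_dict(c("abcd", "abce"), c("C01", "C02")),
               drug = mini_dict("docetaxel", "DOCETAXEL"))
  amb <- link_mention(mention_row("abcf"), dict)
  expect_equal(amb$status, "ambiguous")
  expect_true(is.na(amb$concept_id))

  # same tie within one concept is harmless
  dict1 <- list(disease = mini_dict(c("abcd", "abce"), c("C01", "C01")),
                drug = mini_dict("docetaxel", "DOCETAXEL"))
  ok <- link_mention(mention_row("abcf"), dict1)
  expect_equal(ok$status, "linked")
  expect_equal(ok$concept_id, "C01")

  expect_error(link_mention(mention_row("x"), list(disease = mini_dict(
    character(0), character(0)), drug = NULL)), "empty dictionary")
})

test_that("linker equals the brute-force scan on random instances", {
  set.seed(42)
  for (i in 1:40) {
    n_s <- sample(3:30, 1)
    surfaces <- unique(replicate(60, rnd_str()))
    surfaces <- surfaces[seq_len(min(n_s, length(surfaces)))]
    dict <- mini_dict(surfaces,
                      paste0("C", sample(10, length(surfaces), replace = TRUE)))
    q <- rnd_str()
    got <- link_mention(mention_row(q), list(disease = dict, drug = dict))
    want <- brute_link(q, dict)
    expect_equal(got$score, want$best)
    expect_equal(got$status, want$status)
    if (want$status == "linked") expect_equal(got$concept_id, want$concept)
  }
})

test_that("raising the cutoff never increases the linked count", {
  sim <- simulate_ehr(synth_config(seed = 43, n_patients = 10,
                                   p_surface_perturb = 0.5))
  dicts <- list(disease = sim$disease_dict, drug = sim$drug_dict)
  gt <- sim$ground_truth
  mentions <- tibble::tibble(
    doc_id = gt$doc_id, event_id = gt$event_id, start = gt$start,
    end = gt$end, surface = gt$surface, entity_type = gt$entity_type,
    factuality = "positive"
  )
  linked_at <- vapply(c(0, 40, 70, 90, 100), function(cut) {
    sum(link_mention(mentions, dicts, cutoff = cut)$status == "linked")
  }, numeric(1))
  expect_true(all(diff(linked_at) <= 0))

  res <- link_mention(mentions, dicts, cutoff = 70)
  expect_equal(sum(res$status == "linked") + sum(res$status == "unlinked") +
                 sum(res$status == "ambiguous"), nrow(mentions))
})

test_that("corpus normalization reports sensible link rates", {
  dicts <- list(disease = mini_dict("stomatitis", "K121"),
                drug = mini_dict("docetaxel", "DOCETAXEL"))
  none <- normalize_corpus(mention_row("stomatitis")[0, ], dicts)
  expect_true(all(is.na(none$report$normalized_rate)))

  all_exact <- normalize_corpus(
    dplyr::bind_rows(mention_row("stomatitis"),
                     mention_row("docetaxel", "drug")), dicts)
  expect_equal(all_exact$report$normalized_rate, c(1, 1))
})

test_that("out-of-dictionary fraction drives the normalized rate", {
  cfg <- synth_config(seed = 44, n_patients = 60, p_out_of_dictionary = 0.4,
                      p_surface_perturb = 0, p_negated = 0)
  sim <- simulate_ehr(cfg)
  gt <- sim$ground_truth
  # external-NER route: ground truth plays the recognizer's output
  mentions <- tibble::tibble(
    doc_id = gt$doc_id, event_id = gt$event_id, start = gt$start,
    end = gt$end, surface = gt$surface, entity_type = gt$entity_type,
    factuality = "positive"
  )
  nc <- normalize_corpus(mentions,
                         list(disease = sim$disease_dict,
                              drug = sim$drug_dict))
  rate <- sum(nc$report$total_normalized) / sum(nc$report$total_entities)
  n <- nrow(mentions)
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(rate - 0.6), 4 * se)
})

test_that("product names link to ingredients under the same contract", {
  drug_dict <- mini_dict(c("paclitaxol", "docetaxel"),
                         c("PACLITAXEL", "DOCETAXEL"))
  mo <- tibble::tibble(event_id = c("e1", "e2", "e3"),
                       product_name = c("docetaxel", "paclitaxxol", "qqqq"),
                       route = c("oral", "injection", "oral"))
  lk <- link_mo_products(mo, drug_dict)
  expect_equal(lk$ingredient[1], "DOCETAXEL")
  expect_equal(lk$status[2], "linked")  # one edit in a 10+1-char name
  expect_gte(lk$score[2], 90)
  expect_equal(lk$status[3], "unlinked")
  rep <- attr(lk, "link_report")
  expect_equal(sum(rep), nrow(mo))
})
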