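toy_lists <- function() {
  # 3 events hand-built across the three sources
  dpc <- tibble::tibble(
    event_id = c("e1", "e2", "e3"), patient_id = c("p1", "p1", "p2"),
    icd_codes = list(c("C50", "C509"), "E11", "C50")
  )
  mo <- tibble::tibble(
    event_id = c("e1", "e1", "e2"),
    product_name = c("druga", "drugb", "druga"),
    route = c("oral", "injection", "oral"),
    ingredient = c("ING_A", "ING_B", "ING_A"),
    status = c("linked", "linked", "linked")
  )
  mentions <- tibble::tibble(
    doc_id = c("d1", "d1", "d1", "d2"), event_id = c("e1", "e1", "e1", "e2"),
    start = 0L, end = 1L,
    surface = c("mild stomatitis", "mild stomatitis", "rash", "unknownterm"),
    entity_type = "disease",
    factuality = "positive",
    concept_id = c("K121", "K121", "R21", NA),
    score = c(100, 100, 100, 10),
    status = c("linked", "linked", "linked", "unlinked")
  )
  build_entity_lists(dpc, mo, mentions)
}

test_that("entity lists match hand enumeration on a toy corpus", {
  lists <- toy_lists()
  dpc_part <- lists[lists$source == "TABLE_DPC", ]
  expect_equal(nrow(dpc_part), 4)           # C50, C509, E11, C50
  expect_true(all(dpc_part$linked))
  expect_equal(sort(dpc_part$surface), c("C50", "C50", "C509", "E11"))

  mo_part <- lists[lists$source == "TABLE_MO", ]
  expect_equal(nrow(mo_part), 3)
  text_part <- lists[lists$source == "TEXT", ]
  expect_equal(nrow(text_part), 4)
  # event without text entities contributes no TEXT rows
  expect_false("e3" %in% text_part$event_id)
})

test_that("summary counts entities, normalized entities, and concepts", {
  lists <- toy_lists()
  rep <- summarize_frequency(lists)
  text_row <- rep[rep$source == "TEXT", ]
  expect_equal(text_row$total_entities, 4)
  expect_equal(text_row$total_normalized, 3)
  expect_equal(text_row$normalized_rate, 3 / 4)
  expect_equal(text_row$total_concepts, 2)
  expect_equal(text_row$total_events_with_entities, 2)
  # event e1: mentions [K121, K121, R21] all linked -> 3 entities, 2 concepts
  expect_equal(text_row$entities_median, 2)   # events e1 (3), e2 (1)
  expect_equal(text_row$concepts_mean, 1)     # e1 has 2, e2 has 0

  dpc_row <- rep[rep$source == "TABLE_DPC", ]
  expect_equal(dpc_row$normalized_rate, 1)
  expect_equal(dpc_row$vocabulary_size, 3)
})

test_that("report equals an independent brute-force recount", {
  set.seed(51)
  for (i in 1:5) {
    mini <- run_mini(synth_config(seed = 510 + i, n_patients = 8))
    got <- summarize_frequency(mini$lists)
    want <- oracle_report(mini$lists)
    got <- got[order(got$source, got$entity_type), ]
    want <- want[order(want$source, want$entity_type), ]
    for (col in names(want)[-(1:2)]) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12,
                   ignore_attr = TRUE, label = col)
    }
  }
})

test_that("frequency invariants hold and removing an event only shrinks totals", {
  mini <- run_mini(synth_config(seed = 52, n_patients = 10))
  rep <- summarize_frequency(mini$lists)
  expect_true(all(rep$total_concepts <= rep$total_normalized))
  expect_true(all(rep$total_normalized <= rep$total_entities))
  expect_true(all(rep$concepts_mean <= rep$normalized_mean))

  drop_ev <- mini$lists$event_id[1]
  rep2 <- summarize_frequency(mini$lists[mini$lists$event_id != drop_ev, ])
  merged <- dplyr::inner_join(rep, rep2, by = c("source", "entity_type"))
  expect_true(all(merged$total_entities.y <= merged$total_entities.x))
  expect_true(all(merged$total_normalized.y <= merged$total_normalized.x))
})

test_that("common vocabulary and concept counts are set intersections", {
  lists <- tibble::tibble(
    event_id = "e1",
    source = rep(c("TABLE_DPC", "TEXT"), each = 3),
    entity_type = "disease",
    surface = c("a", "b", "c", "b", "c", "d"),
    concept_id = c("a", "b", "c", "b", "c", "d"),
    linked = TRUE
  )
  cc <- common_counts(lists, "TABLE_DPC", "TEXT", "disease")
  expect_equal(cc$common_entities, 2)
  expect_equal(cc$common_concepts, 2)

  same <- common_counts(lists, "TEXT", "TEXT", "disease")
  expect_equal(same$common_entities, 3)
  expect_equal(common_counts(lists, "TABLE_DPC", "TEXT", "drug")$common_entities, 0)
})

test_that("top concepts rank by frequency with deterministic ties", {
  lists <- tibble::tibble(
    event_id = "e1", source = "TEXT", entity_type = "disease",
    surface = c("x", "x", "x", "y", "y", "z", "z", "w", "w", "w", "u", "v", "v"),
    concept_id = c(rep("C2", 3), rep("C9", 2), rep("C1", 2), rep("C3", 3),
                   "C4", "C5", "C5"),
    linked = TRUE
  )
  top <- top_concepts(lists, "TEXT", "disease", k = 3)
  expect_equal(top$concept_id, c("C2", "C3", "C1"))  # 3,3 tie -> C2 before C3
  expect_equal(top$frequency, c(3, 3, 2))
  expect_equal(top$rank, 1:3)

  all_rows <- top_concepts(lists, "TEXT", "disease", k = 99)
  expect_equal(nrow(all_rows), 6)
  expect_true(all(diff(all_rows$frequency) <= 0))
})

test_that("origin regression matches its closed form", {
  exact <- origin_regression(tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6)))
  g <- glance(exact)
  expect_equal(g$slope, 2)
  expect_equal(g$r2_uncentered, 1)
  expect_equal(g$r2_centered, 1)

  set.seed(53)
  d <- tibble::tibble(x = runif(40, 1, 100),
                      y = runif(40, 1, 100),
                      group = rep(c("oral", "injection"), 20))
  fit <- glance(origin_regression(d))
  for (grp in c("oral", "injection")) {
    sub <- d[d$group == grp, ]
    beta <- sum(sub$x * sub$y) / sum(sub$x^2)
    ss <- sum((sub$y - beta * sub$x)^2)
    row <- fit[fit$group == grp, ]
    expect_equal(row$slope, beta)
    expect_equal(row$r2_uncentered, 1 - ss / sum(sub$y^2))
    expect_equal(row$r2_centered, 1 - ss / sum((sub$y - mean(sub$y))^2))
  }

  expect_error(origin_regression(tibble::tibble(x = 1, y = 2)), "fewer than 2")
  expect_error(origin_regression(tibble::tibble(x = c(0, 1), y = c(1, 2))),
               "positive")
  expect_equal(tidy(exact)$estimate, 2)
})

test_that("scatter assembly and autoplot run on a synthetic corpus", {
  mini <- run_mini(synth_config(seed = 54, n_patients = 25))
  sc <- freq_scatter(mini$lists, mini$linked_mo)
  expect_true(all(sc$x > 0 & sc$y > 0))
  expect_true(all(sc$route %in% c("oral", "injection")))
  if (all(table(sc$route) >= 2)) {
    fit <- origin_regression(dplyr::rename(sc, group = "route"))
    p <- autoplot(fit)
    expect_s3_class(p, "ggplot")
  }
})
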