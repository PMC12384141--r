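test_that("patient categorization renders the canonical query string", {
  rec <- list(pdl1_score = 60, tmb = 12, smoking = "current", age = 68,
              outcome = 1)
  q <- categorize_patient(rec, pT = 0.8, ppT = 0.3)
  expect_equal(q$rendered,
               paste("responder pdl1_score high TMB high high tumoral probability",
                     "low peritumoral probability current smoker",
                     "age between 60 and 70"))
  # threshold arithmetic at the boundaries
  expect_equal(categorize_patient(rec, 0.69, 0.5)$levels[["tumoral probability"]],
               "low")
  expect_equal(categorize_patient(rec, 0.70, 0.5)$levels[["tumoral probability"]],
               "high")
  rec65 <- modifyList(rec, list(age = 65))
  expect_equal(categorize_patient(rec65, 0.5, 0.5)$levels[["age"]], "low")
  rec66 <- modifyList(rec, list(age = 66))
  expect_equal(categorize_patient(rec66, 0.5, 0.5)$levels[["age"]], "high")
  expect_error(categorize_patient(list(pdl1_score = 1), 0.5, 0.5), "missing")
})

test_that("triplets honour the hypothesis table and discard inconsistencies", {
  dag <- tibble::tibble(from = c("pdl1_bin", "smoking"),
                        to = c("outcome", "outcome"))
  hyp <- default_hypotheses()
  q_cons <- categorize_patient(list(pdl1_score = 80, tmb = 12,
                                    smoking = "current", age = 50, outcome = 1),
                               0.2, 0.2)
  q_incons <- categorize_patient(list(pdl1_score = 5, tmb = 12,
                                      smoking = "never", age = 50, outcome = 1),
                                 0.2, 0.2)
  tr <- graph_to_triplets(dag, hyp, list(p1 = q_cons, p2 = q_incons))
  # consistent patient keeps pdl1 high + current smoker sentences
  expect_setequal(tr$feature[tr$patient_id == "p1"], c("pdl1_score", "smoking"))
  expect_true(all(grepl("positive response", tr$sentence[tr$patient_id == "p1"])))
  # pdl1 low + never smoker contradict a responder outcome: both discarded
  expect_equal(sum(tr$patient_id == "p2"), 0)
  # empty patient list: empty output
  expect_equal(nrow(graph_to_triplets(dag, hyp, list())), 0)
})

test_that("the fallback embedder is deterministic with orthogonal disjoint tokens", {
  e1 <- embed_text("pdl1 high responder")
  e2 <- embed_text("pdl1 high responder")
  expect_identical(e1, e2)
  expect_equal(sum(unclass(e1)^2), 1, tolerance = 1e-12)
  expect_equal(answer_relevancy_metric(e1, list(e2)), 1.0, tolerance = 1e-12)
  # token-disjoint, hash-collision-free pair
  ea <- embed_text("alpha")
  eb <- embed_text("bravo")
  expect_equal(sum(unclass(ea) * unclass(eb)), 0)
  expect_error(embed_text(""), "non-empty")

  # injected custom backend is honoured
  ec <- embed_text("anything", backend = function(t) c(1, 2, 3))
  expect_equal(as.numeric(ec), c(1, 2, 3))
})

test_that("ranking orders by cosine and a self-match tops the list", {
  kn <- tibble::tibble(
    feature = c("pdl1_score", "smoking", "TMB"),
    sentence = c("pdl1_score high is associated with positive response",
                 "smoking current is associated with positive response",
                 "unrelated words entirely zebra"))
  q <- "pdl1_score high is associated with positive response"
  rk <- rank_features(q, kn)
  expect_equal(rk$feature[1], "pdl1_score")
  expect_equal(rk$ar[1], 1.0, tolerance = 1e-12)
  expect_setequal(rk$sentence, kn$sentence)  # a permutation of candidates
  expect_true(all(diff(rk$ar) <= 1e-12))
})

test_that("relevancy-margin filtering is monotone in tau", {
  ranked <- tibble::tibble(
    feature = c("f1", "f1", "f2", "f3"),
    sentence = letters[1:4],
    ar = c(0.90, 0.88, 0.75, 0.60))
  # tau = 0: everything unambiguous is retained (all features keep their top)
  r0 <- filter_by_relevancy_margin(ranked, 0)
  expect_equal(nrow(r0), 3)
  # margin 0.02 < tau = 0.05: f1 ambiguous, dropped; singletons stay
  r5 <- filter_by_relevancy_margin(ranked, 0.05)
  expect_setequal(r5$feature, c("f2", "f3"))
  # tau = 0.01 retains the f1 top response
  r1 <- filter_by_relevancy_margin(ranked, 0.01)
  expect_true("f1" %in% r1$feature)
  expect_equal(r1$ar[r1$feature == "f1"], 0.90)
  # set inclusion along increasing tau
  taus <- c(0, 0.01, 0.03, 0.05, 0.2)
  sets <- lapply(taus, function(tau) {
    filter_by_relevancy_margin(ranked, tau)$sentence
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  expect_error(filter_by_relevancy_margin(ranked, -0.1), "non-negative")
})

test_that("the answer relevancy metric is the mean cosine", {
  eo <- embed_text("alpha")
  e_orth <- embed_text("bravo")
  expect_equal(answer_relevancy_metric(eo, list(eo, eo, eo)), 1.0)
  expect_equal(answer_relevancy_metric(eo, list(e_orth)), 0.0)
  expect_equal(answer_relevancy_metric(eo, list(eo, e_orth)), 0.5)
  expect_error(answer_relevancy_metric(eo, list()), "at least one")
  expect_error(answer_relevancy_metric(eo, list(rep(0, 256))), "zero-norm")
})

test_that("reports state the outcome, retained evidence, and flag conflicts", {
  q <- categorize_patient(list(pdl1_score = 80, tmb = 12, smoking = "current",
                               age = 50, outcome = 1), 0.2, 0.2)
  retained <- tibble::tibble(
    feature = c("pdl1_score", "smoking"),
    level = c("high", "current"),
    sentence = c("pdl1_score high is associated with positive response",
                 "smoking current is associated with positive response"))
  rep1 <- generate_report(q, retained)
  rep2 <- generate_report(q, retained)
  expect_identical(rep1, rep2)
  expect_match(rep1, "responder")
  expect_match(rep1, "pdl1_score high")
  expect_match(rep1, "smoking current")

  # a retained sentence claiming a level the patient does not have is excluded
  bad <- tibble::tibble(feature = "pdl1_score", level = "low",
                        sentence = "pdl1_score low is associated with negative response")
  rep_bad <- generate_report(q, bad)
  expect_false(grepl("pdl1_score low", rep_bad))
  expect_match(rep_bad, "No supporting features")

  # custom client injection
  cl <- function(query, sentences) sprintf("custom:%d", nrow(sentences))
  expect_equal(generate_report(q, retained, llm_client = cl), "custom:2")
})
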