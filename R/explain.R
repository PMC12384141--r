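#' Clinical hypothesis table for NSCLC immunotherapy response
#'
#' Literature-grounded direction of each (feature, level) pair: high PD-L1
#' and high TMB favour response; high tumoral / peritumoral predicted
#' probabilities associate with non-response; current and former smokers
#' respond better than never smokers; age above 65 carries a negative
#' direction. Every pair maps to exactly one direction.
#'
#' @return A tibble: `feature`, `level`, `direction`
#'   (`"positive_response"` / `"negative_response"`), `rationale`.
#' @export
default_hypotheses <- function() {
  tibble::tribble(
    ~feature, ~level, ~direction, ~rationale,
    "pdl1_score", "high", "positive_response", "PD-L1 >= 50% enriches responders",
    "pdl1_score", "low", "negative_response", "PD-L1 < 50% enriches non-responders",
    "TMB", "high", "positive_response", "TMB >= 10 mut/Mb favours response",
    "TMB", "low", "negative_response", "TMB < 10 mut/Mb disfavours response",
    "tumoral probability", "high", "negative_response", "high pT tracks non-response",
    "tumoral probability", "low", "positive_response", "low pT tracks response",
    "peritumoral probability", "high", "negative_response", "high ppT tracks non-response",
    "peritumoral probability", "low", "positive_response", "low ppT tracks response",
    "smoking", "current", "positive_response", "smokers carry higher mutation load",
    "smoking", "former", "positive_response", "smokers carry higher mutation load",
    "smoking", "never", "negative_response", "never smokers respond less often",
    "age", "high", "negative_response", "age above 65 disfavours response",
    "age", "low", "positive_response", "age 65 or below favours response"
  )
}

#' Categorize a patient into the query vocabulary
#'
#' PD-L1 and TMB become high/low at the cohort-table cutoffs (50% and
#' 10 mut/Mb), pT and ppT at 0.7 (>= is high), smoking passes through, age
#' is high strictly above 65, and the rendered age band is the decade bin.
#' The rendered query concatenates outcome and feature levels in a fixed
#' order.
#'
#' @param record One-row data frame/list with `pdl1_score`, `tmb`,
#'   `smoking`, `age` and `outcome` (0/1).
#' @param pT,ppT Predicted probabilities in [0, 1].
#' @return A list of class `patient_query`: categorical `levels` (named),
#'   `age_band`, `outcome_label`, and the `rendered` query string.
#' @export
categorize_patient <- function(record, pT, ppT) {
  need <- c("pdl1_score", "tmb", "smoking", "age", "outcome")
  miss <- setdiff(need, names(record))
  if (length(miss)) abort(paste("missing fields:", paste(miss, collapse = ", ")))
  lv <- c(
    `pdl1_score` = ifelse(record$pdl1_score >= 50, "high", "low"),
    `TMB` = ifelse(record$tmb >= 10, "high", "low"),
    `tumoral probability` = ifelse(pT >= 0.7, "high", "low"),
    `peritumoral probability` = ifelse(ppT >= 0.7, "high", "low"),
    `smoking` = as.character(record$smoking),
    `age` = ifelse(record$age > 65, "high", "low")
  )
  decade <- floor(record$age / 10) * 10
  age_band <- sprintf("age between %d and %d", decade, decade + 10)
  outcome_label <- ifelse(as.integer(record$outcome) == 1, "responder",
                          "non responder")
  rendered <- paste(
    outcome_label,
    paste("pdl1_score", lv[["pdl1_score"]]),
    paste("TMB", lv[["TMB"]]),
    paste(lv[["tumoral probability"]], "tumoral probability"),
    paste(lv[["peritumoral probability"]], "peritumoral probability"),
    paste0(lv[["smoking"]], " smoker"),
    age_band
  )
  structure(list(levels = lv, age_band = age_band,
                 outcome_label = outcome_label, rendered = rendered),
            class = "patient_query")
}

#' @export
print.patient_query <- function(x, ...) {
  cat("<patient_query>", x$rendered, "\n")
  invisible(x)
}

# graph neighbours of the outcome node (either edge direction)
outcome_neighbours <- function(dag, outcome = "outcome") {
  edges <- dag_edges(dag)
  unique(c(edges$from[edges$to == outcome], edges$to[edges$from == outcome]))
}

# map graph node names to hypothesis feature vocabulary
node_to_feature <- function(node) {
  switch(node,
    pdl1_bin = "pdl1_score", tmb_bin = "TMB",
    pT = "tumoral probability", ppT = "peritumoral probability",
    smoking = "smoking", age_bin = "age", node)
}

#' Render hypothesis-grounded triplet sentences from a learned graph
#'
#' For every patient and every graph neighbour of the outcome node, a
#' subject-predicate-object sentence is built linking the patient's feature
#' level to their outcome. Sentences whose (feature, level, outcome)
#' combination contradicts the hypothesis table are discarded as clinically
#' irrelevant.
#'
#' @param dag A `bnsl` fit or edge tibble containing the outcome node.
#' @param hypotheses A hypothesis table, see [default_hypotheses()].
#' @param patient_queries List of `patient_query` objects (named by patient
#'   id, or ids taken from position).
#' @return A tibble: `patient_id`, `feature`, `level`, `direction`,
#'   `sentence`.
#' @export
graph_to_triplets <- function(dag, hypotheses, patient_queries) {
  if (!length(patient_queries)) {
    return(tibble::tibble(patient_id = character(0), feature = character(0),
                          level = character(0), direction = character(0),
                          sentence = character(0)))
  }
  feats <- vapply(outcome_neighbours(dag), node_to_feature, character(1))
  ids <- names(patient_queries) %||% sprintf("patient_%d", seq_along(patient_queries))
  rows <- list()
  for (i in seq_along(patient_queries)) {
    q <- patient_queries[[i]]
    for (ft in feats) {
      if (!ft %in% names(q$levels)) next
      level <- q$levels[[ft]]
      hyp <- hypotheses[hypotheses$feature == ft & hypotheses$level == level, ]
      if (nrow(hyp) == 0) {
        abort(sprintf("no hypothesis entry for feature '%s' level '%s'", ft, level))
      }
      wanted <- ifelse(q$outcome_label == "responder",
                       "positive_response", "negative_response")
      if (hyp$direction[1] != wanted) next  # hypothesis-inconsistent: discard
      dir_txt <- ifelse(hyp$direction[1] == "positive_response",
                        "positive response", "negative response")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = ids[i], feature = ft, level = level,
        direction = hyp$direction[1],
        sentence = sprintf("%s %s is associated with %s", ft, level, dir_txt))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(patient_id = character(0), feature = character(0),
                          level = character(0), direction = character(0),
                          sentence = character(0)))
  }
  dplyr::bind_rows(rows)
}

#' Deterministic offline text embedding
#'
#' Hashed bag-of-tokens embedding: the text is lowercased, split on
#' non-alphanumerics, each token is hashed to one of `dim` buckets
#' (polynomial rolling hash), counts are accumulated and the vector is
#' L2-normalized. Fully deterministic and network-free; any function
#' `text -> numeric vector` can be injected instead.
#'
#' @param text Non-empty character scalar.
#' @param backend `"fallback"` for the hashed bag of tokens, or a function.
#' @param dim Embedding dimension of the fallback backend.
#' @return Numeric vector of class `embedding` with attribute `backend_id`.
#' @export
embed_text <- function(text, backend = "fallback", dim = 256L) {
  if (!nzchar(text)) abort("text must be non-empty")
  if (is.function(backend)) {
    v <- backend(text)
    return(structure(as.numeric(v), class = "embedding", backend_id = "custom"))
  }
  tokens <- strsplit(tolower(text), "[^a-z0-9>=<]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  v <- numeric(dim)
  for (tk in tokens) {
    h <- 7L
    for (code in utf8ToInt(tk)) h <- (h * 31L + code) %% dim
    v[h + 1L] <- v[h + 1L] + 1
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  structure(v, class = "embedding", backend_id = paste0("hashed-bow-", dim))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("zero-norm embedding vector")
  sum(a * b) / (na * nb)
}

#' Rank knowledge sentences by cosine similarity to a query
#'
#' @param query A `patient_query` or character string.
#' @param knowledge Tibble with columns `feature` and `sentence`.
#' @param backend Embedding backend, see [embed_text()].
#' @return The knowledge tibble with an `ar` column (cosine to the query),
#'   sorted descending, ties broken lexicographically by sentence.
#' @export
rank_features <- function(query, knowledge, backend = "fallback") {
  qtext <- if (inherits(query, "patient_query")) query$rendered else query
  qe <- embed_text(qtext, backend)
  ar <- vapply(knowledge$sentence,
               function(s) cosine_sim(embed_text(s, backend), qe), numeric(1))
  out <- knowledge
  out$ar <- unname(ar)
  out[order(-out$ar, out$sentence), , drop = FALSE]
}

#' Filter ranked responses by a per-feature relevancy margin
#'
#' A response is retained only when its answer relevancy exceeds the best
#' competing response for the same feature by at least `tau`; a feature's
#' sole candidate is always retained. Raising `tau` can only shrink the
#' retained set, so stricter thresholds yield fewer, more clearly relevant
#' responses.
#'
#' @param ranked Tibble with columns `feature` and `ar`.
#' @param tau Non-negative margin threshold.
#' @return The retained subset of `ranked`.
#' @export
filter_by_relevancy_margin <- function(ranked, tau) {
  if (tau < 0) abort("tau must be non-negative")
  keep <- logical(nrow(ranked))
  for (ft in unique(ranked$feature)) {
    idx <- which(ranked$feature == ft)
    if (length(idx) == 1) {
      keep[idx] <- TRUE
      next
    }
    ars <- sort(ranked$ar[idx], decreasing = TRUE)
    if (ars[1] - ars[2] >= tau) {
      keep[idx[which.max(ranked$ar[idx])]] <- TRUE
    }
  }
  ranked[keep, , drop = FALSE]
}

#' Answer relevancy metric
#'
#' Mean cosine similarity between each generated-response embedding and the
#' original-question embedding:
#' `ARM = (1/N) * sum_i cos(Eg_i, Eo)` with
#' `cos(a, b) = a . b / (|a| |b|)`. Bounded in [-1, 1]; in [0, 1] for the
#' non-negative fallback backend.
#'
#' @param Eo Embedding of the original question.
#' @param Eg_list List of N >= 1 generated-response embeddings.
#' @return ARM (numeric scalar).
#' @export
answer_relevancy_metric <- function(Eo, Eg_list) {
  if (!length(Eg_list)) abort("need at least one generated response")
  mean(vapply(Eg_list, function(e) cosine_sim(e, Eo), numeric(1)))
}

#' Render a patient report from retained sentences
#'
#' The default template client states the predicted outcome and appends
#' each retained hypothesis sentence; any generator with the signature
#' `function(query, sentences)` can be injected. An empty retained set
#' produces an outcome-only report flagged "no supporting features".
#'
#' @param query A `patient_query`.
#' @param retained Tibble of retained sentences (needs `sentence`, `level`,
#'   `feature` columns).
#' @param llm_client Optional generator function.
#' @return Character scalar report.
#' @export
generate_report <- function(query, retained, llm_client = NULL) {
  # drop sentences whose claimed level contradicts the patient's own level
  if (nrow(retained)) {
    ok <- vapply(seq_len(nrow(retained)), function(i) {
      ft <- retained$feature[i]
      !ft %in% names(query$levels) || retained$level[i] == query$levels[[ft]]
    }, logical(1))
    retained <- retained[ok, , drop = FALSE]
  }
  if (!is.null(llm_client)) return(llm_client(query, retained))
  if (!nrow(retained)) {
    return(sprintf("Predicted outcome: %s. No supporting features retained.",
                   query$outcome_label))
  }
  paste0(
    "Predicted outcome: ", query$outcome_label, ". Supporting evidence: ",
    paste(retained$sentence, collapse = "; "), "."
  )
}
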