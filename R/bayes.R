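#' Discretize clinical variables and response probabilities
#'
#' Bins follow the cohort-table conventions: PD-L1 score into
#' `0 / 1-49 / >=50` percent, TMB at 10 mutations/Mb, age into decades,
#' and pT / ppT at 0.7 (values >= 0.7 are `"high"`; the boundary belongs to
#' the high bin by the declared `>=` convention). Smoking and outcome pass
#' through as categories.
#'
#' @param clinical Data frame with `pdl1_score`, `tmb`, `smoking`, `age`
#'   and optionally `outcome`.
#' @param probs Optional data frame/list with `pT` and/or `ppT` in [0, 1].
#' @return A tibble of factors with stable bin labels.
#' @export
discretize_clinical <- function(clinical, probs = NULL) {
  out <- tibble::tibble(
    pdl1_bin = factor(
      ifelse(clinical$pdl1_score <= 0, "0",
             ifelse(clinical$pdl1_score < 50, "1-49", ">=50")),
      levels = c("0", "1-49", ">=50")),
    tmb_bin = factor(ifelse(clinical$tmb >= 10, ">=10", "<10"),
                     levels = c("<10", ">=10")),
    smoking = factor(as.character(clinical$smoking),
                     levels = c("current", "former", "never")),
    age_bin = factor(paste0(floor(clinical$age / 10) * 10, "-",
                            floor(clinical$age / 10) * 10 + 9),
                     levels = paste0(seq(0, 110, 10), "-", seq(9, 119, 10)))
  )
  out$age_bin <- droplevels(out$age_bin)
  if ("outcome" %in% colnames(clinical)) {
    out$outcome <- factor(as.integer(clinical$outcome), levels = c(0, 1))
  }
  if (!is.null(probs)) {
    probs <- as.data.frame(probs)
    for (nm in intersect(c("pT", "ppT"), colnames(probs))) {
      out[[nm]] <- factor(ifelse(probs[[nm]] >= 0.7, "high", "low"),
                          levels = c("low", "high"))
    }
  }
  out
}

# per-node family BDeu score: sum over parent configurations of the
# Dirichlet-multinomial log marginal likelihood with alpha_ijk = ess/(q r)
family_bdeu <- function(data, node, parents, ess) {
  x <- factor(data[[node]])
  r <- nlevels(x)
  if (length(parents) == 0) {
    counts <- table(x)
    q <- 1L
    counts <- matrix(as.numeric(counts), nrow = 1)
  } else {
    pf <- interaction(lapply(parents, function(p) factor(data[[p]])),
                      drop = FALSE, lex.order = TRUE)
    q <- nlevels(pf)
    counts <- as.matrix(table(pf, x))  # q rows, r cols
  }
  a_ijk <- ess / (q * r)
  a_ij <- ess / q
  n_ij <- rowSums(counts)
  sum(lgamma(a_ij) - lgamma(a_ij + n_ij)) +
    sum(lgamma(a_ijk + counts) - lgamma(a_ijk))
}

#' BDeu score of a DAG on categorical data
#'
#' Bayesian Dirichlet equivalent uniform log marginal likelihood with
#' uniform hyperparameters `ess / (q_i * r_i)`; decomposes as a sum of
#' per-node family scores.
#'
#' @param dag Edge tibble (`from`, `to`) or `clinical_dag`; nodes are the
#'   data columns.
#' @param data Data frame of categorical variables.
#' @param ess Equivalent sample size (> 0).
#' @return The log score (numeric scalar).
#' @export
bdeu_score <- function(dag, data, ess = 1.0) {
  if (ess <= 0) abort("ess must be positive")
  edges <- dag_edges(dag)
  nodes <- colnames(data)
  if (!all(unlist(edges) %in% nodes)) abort("dag mentions unknown variables")
  sum(vapply(nodes, function(v) {
    family_bdeu(data, v, edges$from[edges$to == v], ess)
  }, numeric(1)))
}

edge_key <- function(edges) paste(edges$from, edges$to, sep = "->")

#' Hill-climbing Bayesian network structure search under the BDeu score
#'
#' Greedy local search over single-edge moves (add, delete, reverse),
#' applying the best strictly score-improving acyclic move until a local
#' optimum or `max_iter` moves. Candidate moves are enumerated in a fixed
#' lexicographic order (move type, then endpoints), which, with the
#' decomposable score, makes the search fully deterministic.
#'
#' @param data Data frame of categorical variables (>= 2 columns).
#' @param ess Equivalent sample size.
#' @param max_iter Maximum number of accepted moves.
#' @param blacklist,whitelist Optional edge tibbles (`from`, `to`):
#'   forbidden edges and edges fixed in the structure.
#' @return A list of class `bnsl`: `dag` (edge tibble), `score`, `nodes`,
#'   `iterations`.
#' @export
hill_climb_search <- function(data, ess = 1.0, max_iter = 100,
                              blacklist = NULL, whitelist = NULL) {
  nodes <- colnames(data)
  if (length(nodes) < 2) abort("need at least 2 variables")
  if (!all(vapply(data, function(c) is.factor(c) || is.character(c), logical(1)))) {
    abort("all variables must be categorical")
  }
  data <- as.data.frame(lapply(data, factor))

  edges <- whitelist %||% tibble::tibble(from = character(0), to = character(0))
  black <- if (!is.null(blacklist)) edge_key(blacklist) else character(0)
  white <- if (!is.null(whitelist)) edge_key(whitelist) else character(0)

  fam_cache <- new.env(parent = emptyenv())
  fam_score <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(fam_cache[[key]])) {
      fam_cache[[key]] <- family_bdeu(data, node, parents, ess)
    }
    fam_cache[[key]]
  }
  parents_of <- function(edges, v) edges$from[edges$to == v]

  iterations <- 0L
  repeat {
    cur_key <- edge_key(edges)
    best_delta <- 0
    best_edges <- NULL
    # candidate moves in lexicographic order: add, delete, reverse
    pairs <- expand.grid(from = sort(nodes), to = sort(nodes),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[order(pairs$from, pairs$to), ]
    for (move in c("add", "delete", "reverse")) {
      for (i in seq_len(nrow(pairs))) {
        u <- pairs$from[i]; v <- pairs$to[i]
        k <- paste(u, v, sep = "->")
        present <- k %in% cur_key
        if (move == "add") {
          if (present || k %in% black) next
          if (paste(v, u, sep = "->") %in% cur_key) next
          new_edges <- dplyr::bind_rows(edges, tibble::tibble(from = u, to = v))
          delta <- fam_score(v, c(parents_of(edges, v), u)) -
            fam_score(v, parents_of(edges, v))
        } else if (move == "delete") {
          if (!present || k %in% white) next
          new_edges <- edges[!(edges$from == u & edges$to == v), ]
          delta <- fam_score(v, setdiff(parents_of(edges, v), u)) -
            fam_score(v, parents_of(edges, v))
        } else {
          if (!present || k %in% white) next
          if (paste(v, u, sep = "->") %in% black) next
          new_edges <- edges[!(edges$from == u & edges$to == v), ]
          new_edges <- dplyr::bind_rows(new_edges, tibble::tibble(from = v, to = u))
          delta <- (fam_score(v, setdiff(parents_of(edges, v), u)) -
                      fam_score(v, parents_of(edges, v))) +
            (fam_score(u, c(parents_of(edges, u), v)) -
               fam_score(u, parents_of(edges, u)))
        }
        if (delta > best_delta + 1e-12 && is_acyclic(new_edges, nodes)) {
          best_delta <- delta
          best_edges <- new_edges
        }
      }
    }
    if (is.null(best_edges) || iterations >= max_iter) break
    edges <- best_edges
    iterations <- iterations + 1L
  }
  structure(list(dag = tibble::as_tibble(edges),
                 score = bdeu_score(edges, data, ess),
                 nodes = nodes, ess = ess, iterations = iterations),
            class = "bnsl")
}

#' @export
print.bnsl <- function(x, ...) {
  cat(sprintf("<bnsl> %d nodes, %d edges, BDeu score %.3f (%d moves)\n",
              length(x$nodes), nrow(x$dag), x$score, x$iterations))
  if (nrow(x$dag)) {
    cat(paste0("  ", x$dag$from, " -> ", x$dag$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Attach pT / ppT as children of the outcome node
#'
#' The discretized response probabilities are added as conditionally
#' dependent variables of treatment outcome (the out-of-structure mode);
#' the in-structure mode instead includes them in the search itself and
#' skips this step.
#'
#' @param bnsl_fit A `bnsl` object (or edge tibble with a `nodes` attr).
#' @param outcome Name of the outcome node.
#' @return The modified `bnsl` object with nodes `pT`, `ppT` each having
#'   the single parent `outcome`.
#' @export
attach_probability_nodes <- function(bnsl_fit, outcome = "outcome") {
  if (any(c("pT", "ppT") %in% bnsl_fit$nodes)) {
    abort("dag already contains pT/ppT nodes")
  }
  bnsl_fit$dag <- dplyr::bind_rows(
    bnsl_fit$dag,
    tibble::tibble(from = outcome, to = c("pT", "ppT")))
  bnsl_fit$nodes <- c(bnsl_fit$nodes, "pT", "ppT")
  bnsl_fit$score <- NA_real_  # stale until rescored on the extended table
  bnsl_fit
}

#' Fit conditional probability tables on a DAG
#'
#' Posterior-mean (Laplace-style Dirichlet) CPT estimates with
#' hyperparameter `ess / (q_i * r_i)` per cell, so no configuration has
#' probability zero at prediction time.
#'
#' @param bnsl_fit A `bnsl` object whose nodes are columns of `data`.
#' @param data Categorical data frame.
#' @param ess Equivalent sample size for smoothing.
#' @return A list of class `bayes_classifier` with per-node CPTs.
#' @export
fit_bayes_classifier <- function(bnsl_fit, data, ess = 1.0) {
  nodes <- bnsl_fit$nodes
  data <- as.data.frame(lapply(as.data.frame(data)[, nodes, drop = FALSE], factor))
  edges <- bnsl_fit$dag
  cpts <- list()
  for (v in nodes) {
    parents <- edges$from[edges$to == v]
    lv <- levels(data[[v]])
    r <- length(lv)
    if (length(parents) == 0) {
      q <- 1L
      counts <- matrix(as.numeric(table(data[[v]])), nrow = 1,
                       dimnames = list(NULL, lv))
      pconfigs <- NULL
    } else {
      pf <- interaction(lapply(parents, function(p) data[[p]]),
                        drop = FALSE, lex.order = TRUE)
      q <- nlevels(pf)
      counts <- as.matrix(table(pf, data[[v]]))
      pconfigs <- levels(pf)
    }
    a <- ess / (q * r)
    prob <- (counts + a) / rowSums(counts + a)
    cpts[[v]] <- list(parents = parents, levels = lv, prob = prob,
                      pconfigs = pconfigs)
  }
  structure(list(cpts = cpts, dag = edges, nodes = nodes),
            class = "bayes_classifier")
}

node_prob <- function(cpt, value, parent_values) {
  if (length(cpt$parents) == 0) {
    cpt$prob[1, value]
  } else {
    cfg <- paste(parent_values, collapse = ".")
    cpt$prob[cfg, value]
  }
}

#' Predict the outcome posterior by exact inference
#'
#' Computes `P(target | evidence)` on the small discrete network by
#' enumerating the joint over unobserved variables.
#'
#' @param object A `bayes_classifier`.
#' @param newdata Data frame of evidence (columns = observed variables,
#'   values = categories); variables absent from the network are an error,
#'   network variables absent from the data are marginalized.
#' @param target Target variable (default `"outcome"`).
#' @param ... Unused.
#' @return Numeric vector: posterior probability of the target's last
#'   level (`"1"` for a 0/1 outcome) per row.
#' @export
predict.bayes_classifier <- function(object, newdata, target = "outcome", ...) {
  newdata <- as.data.frame(newdata)
  unknown <- setdiff(colnames(newdata), object$nodes)
  if (length(unknown)) {
    abort(paste("evidence variables not in network:", paste(unknown, collapse = ", ")))
  }
  evid_vars <- setdiff(intersect(object$nodes, colnames(newdata)), target)
  free_vars <- setdiff(object$nodes, c(evid_vars, target))
  target_lv <- object$cpts[[target]]$levels

  joint_for <- function(assign_list) {
    p <- 1
    for (v in object$nodes) {
      cpt <- object$cpts[[v]]
      p <- p * node_prob(cpt, assign_list[[v]],
                         unlist(assign_list[cpt$parents], use.names = FALSE))
    }
    p
  }

  free_grid <- if (length(free_vars)) {
    expand.grid(lapply(setNames(free_vars, free_vars),
                       function(v) object$cpts[[v]]$levels),
                stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1)
  }

  vapply(seq_len(nrow(newdata)), function(i) {
    evid <- lapply(setNames(evid_vars, evid_vars),
                   function(v) as.character(newdata[[v]][i]))
    mass <- setNames(numeric(length(target_lv)), target_lv)
    for (tl in target_lv) {
      tot <- 0
      for (g in seq_len(max(nrow(free_grid), 1))) {
        assign_list <- c(evid, list(), setNames(list(tl), target))
        if (length(free_vars)) {
          assign_list <- c(assign_list,
                           lapply(setNames(free_vars, free_vars),
                                  function(v) free_grid[[v]][g]))
        }
        tot <- tot + joint_for(assign_list)
      }
      mass[tl] <- tot
    }
    unname(mass[length(target_lv)] / sum(mass))
  }, numeric(1))
}
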