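#' Directed acyclic graph with conditional probability tables
#'
#' Ground-truth generative structure for the synthetic clinical table. Each
#' node carries its categorical levels, its parents, and a conditional
#' table: a probability vector for root nodes, or a matrix with one column
#' per parent configuration (columns ordered as
#' `interaction(parent factors)`) and one row per own level.
#'
#' @param nodes Named list; each element a list with `levels` (character),
#'   `parents` (character, possibly empty) and `cpt`.
#' @return An object of class `clinical_dag`.
#' @export
clinical_dag <- function(nodes) {
  edges <- dag_edges_from_nodes(nodes)
  ord <- topological_order(edges, names(nodes))  # errors on cycles
  for (v in names(nodes)) {
    node <- nodes[[v]]
    if (length(node$parents) == 0) {
      if (abs(sum(node$cpt) - 1) > 1e-8) {
        abort(sprintf("marginal table of '%s' does not sum to 1", v))
      }
    } else {
      if (!all(abs(colSums(node$cpt) - 1) < 1e-8)) {
        abort(sprintf("conditional table of '%s' has columns not summing to 1", v))
      }
    }
  }
  structure(list(nodes = nodes, order = ord), class = "clinical_dag")
}

dag_edges_from_nodes <- function(nodes) {
  out <- list()
  for (v in names(nodes)) {
    for (p in nodes[[v]]$parents) {
      out[[length(out) + 1L]] <- c(p, v)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(from = character(0), to = character(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(from = m[, 1], to = m[, 2])
}

#' Edge list of a DAG
#'
#' @param dag A `clinical_dag`, a `bnsl` fit, or an edge tibble (returned
#'   unchanged).
#' @return A tibble with columns `from`, `to`.
#' @export
dag_edges <- function(dag) {
  if (inherits(dag, "clinical_dag")) {
    dag_edges_from_nodes(dag$nodes)
  } else if (inherits(dag, "bnsl")) {
    dag$dag
  } else {
    dag
  }
}

# Kahn's algorithm; errors when the edge set has a cycle
topological_order <- function(edges, nodes) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges$to[i]] <- indeg[edges$to[i]] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg_w <- indeg
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- edges$to[edges$from == v]
    for (c in ch) {
      indeg_w[c] <- indeg_w[c] - 1L
      if (indeg_w[c] == 0L) avail <- sort(c(avail, c))
    }
  }
  if (length(order) != length(nodes)) abort("graph is cyclic")
  order
}

is_acyclic <- function(edges, nodes) {
  !inherits(try(topological_order(edges, nodes), silent = TRUE), "try-error")
}

#' Default generative clinical DAG
#'
#' Emulates an advanced-NSCLC immunotherapy cohort: treatment outcome is a
#' root with the configured responder fraction; PD-L1 bin and TMB bin are
#' children of outcome (responders enriched for PD-L1 >= 50 and TMB >= 10);
#' smoking status, sex and decade age bins are independent with cohort-like
#' marginals. The real cohort's TMB is nearly degenerate (99% of patients
#' >= 10 mut/Mb); the generator keeps a usable minority fraction so the
#' variable can participate in structure learning.
#'
#' @param responder_fraction Marginal probability of outcome = 1.
#' @return A `clinical_dag`.
#' @export
default_clinical_dag <- function(responder_fraction = 51 / 187) {
  clinical_dag(list(
    outcome = list(levels = c("0", "1"), parents = character(0),
                   cpt = c(1 - responder_fraction, responder_fraction)),
    pdl1_bin = list(
      levels = c("0", "1-49", ">=50"), parents = "outcome",
      cpt = matrix(c(0.58, 0.20, 0.22,   # outcome = 0
                     0.28, 0.14, 0.58),  # outcome = 1
                   nrow = 3, dimnames = list(c("0", "1-49", ">=50"), c("0", "1")))),
    tmb_bin = list(
      levels = c("<10", ">=10"), parents = "outcome",
      cpt = matrix(c(0.25, 0.75,
                     0.08, 0.92),
                   nrow = 2, dimnames = list(c("<10", ">=10"), c("0", "1")))),
    smoking = list(levels = c("current", "former", "never"),
                   parents = character(0), cpt = c(0.64, 0.24, 0.12)),
    sex = list(levels = c("male", "female"), parents = character(0),
               cpt = c(0.46, 0.54)),
    age_bin = list(levels = c("30-39", "40-49", "50-59", "60-69", "70-79",
                              "80-89", "90-99"),
                   parents = character(0),
                   cpt = c(0.03, 0.08, 0.20, 0.33, 0.25, 0.09, 0.02))
  ))
}

#' Edgeless DAG over the default clinical variables
#'
#' Null-case generator: same variables and marginals as
#' [default_clinical_dag()] but with every dependence removed, so the
#' clinical table carries no outcome signal.
#'
#' @param responder_fraction Marginal probability of outcome = 1.
#' @return A `clinical_dag` with no edges.
#' @export
edgeless_clinical_dag <- function(responder_fraction = 51 / 187) {
  d <- default_clinical_dag(responder_fraction)
  nodes <- d$nodes
  nodes$pdl1_bin$parents <- character(0)
  nodes$pdl1_bin$cpt <- c(0.50, 0.18, 0.32)
  nodes$tmb_bin$parents <- character(0)
  nodes$tmb_bin$cpt <- c(0.2, 0.8)
  clinical_dag(nodes)
}
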