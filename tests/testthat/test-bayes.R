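test_that("discretization follows the cohort-table bin conventions", {
  clin <- data.frame(pdl1_score = c(0, 0.5, 49.9, 50, 80),
                     tmb = c(9.9, 10, 15, 2, 30),
                     smoking = c("current", "former", "never", "current", "former"),
                     age = c(68, 60, 69, 38, 93),
                     outcome = c(1, 0, 1, 0, 1))
  d <- discretize_clinical(clin, probs = data.frame(pT = c(0.71, 0.7, 0.69, 0.2, 0.9),
                                                    ppT = c(0.1, 0.9, 0.5, 0.7, 0.3)))
  expect_equal(as.character(d$pdl1_bin), c("0", "1-49", "1-49", ">=50", ">=50"))
  expect_equal(as.character(d$tmb_bin), c("<10", ">=10", ">=10", "<10", ">=10"))
  expect_equal(as.character(d$age_bin)[1], "60-69")
  expect_equal(as.character(d$age_bin)[4], "30-39")
  # 0.7 boundary goes high by the >= convention; 0.69 stays low
  expect_equal(as.character(d$pT), c("high", "high", "low", "low", "high"))
  expect_equal(as.character(d$ppT)[4], "high")
})

test_that("BDeu matches the Dirichlet-multinomial oracle", {
  # single binary variable, data {1, 0}, ess = 1: hand-computable marginal
  dat1 <- data.frame(a = factor(c("1", "0")))
  no_edges <- tibble::tibble(from = character(0), to = character(0))
  got <- bdeu_score(no_edges, dat1, ess = 1)
  want <- lgamma(1) - lgamma(1 + 2) + 2 * (lgamma(0.5 + 1) - lgamma(0.5))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, oracle_bdeu(no_edges, dat1, 1), tolerance = 1e-12)

  # random small tables, up to 3 binary variables, several DAGs
  set.seed(3)
  for (k in 1:5) {
    dat <- data.frame(a = factor(sample(0:1, 10, TRUE)),
                      b = factor(sample(0:1, 10, TRUE)),
                      c = factor(sample(0:1, 10, TRUE)))
    dags <- list(
      no_edges,
      tibble::tibble(from = "a", to = "b"),
      tibble::tibble(from = c("a", "b"), to = c("b", "c")),
      tibble::tibble(from = c("a", "c"), to = c("b", "b")))
    for (dg in dags) {
      expect_equal(bdeu_score(dg, dat, ess = 1), oracle_bdeu(dg, dat, 1),
                   tolerance = 1e-10)
      expect_equal(bdeu_score(dg, dat, ess = 2.5), oracle_bdeu(dg, dat, 2.5),
                   tolerance = 1e-10)
    }
  }
  expect_error(bdeu_score(no_edges, dat1, ess = 0), "positive")
})

test_that("an edge from independent noise lowers the BDeu score at large n", {
  set.seed(4)
  dat <- data.frame(x = factor(sample(0:1, 5000, TRUE)),
                    y = factor(sample(0:1, 5000, TRUE)))
  s0 <- bdeu_score(tibble::tibble(from = character(0), to = character(0)), dat)
  s1 <- bdeu_score(tibble::tibble(from = "x", to = "y"), dat)
  expect_lt(s1, s0)
})

test_that("hill climbing returns a self-consistent local optimum", {
  set.seed(5)
  a <- sample(0:1, 800, TRUE)
  b <- ifelse(runif(800) < 0.85, a, 1 - a)
  dat <- data.frame(a = factor(a), b = factor(b))
  fit <- hill_climb_search(dat)
  expect_equal(fit$score, bdeu_score(fit$dag, dat), tolerance = 1e-10)
  expect_equal(nrow(fit$dag), 1)  # one dependence found

  # independent variables: empty graph
  set.seed(6)
  ind <- data.frame(a = factor(sample(0:1, 2000, TRUE)),
                    b = factor(sample(0:1, 2000, TRUE)),
                    c = factor(sample(0:1, 2000, TRUE)))
  fit0 <- hill_climb_search(ind)
  expect_equal(nrow(fit0$dag), 0)
  expect_error(hill_climb_search(data.frame(a = factor(0:1))), "at least 2")
  expect_error(hill_climb_search(data.frame(a = 1:5, b = 2:6)), "categorical")
})

test_that("a planted chain is recovered as the correct skeleton", {
  skeleton_of <- function(edges) {
    sort(apply(cbind(pmin(edges$from, edges$to), pmax(edges$from, edges$to)),
               1, paste, collapse = "-"))
  }
  hits <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- 5000
    a <- sample(0:1, n, TRUE)
    b <- ifelse(runif(n) < 0.9, a, 1 - a)
    c <- ifelse(runif(n) < 0.9, b, 1 - b)
    dat <- data.frame(a = factor(a), b = factor(b), c = factor(c))
    fit <- hill_climb_search(dat)
    hits <- hits + identical(skeleton_of(fit$dag), c("a-b", "b-c"))
  }
  expect_gte(hits, 5)
})

test_that("blacklisted edges are never added", {
  set.seed(7)
  a <- sample(0:1, 1500, TRUE)
  b <- ifelse(runif(1500) < 0.9, a, 1 - a)
  dat <- data.frame(a = factor(a), b = factor(b))
  bl <- tibble::tibble(from = c("a", "b"), to = c("b", "a"))
  fit <- hill_climb_search(dat, blacklist = bl)
  expect_equal(nrow(fit$dag), 0)
})

test_that("probability nodes attach as children of outcome only", {
  fit <- list(dag = tibble::tibble(from = "pdl1_bin", to = "outcome"),
              nodes = c("pdl1_bin", "outcome"), score = -10)
  class(fit) <- "bnsl"
  ext <- attach_probability_nodes(fit)
  expect_setequal(ext$dag$to[ext$dag$from == "outcome"], c("pT", "ppT"))
  expect_equal(sum(ext$dag$to == "pT"), 1)
  expect_equal(sum(ext$dag$to == "ppT"), 1)
  expect_error(attach_probability_nodes(ext), "already")
})

test_that("the Bayes classifier performs exact inference", {
  # direct lookup: A -> outcome with a strong CPT and n large enough that
  # the smoothed posterior-mean CPT is close to the sample rates
  set.seed(8)
  n <- 4000
  a <- sample(0:1, n, TRUE)
  y <- ifelse(a == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.2))
  dat <- data.frame(a = factor(a), outcome = factor(y))
  fit <- list(dag = tibble::tibble(from = "a", to = "outcome"),
              nodes = c("a", "outcome"))
  class(fit) <- "bnsl"
  clf <- fit_bayes_classifier(fit, dat, ess = 1)
  p1 <- predict(clf, data.frame(a = "1"))
  expect_equal(p1, mean(y[a == 1]), tolerance = 0.02)
  # no evidence: outcome marginal
  p_marg <- predict(clf, data.frame(row.names = 1))
  expect_equal(p_marg, mean(y), tolerance = 0.02)
  expect_error(predict(clf, data.frame(zzz = "1")), "not in network")
})

test_that("predictions match brute-force joint enumeration on a 4-node net", {
  set.seed(9)
  n <- 500
  a <- sample(0:1, n, TRUE)
  b <- ifelse(runif(n) < 0.7, a, 1 - a)
  y <- ifelse((a + b) > 0, rbinom(n, 1, 0.8), rbinom(n, 1, 0.3))
  d <- ifelse(runif(n) < 0.6, y, rbinom(n, 1, 0.5))
  dat <- data.frame(a = factor(a), b = factor(b),
                    outcome = factor(y), d = factor(d))
  fit <- list(dag = tibble::tibble(from = c("a", "a", "b", "outcome"),
                                   to = c("b", "outcome", "outcome", "d")),
              nodes = c("a", "b", "outcome", "d"))
  class(fit) <- "bnsl"
  clf <- fit_bayes_classifier(fit, dat, ess = 1)

  prob_fun <- function(v, value, parent_values) {
    cpt <- clf$cpts[[v]]
    if (length(cpt$parents) == 0) {
      cpt$prob[1, value]
    } else {
      cpt$prob[paste(parent_values, collapse = "."), value]
    }
  }
  parents <- lapply(setNames(fit$nodes, fit$nodes),
                    function(v) fit$dag$from[fit$dag$to == v])
  # partial evidence forces marginalization over b
  for (ev in list(list(a = "1"), list(a = "0", d = "1"), list(d = "0"))) {
    got <- predict(clf, as.data.frame(ev, stringsAsFactors = FALSE))
    want <- oracle_bn_posterior(fit$nodes, parents,
                                lapply(clf$cpts, `[[`, "levels"),
                                prob_fun, ev, "outcome")
    expect_equal(got, unname(want["1"]), tolerance = 1e-12)
  }
})
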