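# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (naive nested loops, direct formulas) and share no
# code path with the package internals they check.

# naive per-voxel Haralick maps: for each voxel, build each offset's GLCM by
# scanning every voxel pair in the truncated window, compute the eight
# statistics from the dense matrix, average over offsets with any pair
oracle_haralick_maps <- function(vol, n_levels, window_radius = 1) {
  d <- dim(vol)
  q <- pmin(pmax(floor(vol * n_levels), 0), n_levels - 1)
  offsets <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  feat_names <- c("Energy", "Entropy", "InverseDifferenceMoment", "Inertia",
                  "ClusterShade", "ClusterProminence", "Correlation",
                  "HaralickCorrelation")
  maps <- lapply(feat_names, function(f) array(0, dim = d))
  names(maps) <- feat_names

  stats_of <- function(p) {
    idx <- which(p > 0, arr.ind = TRUE)
    pv <- p[idx]
    i <- idx[, 1] - 1
    j <- idx[, 2] - 1
    mu <- sum(i * pv)
    sigma2 <- sum((i - mu)^2 * pv)
    corr <- if (sigma2 > 1e-12) sum((i - mu) * (j - mu) * pv) / sigma2 else 0
    c(Energy = sum(pv^2),
      Entropy = -sum(pv * log2(pv)),
      InverseDifferenceMoment = sum(pv / (1 + (i - j)^2)),
      Inertia = sum((i - j)^2 * pv),
      ClusterShade = sum((i + j - 2 * mu)^3 * pv),
      ClusterProminence = sum((i + j - 2 * mu)^4 * pv),
      Correlation = corr,
      HaralickCorrelation = sum((i + 1) * (j + 1) * pv))
  }

  r <- window_radius
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    x0 <- max(1, x - r); x1 <- min(d[1], x + r)
    y0 <- max(1, y - r); y1 <- min(d[2], y + r)
    z0 <- max(1, z - r); z1 <- min(d[3], z + r)
    acc <- setNames(numeric(8), feat_names)
    n_ok <- 0
    for (o in seq_len(nrow(offsets))) {
      g <- matrix(0, n_levels, n_levels)
      for (cz in z0:z1) for (cy in y0:y1) for (cx in x0:x1) {
        px <- cx + offsets[o, 1]; py <- cy + offsets[o, 2]; pz <- cz + offsets[o, 3]
        if (px < x0 || px > x1 || py < y0 || py > y1 || pz < z0 || pz > z1) next
        a <- q[cx, cy, cz] + 1; b <- q[px, py, pz] + 1
        g[a, b] <- g[a, b] + 1
        g[b, a] <- g[b, a] + 1
      }
      if (sum(g) > 0) {
        acc <- acc + stats_of(g / sum(g))
        n_ok <- n_ok + 1
      }
    }
    if (n_ok > 0) {
      for (f in feat_names) maps[[f]][x, y, z] <- acc[[f]] / n_ok
    }
  }
  maps
}

# direct Dirichlet-multinomial log marginal likelihood of a DAG:
# per node, per parent configuration, log[ Gamma(a)/Gamma(a+n) *
# prod_k Gamma(a/r + n_k)/Gamma(a/r) ] with a = ess/q
oracle_bdeu <- function(edges, data, ess = 1) {
  data <- as.data.frame(lapply(data, factor))
  total <- 0
  for (v in colnames(data)) {
    parents <- edges$from[edges$to == v]
    r <- nlevels(data[[v]])
    if (length(parents) == 0) {
      q <- 1
      configs <- list(rep(TRUE, nrow(data)))
    } else {
      grids <- expand.grid(lapply(parents, function(p) levels(data[[p]])),
                           stringsAsFactors = FALSE)
      q <- nrow(grids)
      configs <- lapply(seq_len(q), function(g) {
        sel <- rep(TRUE, nrow(data))
        for (k in seq_along(parents)) {
          sel <- sel & (as.character(data[[parents[k]]]) == grids[g, k])
        }
        sel
      })
    }
    a_ij <- ess / q
    a_ijk <- ess / (q * r)
    for (sel in configs) {
      nk <- as.numeric(table(factor(data[[v]][sel], levels = levels(data[[v]]))))
      total <- total + lgamma(a_ij) - lgamma(a_ij + sum(nk)) +
        sum(lgamma(a_ijk + nk) - lgamma(a_ijk))
    }
  }
  total
}

# two-group log-rank by the event-time 2x2 table construction
oracle_logrank <- function(times, events, group) {
  group <- as.integer(factor(group)) - 1L
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# AUC as the exhaustive Mann-Whitney pair count with half-credit for ties
oracle_auc <- function(prob, label) {
  pos <- prob[label == 1]
  neg <- prob[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# joint-enumeration posterior for a discrete Bayes net given full CPT specs:
# cpts is a list per node: list(parents, levels, prob) with prob indexed as
# prob[[paste(parent values, collapse=".")]] -> named prob vector
oracle_bn_posterior <- function(nodes, parents, levels, prob_fun, evidence,
                                target) {
  free <- setdiff(nodes, c(names(evidence), target))
  grid <- expand.grid(c(
    setNames(lapply(free, function(v) levels[[v]]), free),
    setNames(list(levels[[target]]), target)), stringsAsFactors = FALSE)
  joint <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(as.list(grid[g, , drop = FALSE]), evidence)
    p <- 1
    for (v in nodes) {
      p <- p * prob_fun(v, assign_all[[v]],
                        unlist(assign_all[parents[[v]]], use.names = FALSE))
    }
    joint[g] <- p
  }
  mass <- tapply(joint, grid[[target]], sum)
  mass / sum(mass)
}
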