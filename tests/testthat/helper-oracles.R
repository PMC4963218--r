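# Independent brute-force oracles used to cross-check the implementation.

# Dihedral via normal-vector cosine + sign of the triple product
# (different route from the atan2 formula in the package).
oracle_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  x <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                        u[3] * v[1] - u[1] * v[3],
                        u[1] * v[2] - u[2] * v[1])
  n1 <- x(b1, b2); n2 <- x(b2, b3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  s <- sum(x(n1, n2) * b2)
  if (s < 0) -ang else ang
}

# O(n^2) clash oracle with hand-rolled BFS bond distances.
oracle_clashes <- function(conf, overlap_factor = 0.5, depth = 3L) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  at <- conf$atoms
  n <- nrow(at)
  adj <- vector("list", n)
  for (r in seq_len(nrow(conf$bonds))) {
    i <- conf$bonds[r, 1]; j <- conf$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  bond_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) if (d[w] > d[v] + 1) {
        d[w] <- d[v] + 1; nxt <- c(nxt, w)
      }
      frontier <- unique(nxt)
    }
    d
  }
  bd <- t(vapply(seq_len(n), bond_dist, numeric(n)))
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                       c(at$x[j], at$y[j], at$z[j]))^2))
    thr <- overlap_factor * (vdw[at$element[i]] + vdw[at$element[j]])
    if (dij < thr && bd[i, j] > depth) {
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(0, 0, 2)
}

# Straight-line reference-statistics oracle: restrict standards,
# re-reference by explicit arithmetic, Tukey fences (type-7 quartiles),
# then mean/sd.
oracle_ref_stats <- function(obs, residue, nucleus) {
  g <- obs[obs$residue == residue & obs$nucleus == nucleus, ]
  g <- g[g$standard %in% c("DSS", "TMS", "TSP"), ]
  v <- ifelse(g$standard == "TSP", g$value + 0.12,
              ifelse(g$standard == "TMS", g$value - 1.7, g$value))
  q1 <- unname(quantile(v, 0.25, type = 7))
  q3 <- unname(quantile(v, 0.75, type = 7))
  lo <- q1 - 1.5 * (q3 - q1); hi <- q3 + 1.5 * (q3 - q1)
  kept <- v[v >= lo & v <= hi]
  list(mean = mean(kept), sd = sd(kept), n_kept = length(kept),
       n_removed = length(v) - length(kept))
}

# Point-mass posterior draws for closed-form probability-profile checks.
collapsed_draws <- function(muA, muB, sigma = 1, n = 50) {
  structure(list(
    A = data.frame(mu = rep(muA, n), sigma = rep(sigma, n), nu = 30),
    B = data.frame(mu = rep(muB, n), sigma = rep(sigma, n), nu = 30),
    diagnostics = data.frame(),
    spec = list(state_priors = c(0.5, 0.5),
                states = list(A = list(samples = muA), B = list(samples = muB)))
  ), class = "posterior_draws")
}

# Small helper: a quick Lys pair shared by several tests.
tiny_lys_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_paired_ensembles(ptm_state("LYS", "monomethyl"),
                                          n_backbones = 25, seed = 123)
    }
    cache
  }
})
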