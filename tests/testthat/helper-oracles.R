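# Independent oracles used to freeze expected values. These deliberately
# avoid the package's closed-form expressions: distances are accumulated by
# stepping node by node, ECDFs come from stats::ecdf, and null
# distributions from full enumeration.

# Effective nodal distance to a bud: +1 per node stepped (primary-stem
# nodes proximal to the decay origin are free), +L per branch junction.
oracle_exponent <- function(path, L, decay_origin = 1) {
  e <- 0
  for (i in seq_along(path)) {
    if (i > 1) e <- e + L
    for (j in seq_len(path[i])) {
      if (i > 1 || j >= decay_origin) e <- e + 1
    }
  }
  e
}

# NRS by repeated multiplication (no ^ operator).
oracle_power <- function(R, k) {
  out <- 1
  k <- as.integer(round(k))
  while (k > 0) { out <- out * R; k <- k - 1L }
  out
}

# Full shoot-system enumeration from first principles: AL from the oracle
# exponent, classification spelled out, children enumerated under the
# capacity rules. Returns one row per position.
oracle_enumerate <- function(R, L, n_primary, thr_branch, thr_short,
                             plus_op = TRUE, decay_origin = 1,
                             excised = integer(0), cap = 2) {
  rows <- list()
  rec <- function(prefix, stem_len, skip) {
    for (j in seq_len(stem_len)) {
      if (j %in% skip) next
      p <- c(prefix, j)
      n <- length(p)
      ex <- oracle_exponent(p, L, decay_origin)
      if (plus_op && n >= 2) ex <- ex + oracle_exponent(p[-n], L, decay_origin)
      al <- 100 * oracle_power(R, ex)
      cat0 <- if (al >= thr_branch) "branch"
              else if (al >= thr_short) "short_shoot" else "unemerged"
      structural <- max(0, stem_len - j - L)
      eff <- switch(cat0, branch = structural,
                    short_shoot = min(cap, structural), unemerged = 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        path = paste(p, collapse = "."), len = n, b1 = p[1],
        al = al, category = cat0, eff = eff, stringsAsFactors = FALSE)
      if (eff > 0) rec(p, eff, integer(0))
    }
  }
  rec(integer(0), n_primary, excised)
  d <- do.call(rbind, rows)
  parent <- sub("\\.[0-9]+$", "", d$path)
  parent[!grepl("\\.", d$path)] <- ""
  has_branch_child <- d$path %in% parent[d$category == "branch"]
  d$branched <- d$category == "branch" & has_branch_child
  d
}

oracle_ks_D <- function(x, y) {
  s <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
  max(abs(Fx(s) - Fy(s)))
}

# Exact permutation null by full enumeration of partitions of the pool.
oracle_exact_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  d_obs <- oracle_ks_D(x, y)
  idx <- utils::combn(n, length(x))
  d_star <- apply(idx, 2L, function(i) oracle_ks_D(pooled[i], pooled[-i]))
  mean(d_star >= d_obs - 1e-12)
}
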