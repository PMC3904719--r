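#' Discrete two-sample Kolmogorov-Smirnov comparison
#'
#' Predicted and observed branching phenotypes are compared as samples of
#' primary-stem node positions: each counted outgrowth contributes one
#' observation of the node position it arises from. Because node positions
#' are small integers the samples are heavily tied, so the classical
#' continuous-case null distribution of the KS statistic does not apply;
#' instead the null is generated by re-partitioning the pooled sample
#' (exactly, by enumerating all partitions, or by Monte Carlo
#' permutation), which is assumption-free on discrete support.
#'
#' `counts_to_sample()` expands a phenotype count table into the multiset
#' of node positions (one entry per counted outgrowth).
#'
#' `ks_statistic()` computes `D`, the maximum absolute difference between
#' the two empirical cumulative distribution functions, evaluated as
#' right-continuous step functions over the union support.
#'
#' `discrete_ks_test()` computes `D` and its permutation p-value. The
#' exact method enumerates all `choose(n, n_x)` assignments of the pooled
#' values (limited to total `n <= 12`) and reports the fraction attaining
#' `D* >= D`. The permutation method draws `n_permutations` random
#' re-partitions and applies the add-one correction
#' `p = (1 + #\{D* >= D\}) / (1 + n_permutations)`, which avoids reporting
#' p = 0. Tie handling is automatic: the ECDFs are compared on the
#' discrete support itself.
#'
#' @param table A phenotype count table with `primary_node` and `count`
#'   columns.
#' @param x,y Integer samples (e.g. node positions), both non-empty.
#' @param method `"permutation"` (default) or `"exact"`.
#' @param n_permutations Number of random re-partitions for the
#'   permutation method.
#' @param seed Integer seed for the permutation method; the global RNG
#'   state is preserved. Required for reproducible p-values.
#' @return `counts_to_sample()`: an integer vector. `ks_statistic()`: a
#'   number in \[0, 1\]. `discrete_ks_test()`: an object of class
#'   `ks_result` with elements `statistic`, `p.value`, `method`, `n_x`,
#'   `n_y`, `seed`.
#' @examples
#' x <- c(1, 1, 2, 3)
#' y <- c(2, 3, 3, 5)
#' ks_statistic(x, y)
#' discrete_ks_test(x, y, method = "exact")
#' discrete_ks_test(x, y, n_permutations = 2000, seed = 1)
#' @name discrete_ks
NULL

#' @rdname discrete_ks
#' @export
counts_to_sample <- function(table) {
  stopifnot(all(c("primary_node", "count") %in% names(table)))
  if (any(table$count < 0)) stop("counts must be non-negative", call. = FALSE)
  as.integer(rep(table$primary_node, table$count))
}

#' @rdname discrete_ks
#' @export
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  support <- sort(unique(c(x, y)))
  fx <- vapply(support, function(s) mean(x <= s), 0)
  fy <- vapply(support, function(s) mean(y <= s), 0)
  max(abs(fx - fy))
}

# D for a 0/1 assignment of the pooled sample; shared by both null methods
ks_stat_pooled <- function(pooled, in_x) {
  ks_statistic(pooled[in_x], pooled[!in_x])
}

#' @rdname discrete_ks
#' @export
discrete_ks_test <- function(x, y, method = c("permutation", "exact"),
                             n_permutations = 10000, seed = NULL) {
  method <- match.arg(method)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  d_obs <- ks_statistic(x, y)
  tol <- 1e-12
  pooled <- c(x, y)
  if (method == "exact") {
    if (n > 12)
      stop("exact enumeration is limited to total n <= 12; ",
           "use method = 'permutation'", call. = FALSE)
    idx <- utils::combn(n, nx)
    d_star <- apply(idx, 2L, function(i) {
      in_x <- logical(n); in_x[i] <- TRUE
      ks_stat_pooled(pooled, in_x)
    })
    p <- mean(d_star >= d_obs - tol)
  } else {
    if (n_permutations < 1)
      stop("'n_permutations' must be >= 1", call. = FALSE)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      in_x <- logical(n)
      in_x[sample.int(n, nx)] <- TRUE
      if (ks_stat_pooled(pooled, in_x) >= d_obs - tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_permutations)
  }
  structure(list(statistic = d_obs, p.value = p, method = method,
                 n_x = nx, n_y = ny,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Discrete two-sample Kolmogorov-Smirnov test (", x$method, ")\n",
      sep = "")
  cat(sprintf("  D = %.6f, p-value = %.6g  (n_x = %d, n_y = %d%s)\n",
              x$statistic, x$p.value, x$n_x, x$n_y,
              if (!is.na(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}
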