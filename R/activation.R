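#' Bud positions and the activation calculus
#'
#' A bud position is the coordinate path `(b1, ..., bn)` of an axillary bud
#' within the branching tree: `b1` is its node index on the primary stem
#' (numbered acropetally from 1 at the base), `b2` its node index on the
#' secondary branch arising there, and so on. A path of length `n` denotes
#' a bud borne on an order-`n` stem, whose outgrowth would be a branch of
#' order `n + 1`; the primary stem is order 1.
#'
#' `nrs_exponent()` returns the effective nodal distance the NRS has to
#' travel to reach the bud, including the developmental delay `L` incurred
#' at each of the `n - 1` branching-order transitions:
#' `d(b1) + b2 + ... + bn + (n - 1) * L`, where
#' `d(b1) = max(0, b1 - (decay_origin - 1))` applies the decay-origin
#' adjustment to the primary-stem coordinate only.
#'
#' `nrs()` is the relative NRS availability at the bud's emergence,
#' `R^nrs_exponent`, scaled from 1 at the oldest node.
#'
#' `outgrowth_potential()` is the bud's intrinsic responsiveness to NRS, in
#' percent. Buds on the primary stem have OP 100 (their parent apical bud
#' is fully activated). For deeper buds the default `op_mode =
#' "parent_nrs"` sets OP to 100 times the NRS the parent branch's founding
#' bud received at its own emergence; `op_mode = "parent_al"` instead uses
#' that founding bud's full activation level, compounding OP recursively
#' across orders. Both are multiplied by `op_gain`.
#'
#' `activation_level()` is the quantity that decides the bud's fate: under
#' the `"plus_op"` variant it is `nrs * outgrowth_potential`; under
#' `"minus_op"` it is `100 * nrs` (OP plays no role).
#'
#' @param path Integer vector `(b1, ..., bn)` of node indices, all >= 1.
#' @param params A [shoot_params] object.
#' @return A single number: the exponent (non-negative), NRS in (0, 1],
#'   OP in (0, 100], or AL in (0, 100], respectively.
#' @examples
#' p <- species_preset("trifolium_repens")
#' nrs_exponent(c(1, 1), p)        # 1 + 1 + L = 4
#' nrs(c(1, 1), p)                 # 0.78^4
#' outgrowth_potential(c(1, 1), p) # 100 * 0.78: parent founding bud's NRS
#' activation_level(c(1, 1, 1), p) # 100 * 0.78^11
#' @name activation
NULL

check_path <- function(path) {
  if (length(path) < 1L || anyNA(path) || any(path < 1) ||
      any(path != as.integer(path)))
    stop("'path' must be a vector of positive integer node indices",
         call. = FALSE)
  as.integer(path)
}

#' @rdname activation
#' @export
nrs_exponent <- function(path, params) {
  path <- check_path(path)
  n <- length(path)
  d1 <- max(0L, path[1L] - (params$decay_origin - 1L))
  d1 + (if (n > 1L) sum(path[-1L]) else 0L) + (n - 1L) * params$delay
}

#' @rdname activation
#' @export
nrs <- function(path, params) {
  params$common_ratio^nrs_exponent(path, params)
}

#' @rdname activation
#' @export
outgrowth_potential <- function(path, params) {
  path <- check_path(path)
  n <- length(path)
  if (n == 1L) return(100)
  parent <- path[-n]
  if (params$op_mode == "parent_nrs") {
    params$op_gain * 100 * nrs(parent, params)
  } else {
    params$op_gain * activation_level(parent, params)
  }
}

#' @rdname activation
#' @export
activation_level <- function(path, params) {
  if (params$variant == "minus_op") {
    100 * nrs(path, params)
  } else {
    nrs(path, params) * outgrowth_potential(path, params)
  }
}
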