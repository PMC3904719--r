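#' Structural node capacity of an outgrowth
#'
#' A branch forming from a fully activated bud carries fewer nodes than the
#' stem bearing it distal to its point of attachment, because of the
#' developmental delay `L`: an outgrowth at node `node_index` of a stem
#' with `parent_length` nodes can structurally carry at most
#' `parent_length - node_index - delay` nodes, clamped at zero.
#'
#' @param parent_length Nodes on the bearing stem (its effective length).
#' @param node_index Node of attachment on the bearing stem, >= 1.
#' @param delay Branch-development delay `L`, in nodes.
#' @return Non-negative integer node capacity.
#' @examples
#' structural_length(21, 1, 2)  # 18-node secondary branch at node 1
#' @export
structural_length <- function(parent_length, node_index, delay) {
  if (node_index < 1) stop("'node_index' must be >= 1", call. = FALSE)
  max(0L, as.integer(parent_length) - as.integer(node_index) -
        as.integer(delay))
}

bud_categories <- c("unemerged", "short_shoot",
                    "branch_unbranched", "branch_branched")

#' Classify a bud by its activation level
#'
#' Allocates a bud to a morphological category from its activation level:
#' below the short-shoot threshold it remains unemerged; at or above it but
#' below the branch threshold it forms a short shoot (1 to fewer than 3
#' emerged nodes); at or above the branch threshold it grows out into a
#' branch (3 or more emerged nodes). Threshold comparisons are inclusive.
#' When `params$structural_downgrade` is `TRUE`, a branch-level AL at a
#' position that can structurally carry fewer than 3 nodes is reported as
#' a short shoot. Branches are later refined into branched vs unbranched
#' by [refine_branched()].
#'
#' @param al Activation level, >= 0.
#' @param params A [shoot_params] object.
#' @param structural Structural node capacity at the position (used only
#'   with `structural_downgrade`).
#' @return One of `"unemerged"`, `"short_shoot"`, `"branch"`.
#' @examples
#' p <- species_preset("trifolium_repens")
#' classify_al(6.5, p)   # "branch"
#' classify_al(1.46, p)  # "short_shoot"
#' @export
classify_al <- function(al, params, structural = Inf) {
  if (length(al) != 1L || is.na(al) || al < 0)
    stop("'al' must be a single non-negative number", call. = FALSE)
  if (al < params$threshold_short) return("unemerged")
  if (al < params$threshold_branch) return("short_shoot")
  if (params$structural_downgrade && structural < 3) "short_shoot" else "branch"
}

#' Grow the complete shoot system predicted by the model
#'
#' Recursively enumerates every axillary-bud position of the shoot system
#' distal to the basal root, starting from the primary stem. At each node
#' of each stem the NRS, OP, and AL are computed from the bud's coordinate
#' path, the bud is classified by its AL, and outgrowth is recursed into:
#' an unemerged bud carries no nodes, a short shoot carries up to
#' `short_shoot_cap` nodes, and a branch carries its full structural
#' capacity. Enumeration terminates because every outgrowth is strictly
#' shorter than the stem bearing it. Buds at excised primary-stem nodes
#' are skipped (the nodes still count for distance). Branch buds are then
#' refined into branched vs unbranched branches.
#'
#' @param params A [shoot_params] object.
#' @return An object of class `shoot_system`: a list with elements
#'   `params` and `buds`, the latter a data frame with one row per
#'   enumerated bud position and columns `path` (dot-separated
#'   coordinates), `parent` (path of the parent branch's founding bud, ""
#'   for primary-stem buds), `order` (path length), `primary_node` (`b1`),
#'   `node` (node index on the bearing stem), `nrs`, `op`, `al`,
#'   `category`, `structural_length` and `effective_length`.
#' @examples
#' sys <- grow_shoot(species_preset("trifolium_repens"))
#' sys
#' summary(sys)
#' @export
grow_shoot <- function(params) {
  validate_shoot_params(params)
  rows <- list()
  nrow_used <- 0L
  add <- function(row) {
    nrow_used <<- nrow_used + 1L
    rows[[nrow_used]] <<- row
  }
  walk <- function(prefix, stem_length, skip) {
    for (j in seq_len(stem_length)) {
      if (j %in% skip) next
      path <- c(prefix, j)
      b_nrs <- nrs(path, params)
      b_op <- if (params$variant == "minus_op") 100
              else outgrowth_potential(path, params)
      b_al <- if (params$variant == "minus_op") 100 * b_nrs
              else b_nrs * b_op
      structural <- structural_length(stem_length, j, params$delay)
      category <- classify_al(b_al, params, structural)
      effective <- switch(category,
        unemerged = 0L,
        short_shoot = min(params$short_shoot_cap, structural),
        branch = structural)
      add(list(path = paste(path, collapse = "."),
               parent = paste(prefix, collapse = "."),
               order = length(path),
               primary_node = path[1L],
               node = j,
               nrs = b_nrs, op = b_op, al = b_al,
               category = category,
               structural_length = structural,
               effective_length = effective))
      if (effective > 0L) walk(path, effective, integer(0))
    }
  }
  walk(integer(0), params$n_primary_nodes, params$excised_primary_nodes)
  rows <- rows[seq_len(nrow_used)]
  buds <- data.frame(
    path = vapply(rows, `[[`, "", "path"),
    parent = vapply(rows, `[[`, "", "parent"),
    order = vapply(rows, `[[`, 0L, "order"),
    primary_node = vapply(rows, `[[`, 0L, "primary_node"),
    node = vapply(rows, `[[`, 0L, "node"),
    nrs = vapply(rows, `[[`, 0, "nrs"),
    op = vapply(rows, `[[`, 0, "op"),
    al = vapply(rows, `[[`, 0, "al"),
    category = vapply(rows, `[[`, "", "category"),
    structural_length = vapply(rows, `[[`, 0L, "structural_length"),
    effective_length = vapply(rows, `[[`, 0L, "effective_length"),
    stringsAsFactors = FALSE)
  system <- structure(list(params = params, buds = buds),
                      class = "shoot_system")
  refine_branched(system)
}

#' Refine branch buds into branched vs unbranched branches
#'
#' A branch is "branched" when it bears at least one branch itself: every
#' bud classified as a branch whose outgrowth carries at least one child
#' bud also classified as a branch is relabelled `branch_branched`; the
#' rest become `branch_unbranched`. Called by [grow_shoot()]; exposed for
#' systems whose categories have been manipulated.
#'
#' @param system A `shoot_system`.
#' @return The system with the `category` column using the four final
#'   categories: `unemerged`, `short_shoot`, `branch_unbranched`,
#'   `branch_branched`.
#' @export
refine_branched <- function(system) {
  stopifnot(inherits(system, "shoot_system"))
  b <- system$buds
  is_branch <- b$category %in% c("branch", "branch_unbranched",
                                 "branch_branched")
  parents_of_branches <- unique(b$parent[is_branch & b$parent != ""])
  b$category[is_branch] <- ifelse(b$path[is_branch] %in% parents_of_branches,
                                  "branch_branched", "branch_unbranched")
  system$buds <- b
  system
}

#' @export
print.shoot_system <- function(x, ...) {
  tab <- table(factor(x$buds$category, levels = bud_categories))
  cat("Simulated shoot system",
      if (!is.na(x$params$species)) paste0("(", x$params$species, ")"),
      sprintf("- %s variant\n", x$params$variant))
  cat(sprintf("  %d bud positions enumerated; max branching order %d\n",
              nrow(x$buds), max_branching_order(x)))
  cat(sprintf("  %d branched branches, %d unbranched branches, %d short shoots, %d unemerged\n",
              tab[["branch_branched"]], tab[["branch_unbranched"]],
              tab[["short_shoot"]], tab[["unemerged"]]))
  invisible(x)
}

#' @export
summary.shoot_system <- function(object, ...) {
  b <- object$buds
  counts <- as.data.frame(table(
    order = b$order + 1L,
    category = factor(b$category, levels = bud_categories)),
    responseName = "count")
  counts$order <- as.integer(as.character(counts$order))
  zones <- primary_zone_boundaries(object)
  out <- list(params = object$params, counts = counts, zones = zones,
              max_order = max_branching_order(object),
              n_positions = nrow(b))
  class(out) <- "summary.shoot_system"
  out
}

#' @export
print.summary.shoot_system <- function(x, ...) {
  print(x$params)
  cat(sprintf("%d bud positions; deepest emerged outgrowth: order %d\n",
              x$n_positions, x$max_order))
  cat(sprintf("Primary stem: branches to node %d, short shoots to node %d\n",
              x$zones[["last_branch_node"]], x$zones[["last_short_node"]]))
  cat("Counts by branching order of the outgrowth:\n")
  print(stats::xtabs(count ~ order + category, data = x$counts))
  invisible(x)
}

#' @export
coef.shoot_system <- function(object, ...) {
  p <- object$params
  c(common_ratio = p$common_ratio, delay = p$delay,
    n_primary_nodes = p$n_primary_nodes,
    threshold_branch = p$threshold_branch,
    threshold_short = p$threshold_short)
}
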