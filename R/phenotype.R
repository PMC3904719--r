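#' Phenotype count tables
#'
#' The branching phenotype of a simulated (or observed) shoot system is
#' summarized as counts of outgrowth categories per primary-stem node
#' position and branching order: for each node `b1` along the primary
#' stem, how many 3rd-, 4th-, ... order outgrowths of each category sit on
#' the branch system arising there. Branching order refers to the bud's
#' outgrowth (primary stem = order 1, so a bud borne on the primary stem
#' founds an order-2 branch); an order-`n` query therefore selects buds
#' with coordinate paths of length `n - 1`.
#'
#' `counts_by_primary_node()` returns a complete grid over primary nodes,
#' the requested orders and categories, with zero fill, as a
#' `phenotype_table` (a data frame with columns `primary_node`, `order`,
#' `category`, `count`).
#'
#' @param system A `shoot_system` from [grow_shoot()].
#' @param order Integer vector of branching orders, all >= 2.
#' @param categories Character vector of categories to tabulate, from
#'   `unemerged`, `short_shoot`, `branch_unbranched`, `branch_branched`.
#' @return A `phenotype_table` data frame.
#' @examples
#' sys <- grow_shoot(species_preset("trifolium_repens", variant = "minus_op"))
#' tab <- counts_by_primary_node(sys, order = 3,
#'                               categories = "branch_branched")
#' sum(tab$count)   # 15 branched tertiary branches
#' extent(tab)      # most distal primary node bearing one
#' @export
counts_by_primary_node <- function(system, order,
                                   categories = c("branch_unbranched",
                                                  "branch_branched")) {
  stopifnot(inherits(system, "shoot_system"))
  if (any(order < 2))
    stop("'order' must be >= 2 (order 1 is the primary stem itself)",
         call. = FALSE)
  categories <- match.arg(categories, bud_categories, several.ok = TRUE)
  b <- system$buds
  grid <- expand.grid(
    primary_node = seq_len(system$params$n_primary_nodes),
    order = as.integer(order),
    category = categories,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sel <- b[(b$order + 1L) %in% order & b$category %in% categories,
           c("primary_node", "order", "category")]
  if (nrow(sel)) {
    sel$order <- sel$order + 1L
    agg <- stats::aggregate(list(count = rep(1L, nrow(sel))), sel, sum)
    grid <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  } else {
    grid$count <- 0L
  }
  grid$count[is.na(grid$count)] <- 0L
  grid <- grid[order(grid$order, grid$category, grid$primary_node),
               c("primary_node", "order", "category", "count")]
  rownames(grid) <- NULL
  grid$count <- as.integer(grid$count)
  as_phenotype_table(grid,
                     variant = system$params$variant,
                     species = system$params$species)
}

as_phenotype_table <- function(df, variant = NA_character_,
                               species = NA_character_) {
  stopifnot(all(c("primary_node", "order", "category", "count") %in%
                  names(df)))
  attr(df, "variant") <- variant
  attr(df, "species") <- species
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Most distal primary node with a positive count
#'
#' @param table A `phenotype_table` (or any data frame with
#'   `primary_node` and `count` columns).
#' @return Largest `primary_node` with `count > 0`, or 0 if all counts are
#'   zero.
#' @examples
#' extent(data.frame(primary_node = 1:3, count = c(2L, 0L, 0L)))
#' @export
extent <- function(table) {
  if (!all(c("primary_node", "count") %in% names(table)) || !nrow(table))
    stop("'table' must be a non-empty phenotype table", call. = FALSE)
  pos <- table$primary_node[table$count > 0]
  if (length(pos)) max(pos) else 0L
}

#' Primary-stem zone boundaries
#'
#' The primary stem of these plants shows a proximal zone of branches, a
#' middle zone of short shoots, and a distal zone of unemerged buds.
#' Returns the most distal primary node classified as a branch and the
#' most distal node classified as at least a short shoot (0 when the zone
#' is absent).
#'
#' @param system A `shoot_system`.
#' @return Named integer vector `c(last_branch_node, last_short_node)`.
#' @examples
#' primary_zone_boundaries(grow_shoot(species_preset("trifolium_repens")))
#' @export
primary_zone_boundaries <- function(system) {
  stopifnot(inherits(system, "shoot_system"))
  b <- system$buds[system$buds$order == 1L, ]
  branch <- b$primary_node[b$category %in% c("branch_unbranched",
                                             "branch_branched")]
  emerged <- b$primary_node[b$category != "unemerged"]
  c(last_branch_node = if (length(branch)) max(branch) else 0L,
    last_short_node = if (length(emerged)) max(emerged) else 0L)
}

#' Maximum branching order of the shoot system
#'
#' The branching order of the deepest emerged outgrowth (primary stem =
#' order 1): one more than the longest coordinate path among buds
#' classified short shoot or better. A system with no emerged outgrowth
#' has order 1 (the bare primary stem).
#'
#' @param system A `shoot_system`.
#' @return Integer branching order.
#' @export
max_branching_order <- function(system) {
  stopifnot(inherits(system, "shoot_system"))
  emerged <- system$buds$order[system$buds$category != "unemerged"]
  if (length(emerged)) max(emerged) + 1L else 1L
}

#' Read and write phenotype tables as CSV
#'
#' Comma-separated with a mandatory header `primary_node,order,category,
#' count`, no row names, UTF-8. Tables round-trip bit-identically.
#'
#' @param table A `phenotype_table`.
#' @param path File path.
#' @return `write_phenotype()` returns `path` invisibly;
#'   `read_phenotype()` returns a `phenotype_table`.
#' @export
write_phenotype <- function(table, path) {
  df <- as.data.frame(table)[, c("primary_node", "order", "category",
                                 "count")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(primary_node = "integer",
                                       order = "integer",
                                       category = "character",
                                       count = "integer"))
  as_phenotype_table(df)
}

#' Predicted phenotype tables from a shoot system
#'
#' `predict()` on a `shoot_system` tabulates the simulated branching
#' phenotype: counts of outgrowths per primary-stem node and branching
#' order.
#'
#' @param object A `shoot_system`.
#' @param order Branching orders to tabulate; defaults to every order
#'   present beyond the primary stem.
#' @param categories Categories to tabulate; defaults to all four.
#' @param ... Unused.
#' @return A `phenotype_table`.
#' @export
predict.shoot_system <- function(object,
                                 order = NULL,
                                 categories = bud_categories,
                                 ...) {
  if (is.null(order))
    order <- sort(unique(object$buds$order)) + 1L
  counts_by_primary_node(object, order = order, categories = categories)
}

#' @export
plot.shoot_system <- function(x, order = 3,
                              categories = c("branch_branched",
                                             "branch_unbranched",
                                             "short_shoot"),
                              ...) {
  tab <- counts_by_primary_node(x, order = order, categories = categories)
  m <- stats::xtabs(count ~ category + primary_node, data = tab)
  graphics::barplot(m, beside = FALSE,
                    legend.text = rownames(m),
                    xlab = "Primary-stem node position",
                    ylab = sprintf("Order-%s outgrowths",
                                   paste(order, collapse = ",")),
                    ...)
  invisible(x)
}

#' Simulate noisy observed phenotypes from a model prediction
#'
#' Draws synthetic "observed" count tables around the model's predicted
#' phenotype, to exercise predicted-vs-observed comparisons: each cell of
#' the predicted table is, independently and with probability
#' `noise_rate`, replaced by a Poisson draw with mean equal to the
#' predicted count (`noise_rate = 0` returns the prediction unchanged).
#'
#' @param object A `shoot_system`.
#' @param nsim Number of tables to simulate.
#' @param seed Integer seed; required for reproducibility (the global RNG
#'   state is preserved).
#' @param order,categories Passed to [counts_by_primary_node()].
#' @param noise_rate Per-cell probability of perturbation, in \[0, 1\].
#' @param ... Unused.
#' @return A list of `nsim` `phenotype_table`s.
#' @export
simulate.shoot_system <- function(object, nsim = 1, seed = NULL,
                                  order = 3,
                                  categories = c("branch_unbranched",
                                                 "branch_branched"),
                                  noise_rate = 1, ...) {
  tab <- counts_by_primary_node(object, order = order,
                                categories = categories)
  perturb_counts(tab, nsim = nsim, seed = seed, noise_rate = noise_rate)
}

perturb_counts <- function(tab, nsim = 1, seed = NULL, noise_rate = 1) {
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i) {
    out <- tab
    hit <- stats::runif(nrow(out)) < noise_rate
    out$count[hit] <- stats::rpois(sum(hit), lambda = out$count[hit])
    out$count <- as.integer(out$count)
    out
  })
}
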