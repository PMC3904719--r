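#' Read a run configuration file
#'
#' A run is configured by a flat key-value YAML document whose keys mirror
#' the [shoot_params()] arguments, optionally starting from a species
#' preset:
#'
#' ```yaml
#' species: trifolium_repens
#' variant: plus_op
#' threshold_branch: 6
#' ```
#'
#' Keys given in the file (or in `overrides`, e.g. from CLI flags, which
#' win over file values) replace the preset's values. Without a `species`
#' key all mandatory [shoot_params()] arguments must be present.
#'
#' @param path Path to the YAML config file.
#' @param overrides Named list of parameter overrides.
#' @return A [shoot_params] object.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value document", call. = FALSE)
  cfg[names(overrides)] <- overrides
  build_params_from_config(cfg)
}

build_params_from_config <- function(cfg) {
  if (!is.null(cfg$species)) {
    preset_keys <- intersect(names(cfg), c("species", "variant",
                                           "decay_adjustment"))
    args <- unclass(do.call(species_preset, cfg[preset_keys]))
    rest <- setdiff(names(cfg), c(preset_keys, "decay_adjustment"))
    bad <- setdiff(rest, names(args))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    args[rest] <- cfg[rest]
    do.call(shoot_params, args)
  } else {
    do.call(shoot_params, cfg)
  }
}

#' Run a simulation and write its outputs
#'
#' Builds the shoot system for the requested model variant(s) and writes,
#' per variant: a phenotype CSV (counts per primary node, order, and
#' category), a Newick export of the branching topology, and a JSON
#' parameter echo from which the run can be reproduced exactly. Resolved
#' parameters and headline counts are logged via [message()].
#'
#' @param params A [shoot_params] object (its `variant` field is ignored
#'   when `variants` is given).
#' @param outdir Output directory; created if missing.
#' @param variants Character vector of model variants to run.
#' @param orders Branching orders tabulated in the CSV; defaults to all
#'   orders present.
#' @return Invisibly, a named list per variant with elements `system`,
#'   `phenotype_csv`, `tree_newick`, `params_json`.
#' @export
run_simulate <- function(params, outdir,
                         variants = params$variant,
                         orders = NULL) {
  validate_shoot_params(params)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  out <- list()
  for (v in variants) {
    p <- params
    p$variant <- v
    message(sprintf("simulate: species=%s variant=%s R=%.4f L=%d nodes=%d thresholds=%g/%g",
                    p$species, v, p$common_ratio, p$delay,
                    p$n_primary_nodes, p$threshold_branch,
                    p$threshold_short))
    sys <- grow_shoot(p)
    ord <- if (is.null(orders)) sort(unique(sys$buds$order)) + 1L else orders
    tab <- counts_by_primary_node(sys, order = ord,
                                  categories = bud_categories)
    stem <- if (!is.na(p$species)) p$species else "run"
    csv <- file.path(outdir, sprintf("%s_%s_phenotype.csv", stem, v))
    nwk <- file.path(outdir, sprintf("%s_%s_tree.nwk", stem, v))
    echo <- file.path(outdir, sprintf("%s_%s_params.json", stem, v))
    write_phenotype(tab, csv)
    writeLines(export_tree(sys, "newick"), nwk)
    jsonlite::write_json(unclass(p), echo, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    message(sprintf("  %d bud positions, %d emerged; wrote %s",
                    nrow(sys$buds),
                    sum(sys$buds$category != "unemerged"), csv))
    out[[v]] <- list(system = sys, phenotype_csv = csv, tree_newick = nwk,
                     params_json = echo)
  }
  invisible(out)
}

category_codes <- c(unemerged = "U", short_shoot = "S",
                    branch_unbranched = "B", branch_branched = "BB",
                    branch = "B")

#' Export the branching topology as text
#'
#' `"newick"` writes the tree of enumerated bud positions as a Newick
#' string: each outgrowth is a node labelled by its coordinate path joined
#' with `.`, suffixed by `-` and a category code (`U` unemerged, `S` short
#' shoot, `B` unbranched branch, `BB` branched branch); outgrowths bearing
#' enumerated children are internal nodes, the rest leaves; no branch
#' lengths (topology, not geometry, is the model's output). `"nested"`
#' writes an indented listing, one bud per line, in stable path order.
#'
#' @param system A `shoot_system`.
#' @param format `"newick"` or `"nested"`.
#' @return A single character string (Newick) or a character vector of
#'   lines (nested).
#' @examples
#' cat(substr(export_tree(grow_shoot(species_preset("trifolium_repens")),
#'                        "newick"), 1, 60), "...\n")
#' @export
export_tree <- function(system, format = c("newick", "nested")) {
  format <- match.arg(format)
  b <- system$buds
  root_key <- "@root"  # primary-stem buds have parent "", not addressable by name
  kids <- split(seq_len(nrow(b)), ifelse(b$parent == "", root_key, b$parent))
  label <- function(i) paste0(b$path[i], "-", category_codes[[b$category[i]]])
  if (format == "newick") {
    render <- function(i) {
      ch <- kids[[b$path[i]]]
      if (is.null(ch)) label(i)
      else paste0("(", paste(vapply(ch[order(b$node[ch])], render, ""),
                             collapse = ","), ")", label(i))
    }
    roots <- kids[[root_key]]
    paste0("(", paste(vapply(roots[order(b$node[roots])], render, ""),
                      collapse = ","), ")plant;")
  } else {
    render <- function(i, depth) {
      line <- sprintf("%s%s [%s] AL=%.4f", strrep("  ", depth), b$path[i],
                      b$category[i], b$al[i])
      ch <- kids[[b$path[i]]]
      if (is.null(ch)) line
      else c(line, unlist(lapply(ch[order(b$node[ch])], render,
                                 depth = depth + 1L)))
    }
    roots <- kids[[root_key]]
    unlist(lapply(roots[order(b$node[roots])], render, depth = 0L))
  }
}

#' Observed-phenotype fixtures
#'
#' Provides "observed" count tables for exercising predicted-vs-observed
#' comparisons. `kind = "trifolium_fig1_zones"` encodes the mean observed
#' primary-stem zonation of greenhouse-grown white clover plants: branches
#' at nodes 1-11, short shoots at nodes 12-18, unemerged buds at nodes
#' 19-21 (one secondary outgrowth per node; the zone data do not resolve
#' branched from unbranched branches, so branches carry the collapsed
#' category label `branch`). `kind = "synthetic"` perturbs a predicted
#' table with seeded per-cell Poisson count noise (see
#' [simulate.shoot_system()]); it requires `seed` and either `system` or
#' `table`.
#'
#' @param kind `"trifolium_fig1_zones"` or `"synthetic"`.
#' @param system A `shoot_system`; used with `kind = "synthetic"` when
#'   `table` is not given.
#' @param table A predicted `phenotype_table` to perturb.
#' @param seed Integer seed (mandatory for `"synthetic"`).
#' @param noise_rate Per-cell perturbation probability in \[0, 1\].
#' @param order,categories Passed to [counts_by_primary_node()] when the
#'   predicted table is derived from `system`.
#' @return A `phenotype_table`.
#' @examples
#' obs <- observed_fixture("trifolium_fig1_zones")
#' extent(obs[obs$category == "short_shoot", ])  # 18
#' @export
observed_fixture <- function(kind = c("trifolium_fig1_zones", "synthetic"),
                             system = NULL, table = NULL, seed = NULL,
                             noise_rate = 1, order = 3,
                             categories = c("branch_unbranched",
                                            "branch_branched")) {
  kind <- match.arg(kind)
  if (kind == "trifolium_fig1_zones") {
    df <- data.frame(
      primary_node = 1:21,
      order = 2L,
      category = rep(c("branch", "short_shoot", "unemerged"),
                     times = c(11L, 7L, 3L)),
      count = 1L,
      stringsAsFactors = FALSE)
    return(as_phenotype_table(df, species = "trifolium_repens"))
  }
  if (is.null(seed))
    stop("'seed' is required for synthetic fixtures", call. = FALSE)
  if (is.null(table)) {
    if (is.null(system))
      stop("give either 'table' or 'system' for synthetic fixtures",
           call. = FALSE)
    table <- counts_by_primary_node(system, order = order,
                                    categories = categories)
  }
  perturb_counts(table, nsim = 1, seed = seed, noise_rate = noise_rate)[[1]]
}
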