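#' Declare a synthetic scRNA-seq scenario
#'
#' Describes a multi-type negative-binomial count scenario with per-type
#' marker genes, class imbalance, query-only ("novel") types and optional
#' multiplicative per-gene batch effects on the query. Generation from a
#' scenario is a pure function of `(scenario, seed)`.
#'
#' Counts are drawn as `NB(mean = baseline * fold_change^[marker] *
#' libsize, dispersion)` with per-gene baselines log-normal across genes
#' and per-cell library-size factors log-normal with sigma
#' `libsize_sigma` (so normalization is non-trivial). Marker gene sets
#' are disjoint blocks assigned in type order.
#'
#' @param n_genes Number of genes.
#' @param types Data frame with columns `name`, `n_ref` (reference cells;
#'   0 for query-only types), `n_query` (query cells), `n_markers`
#'   (marker genes for the type) and `fold_change` (marker mean
#'   multiplier, > 0; 1 removes the signal).
#' @param novel_types Character vector of query-only type names; these
#'   must have `n_ref = 0` and are the ground-truth novel cells.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   default 0.3, a typical scRNA-seq value.
#' @param libsize_sigma Log-normal sigma of per-cell library-size factors
#'   (default 0.2).
#' @param batch_sigma Log-normal sigma of per-gene batch factors applied
#'   to the query only (default 0 = no batch effect).
#' @param marker_baseline Optional fixed baseline mean for marker genes
#'   (markers are typically well-expressed genes); `NULL` (default)
#'   keeps the log-normal baseline draw for markers too.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_genes, types, novel_types = character(),
                               dispersion = 0.3, libsize_sigma = 0.2,
                               batch_sigma = 0, marker_baseline = NULL) {
  types <- tibble::as_tibble(types)
  needed <- c("name", "n_ref", "n_query", "n_markers", "fold_change")
  miss <- setdiff(needed, names(types))
  if (length(miss) > 0) {
    stop("`types` is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (n_genes < sum(types$n_markers)) {
    stop("`n_genes` (", n_genes, ") smaller than total markers (",
         sum(types$n_markers), ")")
  }
  if (anyDuplicated(types$name)) stop("`types$name` must be unique")
  if (any(types$n_ref + types$n_query < 1)) {
    stop("`types`: every type needs at least 1 cell")
  }
  if (any(types$fold_change <= 0)) stop("`fold_change` must be > 0")
  bad_novel <- setdiff(novel_types, types$name)
  if (length(bad_novel) > 0) {
    stop("`novel_types` not in `types$name`: ",
         paste(bad_novel, collapse = ", "))
  }
  if (any(types$n_ref[types$name %in% novel_types] > 0)) {
    stop("`novel_types` must have n_ref = 0 (query-only)")
  }
  if (length(setdiff(types$name, novel_types)) < 2) {
    stop("`types`: need at least 2 non-novel reference types")
  }
  if (dispersion <= 0) stop("`dispersion` must be > 0")
  if (libsize_sigma < 0) stop("`libsize_sigma` must be >= 0")
  if (batch_sigma < 0) stop("`batch_sigma` must be >= 0")
  if (!is.null(marker_baseline) && marker_baseline <= 0) {
    stop("`marker_baseline` must be > 0")
  }
  structure(
    list(n_genes = as.integer(n_genes), types = types,
         novel_types = novel_types, dispersion = dispersion,
         libsize_sigma = libsize_sigma, batch_sigma = batch_sigma,
         marker_baseline = marker_baseline),
    class = "synthetic_scenario"
  )
}

#' @exportS3Method base::print
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d genes, %d types (%d novel)\n",
              x$n_genes, nrow(x$types), length(x$novel_types)))
  print(x$types)
  invisible(x)
}

nb_counts <- function(n_cells, mu_genes, libsize, dispersion) {
  n_genes <- length(mu_genes)
  mu <- outer(libsize, mu_genes)
  matrix(stats::rnbinom(n_cells * n_genes, size = 1 / dispersion, mu = mu),
         n_cells, n_genes)
}

#' Generate a reference/query dataset from a scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with `ref` (a [labeled_reference()] of raw counts over
#'   the non-novel types), `query` (raw-count [expression_matrix()]),
#'   `query_labels` (ground-truth type per query cell) and `query_novel`
#'   (logical flags, `TRUE` exactly for cells of novel types).
#' @export
generate_scenario <- function(scenario, seed = 0) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(as.integer(seed))
  ng <- scenario$n_genes
  baseline <- exp(stats::rnorm(ng, mean = -1, sd = 1))
  # disjoint marker blocks in type order
  marker_sets <- vector("list", nrow(scenario$types))
  nxt <- 1
  for (i in seq_len(nrow(scenario$types))) {
    nm <- scenario$types$n_markers[i]
    marker_sets[[i]] <- if (nm > 0) seq(nxt, nxt + nm - 1) else integer()
    nxt <- nxt + nm
  }
  if (!is.null(scenario$marker_baseline)) {
    baseline[unlist(marker_sets)] <- scenario$marker_baseline
  }
  type_mean <- function(i) {
    mu <- baseline
    mu[marker_sets[[i]]] <- mu[marker_sets[[i]]] *
      scenario$types$fold_change[i]
    mu
  }
  draw_cells <- function(i, n) {
    lib <- exp(stats::rnorm(n, 0, scenario$libsize_sigma))
    nb_counts(n, type_mean(i), lib, scenario$dispersion)
  }
  ref_blocks <- list(); ref_labels <- character()
  query_blocks <- list(); query_labels <- character()
  for (i in seq_len(nrow(scenario$types))) {
    tn <- scenario$types$name[i]
    if (scenario$types$n_ref[i] > 0) {
      ref_blocks[[length(ref_blocks) + 1]] <-
        draw_cells(i, scenario$types$n_ref[i])
      ref_labels <- c(ref_labels, rep(tn, scenario$types$n_ref[i]))
    }
    if (scenario$types$n_query[i] > 0) {
      query_blocks[[length(query_blocks) + 1]] <-
        draw_cells(i, scenario$types$n_query[i])
      query_labels <- c(query_labels, rep(tn, scenario$types$n_query[i]))
    }
  }
  bind_blocks <- function(blocks) {
    if (length(blocks) == 0) matrix(0, 0, ng) else do.call(rbind, blocks)
  }
  ref_vals <- bind_blocks(ref_blocks)
  if (nrow(ref_vals) == 0) {
    stop("scenario generates no reference cells; give a type n_ref > 0")
  }
  query_vals <- bind_blocks(query_blocks)
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  ref_m <- expression_matrix(
    ref_vals, sprintf("ref_%05d", seq_len(nrow(ref_vals))), gene_ids)
  query_m <- expression_matrix(
    query_vals, sprintf("query_%05d", seq_len(nrow(query_vals))), gene_ids)
  if (scenario$batch_sigma > 0) {
    query_m <- add_batch_effect(query_m, scenario$batch_sigma,
                                seed = as.integer(seed) + 10000L)
  }
  list(
    ref = labeled_reference(ref_m, ref_labels),
    query = query_m,
    query_labels = query_labels,
    query_novel = query_labels %in% scenario$novel_types
  )
}

#' Apply a multiplicative per-gene batch effect
#'
#' Scales each gene's counts by a log-normal factor `exp(N(0, sigma^2))`
#' and re-rounds to integers, mimicking protocol chemistry differences
#' between platforms. `sigma = 0` returns the input unchanged.
#'
#' @param m Raw-layer [expression_matrix()].
#' @param sigma Log-normal sigma (>= 0).
#' @param seed Integer seed.
#' @return Raw-layer [expression_matrix()].
#' @export
add_batch_effect <- function(m, sigma, seed = 0) {
  stopifnot(is_expression_matrix(m), sigma >= 0)
  if (m$layer != "raw") stop("`m` must be a raw-layer matrix")
  if (sigma == 0) return(m)
  set.seed(as.integer(seed))
  factors <- exp(stats::rnorm(ncol(m$values), 0, sigma))
  v <- round(sweep(m$values, 2, factors, "*"))
  expression_matrix(v, m$cell_ids, m$gene_ids, layer = "raw")
}

fixture_library <- function() {
  base_types <- tibble::tibble(
    name = c("alpha", "beta", "gamma", "novelX"),
    n_ref = c(700L, 600L, 400L, 0L),
    n_query = c(140L, 120L, 80L, 300L),
    n_markers = 20L,
    fold_change = 8
  )
  list(
    `easy-separable` = synthetic_scenario(
      n_genes = 500, types = base_types, novel_types = "novelX"),
    `rare-novel` = synthetic_scenario(
      n_genes = 500,
      types = tibble::tibble(
        name = c("t1", "t2", "t3", "t4", "rare_novel"),
        n_ref = c(2000L, 1500L, 1000L, 500L, 0L),
        n_query = c(400L, 300L, 200L, 100L, 17L),
        n_markers = 20L,
        fold_change = 8),
      novel_types = "rare_novel"),
    `cross-batch` = synthetic_scenario(
      n_genes = 500, types = base_types, novel_types = "novelX",
      batch_sigma = 0.5)
  )
}

#' Packaged synthetic scenarios
#'
#' Three canned scenarios covering the regimes the detector must handle:
#' `"easy-separable"` (strong 8x markers, one 300-cell novel type among
#' ~2,300 cells, 500 genes), `"rare-novel"` (a 17-cell novel type among
#' >5,000 cells) and `"cross-batch"` (`easy-separable` with a sigma-0.5
#' per-gene batch effect on the query).
#'
#' @param name Fixture name; omit to see choices via
#'   [list_fixture_scenarios()].
#' @return A [synthetic_scenario()].
#' @export
fixture_scenario <- function(name) {
  lib <- fixture_library()
  if (!name %in% names(lib)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  }
  lib[[name]]
}

#' @rdname fixture_scenario
#' @export
list_fixture_scenarios <- function() names(fixture_library())
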