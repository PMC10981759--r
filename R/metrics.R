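#' Novelty-detection metrics
#'
#' First-principles implementations of the three standard
#' out-of-distribution detection metrics, with novel cells as the
#' positive class and higher scores meaning more novel.
#'
#' * `auroc()` — probability that a random novel cell outscores a random
#'   typical cell, ties counted 1/2 (Mann–Whitney formulation).
#' * `aupr()` — area under the precision–recall curve by step
#'   interpolation over all distinct score thresholds in descending
#'   order, tied scores processed as one block.
#' * `fpr_at_95_tpr()` — the false-positive rate at the largest score
#'   threshold whose true-positive rate is at least 0.95.
#'
#' @param scores Numeric novelty scores, higher = more novel.
#' @param labels Logical (or 0/1) ground-truth novel flags.
#' @return A single number in `[0, 1]`.
#' @name detection_metrics
NULL

check_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  if (!any(labels)) stop("no positive (novel) cells in `labels`")
  if (all(labels)) stop("no negative (typical) cells in `labels`")
  labels
}

#' @rdname detection_metrics
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname detection_metrics
#' @export
aupr <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # block boundaries at the last element of each tied-score run
  block_end <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(y)[block_end]
  fp <- cumsum(!y)[block_end]
  n_pos <- sum(labels)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @rdname detection_metrics
#' @export
fpr_at_95_tpr <- function(scores, labels, tpr = 0.95) {
  labels <- check_binary(scores, labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  for (t in thresholds) {
    called <- scores >= t
    if (sum(called & labels) / n_pos >= tpr) {
      return(sum(called & !labels) / n_neg)
    }
  }
  1
}

#' Class-holdout split for novelty evaluation
#'
#' Withholds `c_novel` classes from the reference entirely; the query is
#' a stratified test fraction of every retained class plus all cells of
#' the withheld classes, which become the ground-truth novel cells.
#'
#' @param ref A [labeled_reference()] over all classes.
#' @param c_novel Number of classes to withhold (must be `< C_ref`).
#' @param strategy `"rarest"` (withhold the smallest classes by cell
#'   count, ties by class order), `"named"` (withhold `classes`), or
#'   `"random"`.
#' @param classes Class names to withhold when `strategy = "named"`.
#' @param test_frac Test fraction of retained classes placed in the
#'   query (default 0.2).
#' @param seed Integer seed; splits are deterministic given it.
#' @return An object of class `holdout_split`: list with `c_novel`,
#'   `novel_classes`, `ref_idx`, `query_idx`, `query_novel` (logical per
#'   query cell) and `seed`.
#' @export
make_holdout_split <- function(ref, c_novel = 1,
                               strategy = c("rarest", "named", "random"),
                               classes = NULL, test_frac = 0.2, seed = 0) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ref, "labeled_reference"), c_novel >= 1,
            test_frac > 0, test_frac < 1)
  k <- length(ref$class_names)
  if (c_novel >= k) {
    stop("c_novel (", c_novel, ") must be smaller than the number of ",
         "reference classes (", k, ")")
  }
  set.seed(as.integer(seed))
  counts <- table(factor(ref$labels, levels = ref$class_names))
  novel_classes <- switch(
    strategy,
    rarest = ref$class_names[order(as.integer(counts))][seq_len(c_novel)],
    random = sample(ref$class_names, c_novel),
    named = {
      if (is.null(classes)) stop("strategy='named' requires `classes`")
      bad <- setdiff(classes, ref$class_names)
      if (length(bad) > 0) {
        stop("unknown class(es): ", paste(bad, collapse = ", "))
      }
      if (length(classes) != c_novel) {
        stop("`classes` must have length c_novel = ", c_novel)
      }
      classes
    })
  is_novel_cell <- ref$labels %in% novel_classes
  ref_idx <- integer()
  test_idx <- integer()
  for (cl in setdiff(ref$class_names, novel_classes)) {
    cells <- which(ref$labels == cl)
    n_test <- max(1, round(test_frac * length(cells)))
    test_cells <- sort(sample(cells, n_test))
    test_idx <- c(test_idx, test_cells)
    ref_idx <- c(ref_idx, setdiff(cells, test_cells))
  }
  query_idx <- c(sort(test_idx), which(is_novel_cell))
  structure(
    list(c_novel = as.integer(c_novel), novel_classes = novel_classes,
         ref_idx = sort(ref_idx), query_idx = query_idx,
         query_novel = ref$labels[query_idx] %in% novel_classes,
         seed = as.integer(seed)),
    class = "holdout_split"
  )
}

#' @exportS3Method base::print
print.holdout_split <- function(x, ...) {
  cat(sprintf(
    "<holdout_split> c_novel=%d (%s); %d reference cells, %d query cells (%d novel)\n",
    x$c_novel, paste(x$novel_classes, collapse = ", "),
    length(x$ref_idx), length(x$query_idx), sum(x$query_novel)))
  invisible(x)
}

subset_matrix <- function(m, idx) {
  expression_matrix(m$values[idx, , drop = FALSE], m$cell_ids[idx],
                    m$gene_ids, layer = m$layer)
}

#' Run a novelty-detection evaluation experiment
#'
#' Two designs are supported. With a labeled `ref` plus explicit `query`
#' and `query_novel` ground truth (e.g. from [generate_scenario()]), one
#' classifier is fitted on the reference and all requested modes are
#' scored on the query. With `ref` alone and `c_novel` values, a class
#' [make_holdout_split()] is built per `c_novel` (one classifier per
#' split, all modes scored on the shared query).
#'
#' @param ref A [labeled_reference()].
#' @param query Optional query [expression_matrix()] with ground truth.
#' @param query_novel Logical ground-truth novel flags for `query` cells.
#' @param c_novel Integer vector of holdout sizes (used when `query` is
#'   `NULL`).
#' @param modes Character subset of `c("msp", "odin", "seq", "sim")`.
#' @param epsilon,temperature Score parameters.
#' @param config [fit_config()] for each classifier fit.
#' @param strategy,test_frac Passed to [make_holdout_split()].
#' @param seed Split seed (also used as classifier seed offset base).
#' @return An `eval_report` tibble, one row per mode x split, with
#'   columns `mode`, `c_novel`, `novel_classes`, `auroc`, `aupr`,
#'   `fpr95`, `n_query`, `n_novel`, `seed`.
#' @export
run_experiment <- function(ref, query = NULL, query_novel = NULL,
                           c_novel = 1,
                           modes = c("msp", "odin", "seq", "sim"),
                           epsilon = 0.01, temperature = 1000,
                           config = fit_config(), strategy = "rarest",
                           test_frac = 0.2, seed = 0) {
  stopifnot(inherits(ref, "labeled_reference"))
  modes <- match.arg(modes, several.ok = TRUE)
  eval_one <- function(train_ref, query_m, truth, cn, novel_cls) {
    al <- align_genes(train_ref$matrix, query_m)
    rm_ <- al$ref
    qm <- al$query
    if (rm_$layer == "raw") rm_ <- normalize_expression(rm_)
    if (qm$layer == "raw") qm <- normalize_expression(qm)
    model <- fit_classifier(
      labeled_reference(rm_, train_ref$labels, train_ref$class_names),
      config)
    purrr::map_dfr(modes, function(md) {
      conf <- score_mode(model, qm, md, epsilon, temperature)
      sc <- 1 - conf
      tibble::tibble(
        mode = md, c_novel = cn,
        novel_classes = paste(novel_cls, collapse = ";"),
        auroc = auroc(sc, truth), aupr = aupr(sc, truth),
        fpr95 = fpr_at_95_tpr(sc, truth),
        n_query = length(truth), n_novel = sum(truth),
        seed = as.integer(seed))
    })
  }
  if (!is.null(query)) {
    stopifnot(!is.null(query_novel),
              length(query_novel) == nrow(query$values))
    report <- eval_one(ref, query, as.logical(query_novel),
                       NA_integer_, character())
  } else {
    report <- purrr::map_dfr(c_novel, function(cn) {
      split <- make_holdout_split(ref, cn, strategy = strategy,
                                  test_frac = test_frac, seed = seed)
      train_ref <- labeled_reference(
        subset_matrix(ref$matrix, split$ref_idx),
        ref$labels[split$ref_idx])
      query_m <- subset_matrix(ref$matrix, split$query_idx)
      eval_one(train_ref, query_m, split$query_novel, cn,
               split$novel_classes)
    })
  }
  class(report) <- c("eval_report", class(report))
  report
}

#' Write / read an evaluation report
#' @param report An `eval_report` tibble.
#' @param path CSV path.
#' @return `path` invisibly / the report tibble.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  report <- tibble::as_tibble(df)
  class(report) <- c("eval_report", class(report))
  report
}
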