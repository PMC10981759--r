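# Shared fixtures (memoised: the heavier ones are built once per session)
# and independent brute-force oracles for the detection metrics.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_fit_config <- function(seed = 0, epochs = 20L, hidden = c(128L, 64L)) {
  fit_config(hidden = hidden, epochs = as.integer(epochs), seed = seed)
}

# easy-separable scenario generated at seed 0, classifier fitted on the
# normalized reference, query normalized and aligned
easy_fixture <- function() {
  cached("easy_fixture", {
    d <- generate_scenario(fixture_scenario("easy-separable"), seed = 0)
    al <- align_genes(d$ref$matrix, d$query)
    rn <- normalize_expression(al$ref)
    qn <- normalize_expression(al$query)
    model <- fit_classifier(labeled_reference(rn, d$ref$labels),
                            test_fit_config())
    list(d = d, model = model, rn = rn, qn = qn)
  })
}

# compact scenario for I/O and command tests; four reference classes so
# holdout experiments up to c_novel = 2 keep a trainable reference
small_scenario <- function() {
  synthetic_scenario(
    n_genes = 60,
    types = tibble::tibble(
      name = c("a", "b", "c", "d", "nov"),
      n_ref = c(60L, 50L, 30L, 25L, 0L),
      n_query = c(15L, 12L, 8L, 6L, 20L),
      n_markers = 6L,
      fold_change = 8),
    novel_types = "nov")
}

# two planted novel types for the downstream pipeline; n_markers_novel
# controls how many disjoint marker genes each novel type carries
downstream_scenario <- function(n_markers_novel = 5L) {
  synthetic_scenario(
    n_genes = 300,
    types = tibble::tibble(
      name = c("r1", "r2", "r3", "n1", "n2"),
      n_ref = c(150L, 150L, 150L, 0L, 0L),
      n_query = c(40L, 40L, 40L, 200L, 200L),
      n_markers = c(10L, 10L, 10L, n_markers_novel, n_markers_novel),
      fold_change = 8),
    novel_types = c("n1", "n2"),
    marker_baseline = 3)
}

# marker gene indices per type for a scenario (disjoint blocks in order)
scenario_marker_sets <- function(scenario) {
  sets <- list()
  nxt <- 1
  for (i in seq_len(nrow(scenario$types))) {
    nm <- scenario$types$n_markers[i]
    sets[[scenario$types$name[i]]] <-
      if (nm > 0) seq(nxt, nxt + nm - 1) else integer()
    nxt <- nxt + nm
  }
  sets
}

# hand-built classifier with known weights (list of W matrices / b
# vectors); lets closed-form softmax and gradient cases be asserted
toy_model <- function(W, b, gene_ids = NULL, class_names = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(nrow(W[[1]])))
  }
  if (is.null(class_names)) {
    class_names <- paste0("c", seq_len(ncol(W[[length(W)]])))
  }
  structure(
    list(params = list(W = W, b = b), class_names = class_names,
         gene_ids = gene_ids,
         hidden = if (length(W) > 1) {
           vapply(W[-length(W)], ncol, 0L)
         } else integer(),
         dropout = 0, scale_stats = NULL,
         training_log = tibble::tibble(epoch = integer(), loss = double()),
         config = NULL),
    class = "cell_classifier")
}

# a fixed nonlinear 2-gene / 2-class model with nonzero gradients
tiny_model <- function() {
  toy_model(
    W = list(matrix(c(1, -0.5, -1, 0.8, 0.3, 1.2), 2, 3),
             matrix(c(0.9, -0.4, 0.2, -1.1, 0.6, 0.5), 3, 2)),
    b = list(c(0.1, -0.2, 0.05), c(0, 0.1)))
}

# ---- independent oracles ------------------------------------------------

oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & labels)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_fpr95 <- function(scores, labels, tpr = 0.95) {
  labels <- as.logical(labels)
  best <- 1
  for (t in sort(unique(scores))) {
    called <- scores >= t
    if (sum(called & labels) / sum(labels) >= tpr) {
      best <- min(best, sum(called & !labels) / sum(!labels))
    }
  }
  best
}
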