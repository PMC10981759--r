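#' Gradient-sign input perturbation ("barcode preprocessing")
#'
#' Perturbs each query cell's expression vector along the sign of the
#' gradient of `L(x) = -log S_T(x)`, where `S_T(x)` is the
#' temperature-scaled maximum softmax probability. `direction = "minus"`
#' subtracts the gradient sign (a gradient-descent step on `L`, raising
#' classifier confidence — the classic ODIN step); `"plus"` adds it,
#' lowering confidence. Coordinates with zero gradient are left unchanged,
#' so the sup-norm displacement is at most `epsilon`, with equality on
#' nonzero-gradient coordinates. Perturbation acts in the normalized
#' layer and is not clamped to non-negative values.
#'
#' @param model A [fit_classifier()] result.
#' @param m Normalized-layer [expression_matrix()] on the model's gene
#'   space.
#' @param epsilon Step size (>= 0).
#' @param direction `"minus"` (confidence-raising) or `"plus"`
#'   (confidence-lowering).
#' @param temperature Softmax temperature used in `L`.
#' @return An [expression_matrix()] of perturbed expression.
#' @export
perturb_expression <- function(model, m, epsilon, direction = c("minus", "plus"),
                               temperature = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "cell_classifier"), epsilon >= 0, temperature > 0)
  X <- model_input(model, m)
  if (epsilon == 0) {
    return(expression_matrix(X, m$cell_ids, model$gene_ids,
                             layer = "normalized"))
  }
  g <- input_gradient(model, X, temperature, cell_ids = m$cell_ids)
  step <- epsilon * sign(g)
  Xp <- if (direction == "minus") X - step else X + step
  expression_matrix(Xp, m$cell_ids, model$gene_ids, layer = "normalized")
}

max_softmax <- function(model, m, temperature = 1) {
  p <- predict_proba(model, m, temperature = temperature)
  stats::setNames(apply(p, 1, max), rownames(p))
}

#' Confidence score modes
#'
#' Four per-cell confidence scores in `[0, 1]`; low confidence flags a
#' query cell as novel (see [call_novel()]).
#'
#' * `score_msp()` — maximum softmax probability at temperature 1.
#' * `score_odin()` — temperature-scaled maximum softmax evaluated after a
#'   confidence-raising `T_minus` perturbation step. In-distribution
#'   cells respond more strongly to the step than novel cells.
#' * `score_seq()` — sequential composition: a `T_minus` step followed by
#'   a `T_plus` step with the gradient re-evaluated at the intermediate
#'   point; score is the temperature-scaled max softmax at the endpoint.
#' * `score_sim()` — simultaneous (sharpness) composition: both
#'   perturbations are applied independently to `x` and the sharpness
#'   gap `delta = S(T_minus) - S(T_plus)` (evaluated on the unscaled
#'   softmax; temperature scaling would flatten the saturation structure
#'   the gap measures) is mapped to a novelty score `(delta + 1) / 2`.
#'   Typical cells sit on flat, saturated softmax plateaus and barely
#'   respond (`delta` near 0); novel cells sit in sharp boundary regions
#'   and respond strongly, so a large gap flags novelty. The returned
#'   confidence is `1 - (delta + 1) / 2`.
#'
#' @param model A [fit_classifier()] result.
#' @param m Normalized-layer [expression_matrix()] aligned to the model.
#' @param epsilon Perturbation step size (default 0.01 on log-normalized
#'   expression).
#' @param temperature Softmax temperature (default 1000).
#' @return Named numeric vector of per-cell confidences.
#' @name score_modes
NULL

#' @rdname score_modes
#' @export
score_msp <- function(model, m) {
  max_softmax(model, m, temperature = 1)
}

#' @rdname score_modes
#' @export
score_odin <- function(model, m, epsilon = 0.01, temperature = 1000) {
  mp <- perturb_expression(model, m, epsilon, "minus", temperature)
  max_softmax(model, mp, temperature)
}

#' @rdname score_modes
#' @export
score_seq <- function(model, m, epsilon = 0.01, temperature = 1000) {
  m1 <- perturb_expression(model, m, epsilon, "minus", temperature)
  m2 <- perturb_expression(model, m1, epsilon, "plus", temperature)
  max_softmax(model, m2, temperature)
}

#' @rdname score_modes
#' @export
score_sim <- function(model, m, epsilon = 0.01, temperature = 1000) {
  m_minus <- perturb_expression(model, m, epsilon, "minus", temperature)
  m_plus <- perturb_expression(model, m, epsilon, "plus", temperature)
  delta <- max_softmax(model, m_minus, 1) - max_softmax(model, m_plus, 1)
  1 - (delta + 1) / 2
}

score_mode <- function(model, m, mode, epsilon = 0.01, temperature = 1000) {
  switch(mode,
         msp = score_msp(model, m),
         odin = score_odin(model, m, epsilon, temperature),
         seq = score_seq(model, m, epsilon, temperature),
         sim = score_sim(model, m, epsilon, temperature),
         stop("unknown mode '", mode,
              "'; available modes: msp, odin, seq, sim"))
}

#' Threshold-based novel-cell calling
#'
#' Converts per-cell confidence to a novelty score `1 - confidence` and
#' calls a cell novel when the novelty score is at least `lambda`
#' (equivalently, when confidence falls below `1 - lambda`). Non-novel
#' cells receive the classifier's predicted reference type.
#'
#' @param confidence Named per-cell confidence vector from a score mode.
#' @param mode Mode tag, one of `"msp"`, `"odin"`, `"seq"`, `"sim"`.
#' @param lambda Novelty threshold in `[0, 1]` (default 0.5).
#' @param model,m Classifier and aligned normalized matrix, used to
#'   annotate non-novel cells via [predict_type()]. Optional; without
#'   them `predicted_type` is `NA`.
#' @param epsilon,temperature Score parameters echoed into the result.
#' @return A tibble of class `novelty_result` with columns `cell_id`,
#'   `mode`, `confidence`, `novelty_score`, `is_novel`, `predicted_type`,
#'   and attributes `lambda`, `epsilon`, `temperature`.
#' @export
call_novel <- function(confidence, mode = "msp", lambda = 0.5,
                       model = NULL, m = NULL, epsilon = NA_real_,
                       temperature = NA_real_) {
  stopifnot(lambda >= 0, lambda <= 1,
            all(confidence >= 0 & confidence <= 1))
  mode <- match.arg(mode, c("msp", "odin", "seq", "sim"))
  novelty <- 1 - confidence
  is_novel <- novelty >= lambda
  predicted <- rep(NA_character_, length(confidence))
  if (!is.null(model) && !is.null(m) && any(!is_novel)) {
    predicted[!is_novel] <- predict_type(model, m)[!is_novel]
  }
  out <- tibble::tibble(
    cell_id = names(confidence) %||% as.character(seq_along(confidence)),
    mode = mode,
    confidence = unname(confidence),
    novelty_score = unname(novelty),
    is_novel = unname(is_novel),
    predicted_type = predicted
  )
  attr(out, "lambda") <- lambda
  attr(out, "epsilon") <- epsilon
  attr(out, "temperature") <- temperature
  class(out) <- c("novelty_result", class(out))
  out
}

#' Detect novel cells in a query against a labeled reference
#'
#' One-call pipeline: align gene spaces, normalize, fit the classifier on
#' the reference, score the query with the requested mode and call novel
#' cells by threshold.
#'
#' @param ref A [labeled_reference()] (raw or normalized layer).
#' @param query An [expression_matrix()] (raw or normalized layer).
#' @param mode Score mode (`"sim"` default — the best-performing mode).
#' @param lambda Novelty threshold (default 0.5).
#' @param epsilon,temperature Perturbation parameters.
#' @param config [fit_config()] for the classifier.
#' @param target_sum,log1p Normalization parameters.
#' @return A `novelty_result` tibble (see [call_novel()]) with the fitted
#'   model in attribute `model`.
#' @export
detect_novel <- function(ref, query, mode = "sim", lambda = 0.5,
                         epsilon = 0.01, temperature = 1000,
                         config = fit_config(), target_sum = 1e4,
                         log1p = TRUE) {
  stopifnot(inherits(ref, "labeled_reference"))
  al <- align_genes(ref$matrix, query)
  rm_ <- al$ref
  qm <- al$query
  if (rm_$layer == "raw") rm_ <- normalize_expression(rm_, target_sum, log1p)
  if (qm$layer == "raw") qm <- normalize_expression(qm, target_sum, log1p)
  ref_al <- labeled_reference(rm_, ref$labels, ref$class_names)
  model <- fit_classifier(ref_al, config)
  conf <- score_mode(model, qm, mode, epsilon, temperature)
  res <- call_novel(conf, mode = mode, lambda = lambda, model = model,
                    m = qm, epsilon = epsilon, temperature = temperature)
  attr(res, "model") <- model
  res
}

#' Write / read a novelty result as CSV plus a YAML parameter sidecar
#' @param res A `novelty_result`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.params.yaml`.
#' @return `path`, invisibly.
#' @export
write_novelty <- function(res, path) {
  utils::write.csv(
    as.data.frame(res)[, c("cell_id", "mode", "novelty_score", "is_novel",
                           "predicted_type")],
    path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(lambda = attr(res, "lambda"), epsilon = attr(res, "epsilon"),
         temperature = attr(res, "temperature"),
         mode = res$mode[1]),
    paste0(path, ".params.yaml"))
  invisible(path)
}
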