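#' Training configuration for the cell-type classifier
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout rate applied to hidden activations during
#'   training (inverted dropout; inactive at prediction time).
#' @param epochs Number of training epochs (0 gives an untrained model
#'   with uniform predictions).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and dropout masks.
#' @param scale_genes Standardize each gene to zero mean / unit variance
#'   using training-set statistics (stored in the model and re-applied at
#'   prediction time). Off by default.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(hidden = c(1024L, 512L, 256L), dropout = 0.5,
                       epochs = 50L, batch_size = 128L, lr = 1e-3,
                       seed = 0L, scale_genes = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0,
            dropout >= 0, dropout < 1, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), scale_genes = scale_genes),
            class = "fit_config")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

init_weights <- function(input_dim, hidden, n_classes) {
  dims <- c(input_dim, hidden, n_classes)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    if (l == length(W)) {
      # zero-initialized output layer: an untrained model predicts the
      # uniform distribution exactly
      W[[l]] <- matrix(0, fan_in, dims[l + 1])
    } else {
      W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1],
                                    sd = sqrt(2 / fan_in)),
                       fan_in, dims[l + 1])
    }
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

forward_pass <- function(params, X, dropout = 0, train = FALSE) {
  n_layers <- length(params$W)
  H <- X
  acts <- vector("list", n_layers)  # post-activation inputs to each layer
  masks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    acts[[l]] <- H
    Z <- H %*% params$W[[l]] + rep(params$b[[l]], each = nrow(H))
    if (l < n_layers) {
      H <- relu(Z)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - dropout) /
                         (1 - dropout), nrow(H), ncol(H))
        H <- H * mask
        masks[[l]] <- mask
      }
    } else {
      H <- Z
    }
  }
  list(logits = H, acts = acts, masks = masks)
}

# gradient of mean cross-entropy wrt parameters; dZ is (probs - onehot)/n
backward_pass <- function(params, fwd, dZ) {
  n_layers <- length(params$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- dZ
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Fit the cell-type classifier
#'
#' Trains a feed-forward network (ReLU hidden layers, dropout, softmax
#' output over the reference classes) by minibatch Adam on the
#' cross-entropy loss. Training is deterministic given the data, config
#' and seed. The per-epoch training log records the full-dataset mean
#' cross-entropy evaluated without dropout after each epoch.
#'
#' @param ref A [labeled_reference()]. A raw-layer matrix is normalized
#'   with [normalize_expression()] defaults first.
#' @param config A [fit_config()].
#' @return An object of class `cell_classifier`.
#' @export
fit_classifier <- function(ref, config = fit_config()) {
  stopifnot(inherits(ref, "labeled_reference"), inherits(config, "fit_config"))
  m <- ref$matrix
  if (m$layer == "raw") m <- normalize_expression(m)
  X <- m$values
  counts <- table(factor(ref$labels, levels = ref$class_names))
  if (any(counts < 1)) {
    stop("classes with no cells: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  y <- match(ref$labels, ref$class_names)
  n <- nrow(X)
  k <- length(ref$class_names)

  set.seed(config$seed)
  scale_stats <- NULL
  if (isTRUE(config$scale_genes)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    scale_stats <- list(center = mu, scale = sdv)
  }
  params <- init_weights(ncol(X), config$hidden, k)
  state <- adam_init(params)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), y)] <- 1

  log_loss <- function(p) {
    fwd <- forward_pass(p, X)
    probs <- softmax_rows(fwd$logits)
    -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-300)))
  }
  training_log <- tibble::tibble(epoch = integer(), loss = double())
  if (config$epochs > 0) {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        fwd <- forward_pass(params, X[idx, , drop = FALSE],
                            dropout = config$dropout, train = TRUE)
        probs <- softmax_rows(fwd$logits)
        dZ <- (probs - Y[idx, , drop = FALSE]) / length(idx)
        grads <- backward_pass(params, fwd, dZ)
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params
        state <- upd$state
      }
      epoch_loss <- log_loss(params)
      if (!is.finite(epoch_loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; try a lower learning rate")
      }
      training_log <- dplyr::bind_rows(
        training_log, tibble::tibble(epoch = epoch, loss = epoch_loss))
    }
  }
  structure(
    list(params = params, class_names = ref$class_names,
         gene_ids = m$gene_ids, hidden = config$hidden,
         dropout = config$dropout, scale_stats = scale_stats,
         training_log = training_log, config = config),
    class = "cell_classifier"
  )
}

#' @exportS3Method base::print
print.cell_classifier <- function(x, ...) {
  cat(sprintf("<cell_classifier> %d genes -> [%s] -> %d classes\n",
              length(x$gene_ids), paste(x$hidden, collapse = ", "),
              length(x$class_names)))
  if (nrow(x$training_log) > 0) {
    cat(sprintf("  trained %d epochs, final cross-entropy %.4f\n",
                nrow(x$training_log),
                x$training_log$loss[nrow(x$training_log)]))
  } else {
    cat("  untrained (epochs = 0)\n")
  }
  invisible(x)
}

model_input <- function(model, m) {
  stopifnot(is_expression_matrix(m))
  if (!identical(m$gene_ids, model$gene_ids)) {
    if (ncol(m$values) != length(model$gene_ids) ||
        !setequal(m$gene_ids, model$gene_ids)) {
      stop("gene space mismatch between model (", length(model$gene_ids),
           " genes) and matrix (", ncol(m$values),
           " genes); run align_genes() first")
    }
    m <- expression_matrix(m$values[, model$gene_ids, drop = FALSE],
                           m$cell_ids, model$gene_ids, layer = m$layer)
  }
  X <- m$values
  if (!is.null(model$scale_stats)) {
    X <- sweep(sweep(X, 2, model$scale_stats$center), 2,
               model$scale_stats$scale, "/")
  }
  X
}

#' Class-probability prediction
#'
#' Temperature-scaled softmax over the network logits. Rows sum to 1.
#'
#' @param model A [fit_classifier()] result.
#' @param m An [expression_matrix()] on the model's gene space
#'   (normalized layer expected).
#' @param temperature Positive softmax temperature (default 1).
#' @return Numeric matrix, cells x classes, rownames = cell ids,
#'   colnames = class names.
#' @export
predict_proba <- function(model, m, temperature = 1) {
  stopifnot(inherits(model, "cell_classifier"), temperature > 0)
  X <- model_input(model, m)
  logits <- forward_pass(model$params, X)$logits
  p <- softmax_rows(logits / temperature)
  dimnames(p) <- list(m$cell_ids, model$class_names)
  p
}

#' Hard cell-type prediction
#'
#' Argmax of [predict_proba()] at temperature 1; ties break to the lowest
#' class index.
#'
#' @inheritParams predict_proba
#' @return Character vector of class names, named by cell id.
#' @export
predict_type <- function(model, m) {
  p <- predict_proba(model, m, temperature = 1)
  stats::setNames(model$class_names[max.col(p, ties.method = "first")],
                  m$cell_ids)
}

# gradient of L(x) = -log max_k softmax(logits(x)/T) wrt the input rows
input_gradient <- function(model, X, temperature = 1, cell_ids = NULL) {
  fwd <- forward_pass(model$params, X)
  probs <- softmax_rows(fwd$logits / temperature)
  k <- max.col(fwd$logits, ties.method = "first")
  dZ <- probs
  dZ[cbind(seq_len(nrow(X)), k)] <- dZ[cbind(seq_len(nrow(X)), k)] - 1
  dZ <- dZ / temperature
  n_layers <- length(model$params$W)
  delta <- dZ
  for (l in rev(seq_len(n_layers))) {
    delta <- delta %*% t(model$params$W[[l]])
    if (l > 1) delta <- delta * (fwd$acts[[l]] > 0)
  }
  if (any(!is.finite(delta))) {
    bad <- which(apply(delta, 1, function(r) any(!is.finite(r))))
    id <- if (!is.null(cell_ids)) cell_ids[bad[1]] else bad[1]
    stop("non-finite input gradient for cell ", id)
  }
  delta
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fitted classifier
#' @param x A `cell_classifier`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss`.
#' @export
tidy.cell_classifier <- function(x, ...) x$training_log

#' One-row model summary
#' @param x A `cell_classifier`.
#' @param ... Unused.
#' @return Tibble with model dimensions, parameter count and final loss.
#' @export
glance.cell_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$params$W, length, 0L)) +
    sum(vapply(x$params$b, length, 0L))
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_classes = length(x$class_names),
    n_parameters = n_par,
    epochs = nrow(x$training_log),
    final_loss = if (nrow(x$training_log) > 0) {
      x$training_log$loss[nrow(x$training_log)]
    } else NA_real_
  )
}

#' Save / load a fitted classifier
#'
#' The model is stored as a directory: `model.yaml` (architecture, class
#' names, gene ids, config, training log) plus one whitespace-delimited
#' text file per weight matrix with full double precision.
#'
#' @param model A `cell_classifier`.
#' @param dir Directory to create/read.
#' @return `save_classifier` returns `dir` invisibly; `load_classifier`
#'   returns the reconstructed `cell_classifier`.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "cell_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    hidden = as.integer(model$hidden), dropout = model$dropout,
    class_names = model$class_names, gene_ids = model$gene_ids,
    config = unclass(model$config),
    scaled = !is.null(model$scale_stats),
    n_layers = length(model$params$W)
  )
  yaml::write_yaml(meta, file.path(dir, "model.yaml"))
  # full double precision (YAML rounds numerics)
  writeLines(
    c("epoch\tloss",
      sprintf("%d\t%.17g", model$training_log$epoch,
              model$training_log$loss)),
    file.path(dir, "training_log.tsv"))
  write_mat <- function(x, f) {
    con <- file(file.path(dir, f), "w")
    on.exit(close(con))
    writeLines(apply(matrix(sprintf("%.17g", x), nrow(x)), 1, paste,
                     collapse = " "), con)
  }
  for (l in seq_along(model$params$W)) {
    write_mat(model$params$W[[l]], sprintf("W%d.txt", l))
    write_mat(matrix(model$params$b[[l]], nrow = 1), sprintf("b%d.txt", l))
  }
  if (!is.null(model$scale_stats)) {
    write_mat(rbind(model$scale_stats$center, model$scale_stats$scale),
              "scale.txt")
  }
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  read_mat <- function(f) {
    m <- unname(as.matrix(utils::read.table(file.path(dir, f))))
    storage.mode(m) <- "double"
    m
  }
  W <- vector("list", meta$n_layers)
  b <- vector("list", meta$n_layers)
  for (l in seq_len(meta$n_layers)) {
    W[[l]] <- unname(read_mat(sprintf("W%d.txt", l)))
    b[[l]] <- as.numeric(read_mat(sprintf("b%d.txt", l)))
  }
  scale_stats <- NULL
  if (isTRUE(meta$scaled)) {
    sm <- read_mat("scale.txt")
    scale_stats <- list(center = as.numeric(sm[1, ]),
                        scale = as.numeric(sm[2, ]))
  }
  cfg <- meta$config
  config <- fit_config(hidden = cfg$hidden, dropout = cfg$dropout,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       lr = cfg$lr, seed = cfg$seed,
                       scale_genes = isTRUE(cfg$scale_genes))
  log_df <- utils::read.table(file.path(dir, "training_log.tsv"),
                              header = TRUE, sep = "\t")
  structure(
    list(params = list(W = W, b = b),
         class_names = as.character(meta$class_names),
         gene_ids = as.character(meta$gene_ids),
         hidden = as.integer(meta$hidden), dropout = meta$dropout,
         scale_stats = scale_stats,
         training_log = tibble::tibble(epoch = as.integer(log_df$epoch),
                                       loss = as.numeric(log_df$loss)),
         config = config),
    class = "cell_classifier"
  )
}
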