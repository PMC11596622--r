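#' Configuration for the MLP pair classifier
#'
#' The classifier is a multi-layer perceptron over the concatenated
#' compound and pathway count vectors: ReLU hidden layers with inverted
#' dropout, a single sigmoid output unit, binary cross-entropy loss, and
#' Adam updates with decoupled weight decay. Inputs are raw counts without
#' scaling. Defaults are sized for desk-scale datasets (hundreds of
#' compounds, tens of pathways); widen the hidden layers for KEGG-scale
#' feature dimensions.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param dropout Dropout probability on hidden activations, in [0, 1).
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled L2 penalty applied per step.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum passes over the training entries (0 gives an
#'   untrained network that predicts ~0.5 everywhere).
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without improvement of the epoch-mean training loss.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @param threshold Classification threshold on the predicted probability;
#'   probabilities >= threshold are labeled positive.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(64L, 32L), dropout = 0.1,
                       learning_rate = 3e-3, weight_decay = 0.1,
                       batch_size = 256L, max_epochs = 400L, patience = 40L,
                       seed = 1L, threshold = 0.5) {
  stopifnot(all(hidden_sizes >= 1L), dropout >= 0, dropout < 1,
            learning_rate > 0, weight_decay >= 0, batch_size >= 1L,
            max_epochs >= 0L, threshold > 0, threshold < 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 threshold = threshold),
            class = "mlp_config")
}

#' Assemble a dense batch of concatenated pair features
#'
#' Gathers the compound and pathway feature rows for the requested entries in
#' one block operation and concatenates them column-wise. The result is
#' identical to assembling each entry individually (one row = one compound
#' vector followed by one pathway vector), but the block gather is what makes
#' training on millions of conceptual entries tractable: the cross-joined
#' table itself is never materialized.
#'
#' @param ds A `pair_dataset`.
#' @param entry_indices Vector of 1-based entry indices.
#' @return Dense numeric matrix, one row per entry, `d_c + d_p` columns.
#' @export
assemble_batch <- function(ds, entry_indices) {
  ip <- entry_pairs(ds, entry_indices)
  cbind(as.matrix(ds$compound_matrix[ip[, "i_c"], , drop = FALSE]),
        as.matrix(ds$pathway_matrix[ip[, "i_p"], , drop = FALSE]))
}

.mlp_init <- function(input_dim, hidden_sizes) {
  dims <- c(input_dim, hidden_sizes, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    # He-style scaling for ReLU layers; small output layer keeps sigmoid ~0.5
    sd <- sqrt(2 / dims[l])
    if (l == length(W)) sd <- 1e-3
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sd),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  L <- length(par$W)
  A <- X
  cache <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    Z <- A %*% par$W[[l]]
    Z <- sweep(Z, 2L, par$b[[l]], "+")
    A_new <- pmax(Z, 0)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(A_new)) >= dropout,
                     nrow(A_new), ncol(A_new)) / (1 - dropout)
      A_new <- A_new * mask
    } else mask <- NULL
    cache[[l]] <- list(A_in = A, A_out = A_new, mask = mask)
    A <- A_new
  }
  z <- drop(A %*% par$W[[L]]) + par$b[[L]]
  cache[[L]] <- list(A_in = A)
  list(logits = z, cache = cache)
}

# gradient of mean BCE wrt parameters; y in {0,1}
.mlp_backward <- function(par, fwd, y) {
  L <- length(par$W)
  n <- length(y)
  p <- 1 / (1 + exp(-fwd$logits))
  delta <- matrix((p - y) / n, ncol = 1L)          # dL/dz at output
  gW <- vector("list", L)
  gb <- vector("list", L)
  gW[[L]] <- crossprod(fwd$cache[[L]]$A_in, delta)
  gb[[L]] <- colSums(delta)
  back <- delta %*% t(par$W[[L]])
  for (l in rev(seq_len(L - 1L))) {
    cc <- fwd$cache[[l]]
    d_act <- (cc$A_out > 0) * 1
    if (!is.null(cc$mask)) d_act <- d_act * cc$mask
    delta <- back * d_act
    gW[[l]] <- crossprod(cc$A_in, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) back <- delta %*% t(par$W[[l]])
  }
  list(W = gW, b = gb)
}

.bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Train the MLP pair classifier
#'
#' Minimizes binary cross-entropy over the training entries of a split plan.
#' Epoch shuffling, weight initialization and dropout masks are driven by a
#' seeded generator, so training is reproducible given `(plan, cfg)`.
#' Training aborts with a diagnostic if the loss becomes non-finite and
#' errors if the training entries contain a single class.
#'
#' @param ds A `pair_dataset`.
#' @param plan A `split_plan` from [stratified_split()]; only
#'   `plan$train` is used for fitting.
#' @param cfg An [mlp_config()].
#' @param verbose Print the per-epoch training loss.
#' @return A fitted model of class `kegg_mlp` with the parameter set, the
#'   config echo, the input dimension, and the training-loss trace.
#' @export
mlp_fit <- function(ds, plan, cfg = mlp_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(plan, "split_plan"),
            inherits(cfg, "mlp_config"))
  train_idx <- plan$train
  if (length(train_idx) == 0L) stop("empty training set")
  y <- entry_labels(ds, train_idx)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; both labels are required")
  input_dim <- ncol(ds$compound_matrix) + ncol(ds$pathway_matrix)
  trace <- numeric(0)
  par <- local_seed(cfg$seed, {
    par <- .mlp_init(input_dim, cfg$hidden_sizes)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    best <- Inf; wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_idx))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        sel <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        X <- assemble_batch(ds, train_idx[sel])
        yb <- y[sel]
        fwd <- .mlp_forward(par, X, dropout = cfg$dropout, training = TRUE)
        loss <- .bce_loss(fwd$logits, yb)
        if (!is.finite(loss))
          stop(sprintf("training aborted: non-finite loss at epoch %d", epoch))
        losses <- c(losses, loss)
        g <- .mlp_backward(par, fwd, yb)
        t <- t + 1L
        for (l in seq_along(par$W)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
          mW_hat <- mW[[l]] / (1 - beta1^t); vW_hat <- vW[[l]] / (1 - beta2^t)
          mb_hat <- mb[[l]] / (1 - beta1^t); vb_hat <- vb[[l]] / (1 - beta2^t)
          par$W[[l]] <- par$W[[l]] -
            cfg$learning_rate * (mW_hat / (sqrt(vW_hat) + eps) +
                                   cfg$weight_decay * par$W[[l]])
          par$b[[l]] <- par$b[[l]] -
            cfg$learning_rate * mb_hat / (sqrt(vb_hat) + eps)
        }
      }
      epoch_loss <- mean(losses)
      trace <- c(trace, epoch_loss)
      if (verbose)
        message(sprintf("epoch %d: train loss %.5f", epoch, epoch_loss))
      if (epoch_loss < best - 1e-4) { best <- epoch_loss; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    par
  })
  structure(list(parameters = par, config = cfg, input_dim = input_dim,
                 loss_trace = trace),
            class = "kegg_mlp")
}

#' @export
print.kegg_mlp <- function(x, ...) {
  cat(sprintf("<MLP pair classifier: input %d -> %s -> 1; %d epoch(s) trained>\n",
              x$input_dim, paste(x$config$hidden_sizes, collapse = " -> "),
              length(x$loss_trace)))
  invisible(x)
}

#' Predict compound-pathway associations
#'
#' Computes association probabilities for the requested entries and binary
#' labels at the threshold (probability >= threshold is positive).
#' Deterministic given the fitted parameters.
#'
#' @param object A fitted `kegg_mlp`.
#' @param ds A `pair_dataset` with the same feature dimensions the model was
#'   trained on.
#' @param entry_indices Vector of 1-based entry indices; default all entries.
#' @param threshold Decision threshold; defaults to the training config's.
#' @param batch_size Entries scored per block.
#' @param ... Unused.
#' @return List with `probabilities` and `labels` (0/1), both in the order of
#'   `entry_indices`.
#' @export
predict.kegg_mlp <- function(object, ds, entry_indices = seq_len(n_entries(ds)),
                             threshold = NULL, batch_size = 8192L, ...) {
  stopifnot(inherits(ds, "pair_dataset"))
  d <- ncol(ds$compound_matrix) + ncol(ds$pathway_matrix)
  if (d != object$input_dim)
    stop(sprintf("feature dimension mismatch: model expects %d, dataset has %d",
                 object$input_dim, d))
  if (is.null(threshold)) threshold <- object$config$threshold
  probs <- numeric(length(entry_indices))
  for (start in seq(1L, length(entry_indices), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, length(entry_indices))
    X <- assemble_batch(ds, entry_indices[sel])
    z <- .mlp_forward(object$parameters, X)$logits
    probs[sel] <- 1 / (1 + exp(-z))
  }
  list(probabilities = probs, labels = as.numeric(probs >= threshold))
}

#' Save / load a fitted MLP
#'
#' Plain-text checkpoint: parameters as one JSON file (weights are stored in
#' full double precision as base-independent numeric arrays) with the config
#' alongside.
#'
#' @param model A `kegg_mlp`.
#' @param path File path for the checkpoint (JSON).
#' @return `read_mlp()` returns the restored `kegg_mlp`.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "kegg_mlp"))
  payload <- list(
    input_dim = model$input_dim,
    config = unclass(model$config),
    loss_trace = model$loss_trace,
    W = lapply(model$parameters$W, function(w)
      list(dim = dim(w), x = as.numeric(w))),
    b = model$parameters$b
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(seq_along(p$W$dim), function(l)
    matrix(p$W$x[[l]], p$W$dim[[l]][1], p$W$dim[[l]][2]))
  b <- if (is.list(p$b)) lapply(p$b, as.numeric) else list(as.numeric(p$b))
  cfg <- do.call(mlp_config, p$config)
  structure(list(parameters = list(W = W, b = b), config = cfg,
                 input_dim = p$input_dim, loss_trace = p$loss_trace),
            class = "kegg_mlp")
}
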