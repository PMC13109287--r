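# Compact convolutional classifier for residue-pair feature matrices.
#
# Architecture: conv(3x3, zero-padded) -> ReLU -> conv(3x3) -> ReLU ->
# dropout -> flatten -> dense -> ReLU -> dense(1) -> sigmoid. Trained with
# binary cross-entropy and Adam, early stopping on validation loss.
#
# Implemented directly in matrix algebra: convolutions are gather
# (im2col) + matrix multiply, with a sparse scatter matrix for the
# backward pass. Feature maps are stored as n x (C*H*W) matrices with flat
# index (c-1)*H*W + (w-1)*H + h; the reshapes between the gathered and the
# flat layout are plain matrix() calls because both orderings keep the
# sample index fastest. Gradients are verified against numerical
# differentiation in the test suite.

#' Classifier configuration
#'
#' Defaults are sized for the 3 x 10 complementarity input: two
#' convolutional layers of 16 and 32 filters (3 x 3 kernels, zero padding),
#' dropout 0.25, dense widths 64 and 1, Adam at learning rate 1e-3, at most
#' 200 epochs with early-stopping patience 20, batch size 64.
#'
#' @param filters Integer 2-vector of filter counts.
#' @param kernel Integer 2-vector, kernel height and width.
#' @param dropout Dropout rate after the second convolution.
#' @param dense Integer 2-vector of dense widths; the second must be 1.
#' @param learning_rate,epochs,patience,batch_size Training parameters.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(filters = c(16L, 32L), kernel = c(3L, 3L),
                              dropout = 0.25, dense = c(64L, 1L),
                              learning_rate = 1e-3, epochs = 200L,
                              patience = 20L, batch_size = 64L,
                              seed = 1337L) {
  stopifnot(
    length(filters) == 2, all(filters >= 1),
    length(kernel) == 2, all(kernel >= 1),
    dropout >= 0, dropout < 1,
    length(dense) == 2, dense[2] == 1,
    learning_rate > 0, epochs >= 1, batch_size >= 1
  )
  structure(
    list(
      filters = as.integer(filters), kernel = as.integer(kernel),
      dropout = dropout, dense = as.integer(dense),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

# gather index and scatter matrix for a zero-padded convolution
conv_plan <- function(C, H, W, kh, kw, pad = 1L) {
  HW <- H * W
  zero_slot <- C * HW + 1L
  G <- matrix(zero_slot, HW, kh * kw * C)
  for (c in seq_len(C)) {
    for (dw in seq_len(kw)) {
      for (dh in seq_len(kh)) {
        q <- (c - 1L) * kh * kw + (dw - 1L) * kh + dh
        for (w0 in seq_len(W)) {
          for (h0 in seq_len(H)) {
            h <- h0 + dh - 1L - pad
            w <- w0 + dw - 1L - pad
            p <- (w0 - 1L) * H + h0
            if (h >= 1 && h <= H && w >= 1 && w <= W) {
              G[p, q] <- (c - 1L) * HW + (w - 1L) * H + h
            }
          }
        }
      }
    }
  }
  gidx <- as.vector(G) # column-major: p fastest
  S <- Matrix::sparseMatrix(
    i = seq_along(gidx), j = gidx,
    x = 1, dims = c(length(gidx), zero_slot)
  )
  list(C = C, H = H, W = W, HW = HW, K = kh * kw * C, gidx = gidx, S = S)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained classifier
#'
#' @param config A [classifier_config()].
#' @param input_shape Height and width of the input matrix (default
#'   `c(3, 10)`: three complementarity kinds, partner plus nine neighbors).
#' @return A `cir_model` with randomly initialized weights (reproducible
#'   under `config$seed`) and a reported parameter count.
#' @export
build_model <- function(config = classifier_config(), input_shape = c(3L, 10L)) {
  H <- as.integer(input_shape[1])
  W <- as.integer(input_shape[2])
  kh <- config$kernel[1]
  kw <- config$kernel[2]
  pad <- 1L
  if (kh > H + 2L * pad || kw > W + 2L * pad) {
    abort("kernel larger than padded input", class = "surfcomp_config_error")
  }
  F1 <- config$filters[1]
  F2 <- config$filters[2]
  D1 <- config$dense[1]
  plan1 <- conv_plan(1L, H, W, kh, kw, pad)
  plan2 <- conv_plan(F1, H, W, kh, kw, pad)
  flat <- F2 * H * W
  weights <- with_seed(config$seed, list(
    W1 = he_init(plan1$K, F1, plan1$K), b1 = numeric(F1),
    W2 = he_init(plan2$K, F2, plan2$K), b2 = numeric(F2),
    W3 = he_init(flat, D1, flat), b3 = numeric(D1),
    W4 = he_init(D1, 1L, D1), b4 = numeric(1L)
  ))
  model <- list(
    config = config, input_shape = c(H, W),
    plan1 = plan1, plan2 = plan2, flat = flat,
    weights = weights,
    n_parameters = sum(vapply(weights, length, numeric(1))),
    trained = FALSE, history = NULL, norm_stats = NULL
  )
  class(model) <- "cir_model"
  model
}

#' @export
print.cir_model <- function(x, ...) {
  cat(
    "<cir_model>", paste0(x$input_shape[1], "x", x$input_shape[2]),
    "input; conv", x$config$filters[1], "-> conv", x$config$filters[2],
    "-> dropout -> dense", x$config$dense[1], "-> dense 1 (sigmoid);",
    x$n_parameters, "parameters;",
    if (x$trained) "trained" else "untrained", "\n"
  )
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# gather + multiply for one conv layer; returns pre-activation in flat layout
conv_forward <- function(Xflat, plan, W, b) {
  n <- nrow(Xflat)
  Xp <- cbind(Xflat, 0)
  M <- matrix(Xp[, plan$gidx], n * plan$HW, plan$K)
  Z <- M %*% W
  Z <- sweep(Z, 2, b, "+")
  list(M = M, Z = Z, flat = matrix(as.vector(relu(Z)), n, ncol(W) * plan$HW))
}

conv_backward <- function(dFlat, fwd, plan, W) {
  n <- nrow(dFlat)
  FF <- ncol(W)
  dA <- matrix(as.vector(dFlat), n * plan$HW, FF)
  dZ <- dA * (fwd$Z > 0)
  dW <- crossprod(fwd$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  dXcol <- matrix(as.vector(dM), n, plan$HW * plan$K)
  dXp <- as.matrix(dXcol %*% plan$S)
  list(dX = dXp[, -ncol(dXp), drop = FALSE], dW = dW, db = db)
}

nn_forward <- function(model, X, dropout_mask = NULL) {
  w <- model$weights
  c1 <- conv_forward(X, model$plan1, w$W1, w$b1)
  c2 <- conv_forward(c1$flat, model$plan2, w$W2, w$b2)
  h2 <- c2$flat
  if (!is.null(dropout_mask)) h2 <- h2 * dropout_mask
  Z3 <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  A3 <- relu(Z3)
  Z4 <- sweep(A3 %*% w$W4, 2, w$b4, "+")
  list(c1 = c1, c2 = c2, h2 = h2, Z3 = Z3, A3 = A3, Z4 = Z4, p = sigmoid(Z4))
}

nn_backward <- function(model, X, y, fwd, dropout_mask = NULL) {
  w <- model$weights
  n <- nrow(X)
  dZ4 <- (fwd$p - y) / n # BCE + sigmoid
  dW4 <- crossprod(fwd$A3, dZ4)
  db4 <- colSums(dZ4)
  dA3 <- tcrossprod(dZ4, w$W4)
  dZ3 <- dA3 * (fwd$Z3 > 0)
  dW3 <- crossprod(fwd$h2, dZ3)
  db3 <- colSums(dZ3)
  dh2 <- tcrossprod(dZ3, w$W3)
  if (!is.null(dropout_mask)) dh2 <- dh2 * dropout_mask
  g2 <- conv_backward(dh2, fwd$c2, model$plan2, w$W2)
  g1 <- conv_backward(g2$dX, fwd$c1, model$plan1, w$W1)
  list(
    W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4
  )
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Convert a normalized feature table to a model input matrix
#'
#' Arranges the wide feature columns into the flat layout the classifier
#' expects (rows of the image = complementarity kinds in the order given,
#' columns = neighbors 0..9).
#'
#' @param features Normalized feature tibble.
#' @param kinds Character subset of `c("s", "e", "h")` selecting the rows.
#' @return List with `x` (n x (rows*10) matrix), `y` (0/1 labels or NULL),
#'   `meta` (metadata tibble), `shape`.
#' @export
as_model_input <- function(features, kinds = c("s", "e", "h")) {
  kinds <- match.arg(kinds, c("s", "e", "h", "d"), several.ok = TRUE)
  H <- length(kinds)
  W <- 10L
  x <- matrix(0, nrow(features), H * W)
  for (w0 in seq_len(W)) {
    for (h0 in seq_len(H)) {
      col <- paste0(kinds[h0], "_", w0 - 1L)
      if (!col %in% names(features)) abort(paste0("missing feature column ", col))
      x[, (w0 - 1L) * H + h0] <- features[[col]]
    }
  }
  if (anyNA(x)) abort("feature matrix contains NA; normalize first")
  y <- if ("label" %in% names(features)) {
    as.integer(features$label %in% c("core", "1", "TRUE", "interacting"))
  }
  meta_cols <- intersect(
    c(
      "chain_a", "resnum_a", "resname_a", "chain_b", "resnum_b",
      "resname_b", "label", "pair_class", "complex"
    ),
    names(features)
  )
  list(
    x = x, y = y, meta = tibble::as_tibble(features)[meta_cols],
    shape = c(H, W), kinds = kinds
  )
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam; shuffled mini-batches and
#' dropout are reproducible under the config seed. Training stops early
#' when the validation loss has not improved for `patience` epochs and the
#' best-validation weights are restored.
#'
#' @param model An untrained (or warm) `cir_model` from [build_model()].
#' @param train List from [as_model_input()] (with labels), or a normalized
#'   feature tibble.
#' @param val Optional validation set in the same form.
#' @param config Overrides `model$config` when given.
#' @param norm_stats Normalization stats to store for inference.
#' @param verbose Print per-epoch losses.
#' @return The trained model with a `history` tibble (epoch, train loss,
#'   validation loss, training accuracy).
#' @export
train_classifier <- function(model, train, val = NULL, config = NULL,
                             norm_stats = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cir_model"))
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  if (is.data.frame(train)) train <- as_model_input(train)
  if (is.data.frame(val)) val <- as_model_input(val)
  if (is.null(train$y)) abort("training set has no labels")
  X <- train$x
  y <- matrix(train$y, ncol = 1)
  n <- nrow(X)
  state <- list(
    w = model$weights,
    m = lapply(model$weights, function(w) w * 0),
    v = lapply(model$weights, function(w) w * 0)
  )
  best <- list(loss = Inf, weights = model$weights, epoch = 0L)
  hist <- list()
  t_step <- 0L
  p_keep <- 1 - cfg$dropout
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      batch_loss <- 0
      batch_hits <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        mask <- if (cfg$dropout > 0) {
          matrix(
            rbinom(length(idx) * model$flat, 1, p_keep) / p_keep,
            length(idx), model$flat
          )
        }
        model$weights <- state$w
        fwd <- nn_forward(model, xb, dropout_mask = mask)
        if (!all(is.finite(fwd$p))) {
          abort("non-finite loss during training; lower the learning rate")
        }
        grads <- nn_backward(model, xb, yb, fwd, dropout_mask = mask)
        t_step <- t_step + 1L
        state <- adam_step(state, grads, cfg$learning_rate, t_step)
        batch_loss <- batch_loss + bce_loss(fwd$p, yb) * length(idx)
        batch_hits <- batch_hits + sum((fwd$p > 0.5) == (yb == 1))
      }
      model$weights <- state$w
      # train metrics accumulated from the minibatch passes (cheaper than
      # a second full-set forward; dropout makes them slightly pessimistic)
      tr_loss <- batch_loss / n
      tr_acc <- batch_hits / n
      va_loss <- NA_real_
      if (!is.null(val)) {
        p_va <- nn_forward(model, val$x)$p
        va_loss <- bce_loss(p_va, matrix(val$y, ncol = 1))
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss,
        val_loss = va_loss, train_acc = tr_acc
      )
      if (verbose) {
        cat(sprintf(
          "epoch %3d train %.4f val %s\n", epoch, tr_loss,
          ifelse(is.na(va_loss), "-", sprintf("%.4f", va_loss))
        ))
      }
      monitor <- if (is.null(val)) tr_loss else va_loss
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, weights = state$w, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  if (!is.null(norm_stats)) model$norm_stats <- norm_stats
  model
}

#' Predict core-interaction probabilities
#'
#' Deterministic at inference (dropout disabled). Refuses obviously
#' unnormalized input (feature values outside `[0, 1]`).
#'
#' @param object A trained `cir_model`.
#' @param newdata Normalized feature tibble or [as_model_input()] list.
#' @param ... Unused.
#' @return A `prediction_set` tibble: metadata, `score` in `[0, 1]`, and
#'   `label`/`pair_class` when available.
#' @export
predict.cir_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as_model_input(newdata)
  if (nrow(newdata$x) == 0) {
    out <- tibble::tibble(score = numeric(0))
    class(out) <- c("prediction_set", class(out))
    return(out)
  }
  if (min(newdata$x) < 0 || max(newdata$x) > 1) {
    abort("input features are not normalized to [0, 1]; run normalize_features()")
  }
  p <- as.vector(nn_forward(object, newdata$x)$p)
  out <- newdata$meta
  out$score <- p
  if (!is.null(newdata$y)) out$truth <- as.integer(newdata$y)
  class(out) <- c("prediction_set", class(out))
  out
}

#' Tidy a fitted classifier
#'
#' One row per layer with its output shape and parameter count.
#'
#' @param x A `cir_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cir_model <- function(x, ...) {
  tibble::tibble(
    layer = c("conv1", "conv2", "dense1", "dense2"),
    output = c(
      paste0(x$config$filters[1], "x", x$input_shape[1], "x", x$input_shape[2]),
      paste0(x$config$filters[2], "x", x$input_shape[1], "x", x$input_shape[2]),
      as.character(x$config$dense[1]), "1"
    ),
    parameters = c(
      length(x$weights$W1) + length(x$weights$b1),
      length(x$weights$W2) + length(x$weights$b2),
      length(x$weights$W3) + length(x$weights$b3),
      length(x$weights$W4) + length(x$weights$b4)
    )
  )
}

#' One-row training summary of a fitted classifier
#'
#' @param x A `cir_model`.
#' @param ... Unused.
#' @return A tibble with parameter count, epochs run, best epoch and final
#'   losses.
#' @export
glance.cir_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = x$n_parameters,
    epochs_run = if (is.null(h)) 0L else nrow(h),
    best_epoch = x$best_epoch %||% NA_integer_,
    train_loss = if (is.null(h)) NA_real_ else h$train_loss[nrow(h)],
    val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)],
    train_acc = if (is.null(h)) NA_real_ else h$train_acc[nrow(h)]
  )
}

#' Save / load model weights
#'
#' Weights, config and normalization stats serialize to a plain JSON
#' archive so trained models are portable across sessions.
#'
#' @param model A `cir_model`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_model()` returns the restored model.
#' @export
write_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    input_shape = model$input_shape,
    weights = lapply(model$weights, function(w) {
      list(dim = if (is.matrix(w)) dim(w) else 0L, data = as.vector(w))
    }),
    norm_stats = if (!is.null(model$norm_stats)) as.data.frame(model$norm_stats),
    trained = model$trained
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, payload$config)
  model <- build_model(cfg, input_shape = payload$input_shape)
  model$weights <- lapply(payload$weights, function(w) {
    d <- unlist(w$dim)
    v <- as.numeric(unlist(w$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
  if (!is.null(payload$norm_stats)) {
    model$norm_stats <- tibble::as_tibble(payload$norm_stats)
  }
  model$trained <- isTRUE(payload$trained)
  model
}
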