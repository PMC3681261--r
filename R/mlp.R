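#' Training configuration for the multilayer perceptron
#'
#' The classifier is a fully connected 13-10-1 network with sigmoid hidden
#' and output units, trained by full-batch gradient descent on the
#' mean-squared error, stopping at `target_mse` or after `max_iterations`
#' epochs. The defaults fix the target MSE at 1e-4 and the iteration cap at
#' 5000.
#'
#' @param n_hidden hidden-layer size (default 10).
#' @param learning_rate gradient-descent step size (default 0.05).
#' @param momentum classical momentum coefficient in \[0, 1) (default 0.9).
#' @param max_iterations epoch cap (default 5000).
#' @param target_mse early-stopping MSE target (default 1e-4).
#' @param seed integer seed for weight initialization.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 10, learning_rate = 0.05, momentum = 0.9,
                       max_iterations = 5000, target_mse = 1e-4, seed = 1L) {
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate, momentum = momentum,
                 max_iterations = as.integer(max_iterations),
                 target_mse = target_mse, seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(model, xs) {
  h <- sigmoid(sweep(xs %*% model$w1, 2L, model$b1, `+`))
  o <- as.numeric(sigmoid(h %*% model$w2 + model$b2))
  list(h = h, o = o)
}

# analytic gradients of mean((o - y)^2) w.r.t. all parameters
mlp_gradients <- function(model, xs, y) {
  fw <- mlp_forward(model, xs)
  n <- nrow(xs)
  do <- 2 * (fw$o - y) / n * fw$o * (1 - fw$o)      # n-vector
  gw2 <- drop(t(fw$h) %*% do)
  gb2 <- sum(do)
  dh <- outer(do, drop(model$w2)) * fw$h * (1 - fw$h)   # n x h
  gw1 <- t(xs) %*% dh
  gb1 <- colSums(dh)
  list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2,
       mse = mean((fw$o - y)^2))
}

standardize_features <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, `-`), 2L, scale, `/`)
}

#' Train the 13-10-1 perceptron
#'
#' Full-batch gradient descent (with optional momentum) on the MSE between
#' the sigmoid output and the 0/1 class targets. Inputs are z-scored with
#' training-set statistics, which are stored in the model and re-applied at
#' prediction time. Initialization draws uniform(-0.5, 0.5) weights scaled by
#' the inverse square root of the fan-in, deterministically under
#' `config$seed`.
#'
#' @param x numeric matrix, one row per example (typically 13 pooled cepstral
#'   coefficients).
#' @param y numeric or integer 0/1 labels (1 = pathological); both classes
#'   must be present with at least two examples each.
#' @param config an [mlp_config()].
#' @return a list with elements `model` (class `mlp_model`) and `report`
#'   (class `mlp_train_report`: `final_mse`, `iterations_run`, `converged`,
#'   `loss_curve`).
#' @export
train_mlp <- function(x, y, config = mlp_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(is.finite(x))) stop("features contain non-finite values")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 (normal) or 1 (pathological)")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (sum(y == 0) < 2L || sum(y == 1) < 2L)
    stop("need at least two examples of each class")

  d <- ncol(x)
  h <- config$n_hidden
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  xs <- standardize_features(x, center, scale)

  model <- withr::with_seed(config$seed, {
    list(w1 = matrix(runif(d * h, -0.5, 0.5) / sqrt(d), d, h),
         b1 = numeric(h),
         w2 = matrix(runif(h, -0.5, 0.5) / sqrt(h), h, 1L),
         b2 = 0)
  })
  model$layer_sizes <- c(d, h, 1L)
  model$activation <- "sigmoid"
  model$center <- center
  model$scale <- scale
  model$config <- config

  vel <- list(w1 = model$w1 * 0, b1 = numeric(h), w2 = model$w2 * 0, b2 = 0)
  lr <- config$learning_rate
  mo <- config$momentum
  loss <- numeric(config$max_iterations)
  it <- 0L
  converged <- FALSE
  while (it < config$max_iterations) {
    g <- mlp_gradients(model, xs, y)
    vel$w1 <- mo * vel$w1 - lr * g$w1
    vel$b1 <- mo * vel$b1 - lr * g$b1
    vel$w2 <- mo * vel$w2 - lr * matrix(g$w2, ncol = 1L)
    vel$b2 <- mo * vel$b2 - lr * g$b2
    model$w1 <- model$w1 + vel$w1
    model$b1 <- model$b1 + vel$b1
    model$w2 <- model$w2 + vel$w2
    model$b2 <- model$b2 + vel$b2
    it <- it + 1L
    loss[it] <- mean((mlp_forward(model, xs)$o - y)^2)
    if (loss[it] <= config$target_mse) { converged <- TRUE; break }
  }
  model <- structure(model, class = "mlp_model")
  report <- structure(list(final_mse = loss[it], iterations_run = it,
                           converged = converged,
                           loss_curve = loss[seq_len(it)]),
                      class = "mlp_train_report")
  list(model = model, report = report)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, sigmoid units, seed %d\n",
              paste(x$layer_sizes, collapse = "-"), x$config$seed))
  invisible(x)
}

#' @export
print.mlp_train_report <- function(x, ...) {
  cat(sprintf("<mlp_train_report> %d iterations, final MSE %.3g (%s)\n",
              x$iterations_run, x$final_mse,
              if (x$converged) "reached target" else "iteration cap"))
  invisible(x)
}

#' Predict class scores and labels
#'
#' Scores are the sigmoid output in (0, 1); the label is pathological (1)
#' when the score is at least 0.5 (ties favor the pathological class, i.e.
#' sensitivity).
#'
#' @param object an `mlp_model`.
#' @param newdata numeric matrix (or single vector) of raw features; they are
#'   standardized with the training statistics stored in the model.
#' @param ... unused.
#' @return a data frame with columns `score` and `label` (0/1).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$layer_sizes[1L])
    stop(sprintf("feature dimension %d does not match the model input size %d",
                 ncol(newdata), object$layer_sizes[1L]))
  if (!all(is.finite(newdata))) stop("features contain non-finite values")
  xs <- standardize_features(newdata, object$center, object$scale)
  score <- mlp_forward(object, xs)$o
  data.frame(score = score, label = as.integer(score >= 0.5))
}

flatten_params <- function(model) {
  c(as.numeric(model$w1), model$b1, as.numeric(model$w2), model$b2)
}

unflatten_params <- function(model, theta) {
  d <- model$layer_sizes[1L]; h <- model$layer_sizes[2L]
  i <- 0L
  model$w1 <- matrix(theta[i + seq_len(d * h)], d, h); i <- i + d * h
  model$b1 <- theta[i + seq_len(h)]; i <- i + h
  model$w2 <- matrix(theta[i + seq_len(h)], h, 1L); i <- i + h
  model$b2 <- theta[i + 1L]
  model
}

#' Check backpropagation against central finite differences
#'
#' Compares the analytic MSE gradient with a central-difference approximation
#' over every parameter of the network, on a (small) batch of raw features.
#'
#' @param model an `mlp_model`.
#' @param x raw feature matrix (standardized internally with the model's
#'   statistics).
#' @param y 0/1 targets.
#' @param eps finite-difference step (default 1e-5).
#' @return the maximum relative discrepancy across parameters.
#' @export
mlp_gradient_check <- function(model, x, y, eps = 1e-5) {
  x <- as.matrix(x)
  xs <- standardize_features(x, model$center, model$scale)
  analytic <- mlp_gradients(model, xs, y)
  ga <- c(as.numeric(analytic$w1), analytic$b1, analytic$w2, analytic$b2)
  theta <- flatten_params(model)
  loss_at <- function(th) {
    m <- unflatten_params(model, th)
    mean((mlp_forward(m, xs)$o - y)^2)
  }
  gn <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, numeric(1))
  max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-8))
}

#' Save / load an MLP model as JSON
#'
#' Serializes layer sizes, weights (row-major), activation, standardization
#' statistics and the training configuration at full double precision, so a
#' reloaded model reproduces predictions bit-identically.
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @return `save_mlp()`: `path` invisibly; `load_mlp()`: the `mlp_model`.
#' @export
save_mlp <- function(model, path) {
  enc <- function(v) sprintf("%.17g", as.numeric(v))  # lossless round trip
  payload <- list(
    layer_sizes = model$layer_sizes,
    activation = model$activation,
    w1 = enc(t(model$w1)), b1 = enc(model$b1),
    w2 = enc(model$w2), b2 = enc(model$b2),
    center = enc(model$center), scale = enc(model$scale),
    config = unclass(model$config))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- p$layer_sizes[1L]; h <- p$layer_sizes[2L]
  structure(list(
    w1 = matrix(as.numeric(p$w1), d, h, byrow = TRUE),
    b1 = as.numeric(p$b1),
    w2 = matrix(as.numeric(p$w2), h, 1L),
    b2 = as.numeric(p$b2),
    layer_sizes = as.integer(p$layer_sizes),
    activation = p$activation,
    center = as.numeric(p$center),
    scale = as.numeric(p$scale),
    config = do.call(mlp_config, as.list(p$config))),
    class = "mlp_model")
}
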