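#' Training configuration for one network
#'
#' @param window Sliding-window size; one of 5, 7, 9, 11, 13.
#' @param hidden_units Hidden-layer size; the full study grid crosses
#'   windows 5/7/9/11/13 with 50/75/100/125 hidden units (20
#'   architectures).
#' @param learning_rate Online gradient-descent step size.
#' @param max_epochs Training epochs; the returned weights are those of
#'   the best test-MCC epoch, not the last.
#' @param momentum,weight_decay Optional classic extensions (both default
#'   0).
#' @param init_range Weights are initialised uniformly in
#'   `[-init_range, init_range]`.
#' @param seed Integer seed controlling init and example shuffling.
#' @return A `bturn_train_config` list.
#' @export
train_config <- function(window = 9, hidden_units = 50,
                         learning_rate = 0.01, max_epochs = 300,
                         momentum = 0, weight_decay = 0,
                         init_range = 0.1, seed = 1) {
  structure(list(window = window, hidden_units = hidden_units,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 momentum = momentum, weight_decay = weight_decay,
                 init_range = init_range, seed = seed),
            class = "bturn_train_config")
}

#' The full architecture grid
#'
#' @param windows Window sizes.
#' @param hidden Hidden-unit counts.
#' @return Tibble with one row per architecture (`window`, `hidden_units`).
#' @export
architecture_grid <- function(windows = c(5, 7, 9, 11, 13),
                              hidden = c(50, 75, 100, 125)) {
  tidyr::expand_grid(window = windows, hidden_units = hidden)
}

#' Initialise network weights
#'
#' Weights are drawn uniformly from `[-init_range, init_range]` by a
#' dedicated generator, so the draw is fully determined by the seed.
#'
#' @param n_inputs Input dimension.
#' @param config A [train_config()].
#' @return List with `W1` (hidden x inputs), `b1`, `W2` (2 x hidden),
#'   `b2`.
#' @export
init_network <- function(n_inputs, config = train_config()) {
  .nn_init_cpp(as.integer(n_inputs), as.integer(config$hidden_units),
               config$init_range, as.integer(config$seed))
}

#' Forward pass: per-example turn score
#'
#' Hidden and output units are logistic; the score is the positive-class
#' share `out_pos / (out_pos + out_neg)` of the two output neurons, in
#' (0, 1).
#'
#' @param network A trained network (or raw weight list).
#' @param x Input vector, or a matrix with one example per row.
#' @return Numeric score(s).
#' @export
nn_forward <- function(network, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(network$W1)) {
    stop(sprintf("input has %d values but network expects %d",
                 ncol(x), ncol(network$W1)))
  }
  as.numeric(.nn_scores_cpp(x, network$W1, network$b1, network$W2,
                            network$b2))
}

#' Analytic error gradient for one example
#'
#' Gradient of the squared error of the two logistic outputs against the
#' one-hot target; used internally by training and exposed for
#' finite-difference verification.
#'
#' @param network Weight list.
#' @param x Input vector.
#' @param y Binary label (0/1).
#' @return List `gW1`, `gb1`, `gW2`, `gb2`, `loss`.
#' @export
nn_gradient <- function(network, x, y) {
  .nn_gradient_cpp(as.numeric(x), as.integer(y), network$W1, network$b1,
                   network$W2, network$b2)
}

#' Train one network with MCC-based epoch selection
#'
#' Online (per-example) gradient descent on the squared error, examples
#' visited in a freshly shuffled order each epoch. After every epoch the
#' Matthews correlation coefficient on the test examples (threshold 0.5)
#' is recorded; the returned network carries the weights of the
#' best-MCC epoch ("synapse weights stored for the best test-set MCC
#' epoch"), and that value is kept as `leaveout_mcc`.
#'
#' @param x_train,y_train Training examples (matrix rows) and binary
#'   labels.
#' @param x_test,y_test Test examples used for epoch selection; both
#'   classes must be present.
#' @param config A [train_config()].
#' @param fold Optional fold id recorded on the result.
#' @return A `bturn_net`: weights, architecture, `fold`, `best_epoch`,
#'   `leaveout_mcc` and the per-epoch `log`.
#' @export
train_backprop <- function(x_train, y_train, x_test, y_test,
                           config = train_config(), fold = NA_integer_) {
  y_train <- as.integer(as.logical(y_train))
  y_test <- as.integer(as.logical(y_test))
  if (length(y_train) == 0 || length(y_test) == 0) {
    stop("train and test sets must be nonempty")
  }
  if (length(unique(y_test)) < 2) {
    stop("test set must contain both classes (MCC undefined otherwise)")
  }
  fit <- .nn_train_cpp(x_train, y_train, x_test, y_test,
                       as.integer(config$hidden_units),
                       config$learning_rate,
                       as.integer(config$max_epochs),
                       config$momentum, config$weight_decay,
                       config$init_range, as.integer(config$seed))
  structure(list(
    W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = fit$W2,
    b2 = as.numeric(fit$b2),
    window = config$window, hidden_units = config$hidden_units,
    fold = fold, seed = config$seed,
    best_epoch = fit$best_epoch, leaveout_mcc = fit$leaveout_mcc,
    log = tibble::tibble(epoch = seq_along(fit$train_error),
                         train_error = fit$train_error,
                         test_mcc = fit$test_mcc)
  ), class = "bturn_net")
}

#' @export
print.bturn_net <- function(x, ...) {
  cat(sprintf(
    "<bturn_net: window %d, %d hidden, fold %s, best epoch %d, MCC %.3f>\n",
    x$window, x$hidden_units, as.character(x$fold), x$best_epoch,
    x$leaveout_mcc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bturn_net <- function(x, ...) x$log

#' @export
glance.bturn_net <- function(x, ...) {
  tibble::tibble(window = x$window, hidden_units = x$hidden_units,
                 fold = x$fold, best_epoch = x$best_epoch,
                 leaveout_mcc = x$leaveout_mcc)
}

#' Finite-difference check of the analytic gradient
#'
#' @param network Weight list.
#' @param x Input vector.
#' @param y Binary label.
#' @param eps Perturbation size.
#' @return Max relative error over all weights.
#' @export
gradient_check <- function(network, x, y, eps = 1e-6) {
  g <- nn_gradient(network, x, y)
  loss_at <- function(net) nn_gradient(net, x, y)$loss
  max_rel <- 0
  for (nm in c("W1", "b1", "W2", "b2")) {
    w <- network[[nm]]
    gw <- g[[paste0("g", nm)]]
    for (i in seq_along(w)) {
      np <- network; np[[nm]][i] <- w[i] + eps
      nm2 <- network; nm2[[nm]][i] <- w[i] - eps
      num <- (loss_at(np) - loss_at(nm2)) / (2 * eps)
      denom <- max(abs(num), abs(gw[i]), 1e-8)
      max_rel <- max(max_rel, abs(num - gw[i]) / denom)
    }
  }
  max_rel
}

#' Serialize a trained network to JSON text
#'
#' @param network A `bturn_net`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
write_network <- function(network, path = NULL) {
  payload <- list(
    architecture = list(window = network$window,
                        hidden_units = network$hidden_units,
                        inputs = ncol(network$W1)),
    fold = network$fold, seed = network$seed,
    best_epoch = network$best_epoch, leaveout_mcc = network$leaveout_mcc,
    W1 = network$W1, b1 = network$b1, W2 = network$W2, b2 = network$b2)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a serialized network
#' @param path JSON file from [write_network()].
#' @return A `bturn_net` (without training log).
#' @export
read_network <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(
    W1 = matrix(p$W1, nrow = p$architecture$hidden_units),
    b1 = as.numeric(p$b1),
    W2 = matrix(p$W2, nrow = 2), b2 = as.numeric(p$b2),
    window = p$architecture$window,
    hidden_units = p$architecture$hidden_units,
    fold = p$fold, seed = p$seed, best_epoch = p$best_epoch,
    leaveout_mcc = p$leaveout_mcc,
    log = NULL), class = "bturn_net")
}
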