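#' Hidden layer sizing rule
#'
#' Geometric-mean heuristic for the number of hidden neurons:
#' `round(sqrt(n_inputs * n_outputs))`, at least 1. With the package's five
#' ACE-R inputs and nine CHC outputs this gives 7, i.e. the 5-7-9 topology.
#'
#' @param n_inputs,n_outputs Positive integers.
#' @return A positive integer.
#' @export
#' @examples
#' hidden_size(5, 9)
hidden_size <- function(n_inputs, n_outputs) {
  if (length(n_inputs) != 1 || length(n_outputs) != 1 ||
      !is.finite(n_inputs) || !is.finite(n_outputs) ||
      n_inputs < 1 || n_outputs < 1) {
    abort("n_inputs and n_outputs must be single integers >= 1.",
      class = "chclevels_validation_error"
    )
  }
  max(1L, as.integer(round(sqrt(n_inputs * n_outputs))))
}

#' Logistic activation
#'
#' Standard logistic sigmoid with a steepness parameter:
#' `1 / (1 + exp(-steepness * z))`.
#'
#' @param z Numeric input (vectorised).
#' @param steepness Positive slope parameter (default 1).
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(z, steepness = 1) {
  1 / (1 + exp(-steepness * z))
}

#' Training configuration for the MLP surrogate
#'
#' The adaptation protocol: online backpropagation with a staged learning
#' rate (1.0 for cycles 1-1000, 0.5 for 1001-2000, 0.1 beyond), stopping at
#' the first cycle whose end-of-cycle total error reaches `threshold`. The
#' total error E is the Euclidean norm of the nine-dimensional output-error
#' vector averaged over the training set -- E <= 0.07 on a unit-scaled
#' output corresponds to near-perfect learning of the whole set -- while the
#' quantity the gradient descends is the quadratic loss of [mlp_loss()]. A
#' cycle is one full pass (epoch) over the training set.
#'
#' @param schedule A data frame with columns `from`, `to`, `rate`: contiguous
#'   increasing cycle ranges and their positive learning rates.
#' @param threshold Stop once the end-of-cycle total error E is `<=` this
#'   (default 0.07).
#' @param max_cycles Hard cap on cycles (default 10000).
#' @param init_range Weights and biases initialised uniformly on
#'   `[-init_range, init_range]`.
#' @param steepness Sigmoid steepness of every neuron (default 1).
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(schedule = NULL, threshold = 0.07, max_cycles = 10000,
                       init_range = 0.5, steepness = 1) {
  if (is.null(schedule)) {
    schedule <- tibble(
      from = c(1, 1001, 2001), to = c(1000, 2000, Inf), rate = c(1, 0.5, 0.1)
    )
  }
  schedule <- as_tibble(schedule)
  ok <- all(c("from", "to", "rate") %in% names(schedule)) &&
    all(schedule$rate > 0) && all(schedule$from <= schedule$to) &&
    schedule$from[1] == 1 &&
    (nrow(schedule) == 1 ||
      all(schedule$from[-1] == head(schedule$to, -1) + 1))
  if (!ok) {
    abort("Learning-rate schedule must cover contiguous increasing cycle ranges from 1 with positive rates.",
      class = "chclevels_validation_error"
    )
  }
  if (!is.finite(threshold) || threshold <= 0) {
    abort("threshold must be > 0.", class = "chclevels_validation_error")
  }
  structure(
    list(
      schedule = schedule, threshold = threshold,
      max_cycles = as.integer(max_cycles), init_range = init_range,
      steepness = steepness
    ),
    class = "mlp_config"
  )
}

schedule_rate <- function(schedule, cycle) {
  schedule$rate[which(cycle >= schedule$from & cycle <= schedule$to)[1]]
}

#' Initialise a feed-forward network
#'
#' A fully connected network with one hidden layer; weights and biases drawn
#' uniformly from `[-init_range, init_range]` (all zero when
#' `init_range = 0`). The hidden size defaults to the [hidden_size()] rule.
#'
#' @param n_inputs,n_outputs Layer sizes (defaults 5 and 9).
#' @param n_hidden Hidden layer size; `NULL` for auto-sizing.
#' @param init_range Half-width of the uniform initialisation interval.
#' @param steepness Sigmoid steepness.
#' @param seed Integer seed for reproducible initialisation (`NULL` to use
#'   the current RNG state).
#' @return A list of class `mlp_network` with elements `w1`, `b1`, `w2`,
#'   `b2`, `steepness`, `topology`.
#' @export
mlp_network <- function(n_inputs = 5, n_hidden = NULL, n_outputs = 9,
                        init_range = 0.5, steepness = 1, seed = NULL) {
  if (is.null(n_hidden)) n_hidden <- hidden_size(n_inputs, n_outputs)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) runif(n, -init_range, init_range)
  structure(
    list(
      w1 = matrix(draw(n_hidden * n_inputs), n_hidden, n_inputs),
      b1 = draw(n_hidden),
      w2 = matrix(draw(n_outputs * n_hidden), n_outputs, n_hidden),
      b2 = draw(n_outputs),
      steepness = steepness,
      topology = c(n_inputs = n_inputs, n_hidden = n_hidden, n_outputs = n_outputs)
    ),
    class = "mlp_network"
  )
}

#' Generate a machine-labelled training set
#'
#' Draws `n` input vectors uniformly on the unit hypercube (one value per
#' ACE-R domain) and labels each with the expert conversion's CHC
#' saturations, producing the training material for the surrogate network.
#'
#' @param n Number of training patterns (default 1000).
#' @param matrix A [transfer_matrix()].
#' @param seed Integer seed.
#' @return A tibble with five `*_norm` input columns and nine CHC target
#'   columns.
#' @export
#' @examples
#' head(mlp_training_set(10, seed = 1))
mlp_training_set <- function(n = 1000, matrix = default_transfer_matrix(),
                             seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(runif(n * 5), n, 5)
  colnames(x) <- paste0(acer_domains(), "_norm")
  y <- chc_saturation_matrix(x, matrix)
  dplyr::bind_cols(as_tibble(x), as_tibble(y))
}

# Split a training tibble into input (n x 5) and target (n x 9) matrices.
training_matrices <- function(data) {
  x <- acer_profile_matrix(data)
  missing <- setdiff(chc_domains(), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing target column(s): ", paste(missing, collapse = ", ")),
      class = "chclevels_validation_error"
    )
  }
  y <- as.matrix(data[chc_domains()])
  storage.mode(y) <- "double"
  validate_unit_interval(y, "Target saturation")
  list(x = x, y = y)
}

#' Forward propagation
#'
#' Propagates normalised ACE-R profiles through the network: affine map then
#' logistic activation per layer.
#'
#' @param network An [mlp_network()].
#' @param x A numeric matrix (rows = patterns, 5 columns) or a single profile
#'   vector of length 5.
#' @return A matrix (rows = patterns) of nine outputs in `(0, 1)`.
#' @export
mlp_forward <- function(network, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != network$topology[["n_inputs"]]) {
    abort("Input width does not match the network's input layer.",
      class = "chclevels_validation_error"
    )
  }
  s <- network$steepness
  a1 <- sigmoid(tcrossprod(x, network$w1) +
    rep(network$b1, each = nrow(x)), s)
  a2 <- sigmoid(tcrossprod(a1, network$w2) +
    rep(network$b2, each = nrow(x)), s)
  colnames(a2) <- chc_domains()[seq_len(ncol(a2))]
  a2
}

#' Quadratic training loss
#'
#' Mean over patterns of half the squared Euclidean distance between target
#' and network output: `L = 1/(2n) * sum_x ||y(x) - a(x)||^2`.
#'
#' @param network An [mlp_network()].
#' @param data A training tibble as from [mlp_training_set()].
#' @return A nonnegative scalar.
#' @export
mlp_loss <- function(network, data) {
  if (nrow(data) == 0) {
    abort("Training set is empty.", class = "chclevels_validation_error")
  }
  m <- training_matrices(data)
  sum((m$y - mlp_forward(network, m$x))^2) / (2 * nrow(m$x))
}

# Full-batch analytic gradient of the quadratic loss. Returns a list shaped
# like the network parameters. Used by batch-mode training and gradient tests.
mlp_gradients <- function(network, x, y) {
  n <- nrow(x)
  s <- network$steepness
  a1 <- sigmoid(tcrossprod(x, network$w1) + rep(network$b1, each = n), s)
  a2 <- sigmoid(tcrossprod(a1, network$w2) + rep(network$b2, each = n), s)
  d2 <- (a2 - y) * s * a2 * (1 - a2) / n
  d1 <- (d2 %*% network$w2) * s * a1 * (1 - a1)
  list(
    w1 = unname(crossprod(d1, x)), b1 = unname(colSums(d1)),
    w2 = unname(crossprod(d2, a1)), b2 = unname(colSums(d2))
  )
}

#' Train the MLP surrogate
#'
#' Backpropagation gradient descent on the quadratic loss. In the default
#' `"online"` mode weights are updated after every pattern, with the pattern
#' order reshuffled each cycle; `"batch"` mode performs one full-gradient
#' step per cycle (useful to verify monotone loss decrease). The staged
#' learning-rate schedule and the stopping rule come from [mlp_config()].
#' Training stops at the first cycle whose end-of-cycle loss reaches the
#' threshold; hitting `max_cycles` first yields a warning and
#' `converged = FALSE` in the report. The report tracks both the quadratic
#' loss and the total error E per cycle.
#'
#' @param data A training tibble with `*_norm` inputs and CHC targets (see
#'   [mlp_training_set()]).
#' @param config An [mlp_config()].
#' @param network Optional starting [mlp_network()]; by default a fresh
#'   network initialised under `seed`.
#' @param seed Integer seed controlling initialisation and pattern shuffling.
#' @param mode `"online"` (per-pattern updates) or `"batch"`.
#' @return An object of class `chc_mlp`: list with `network`, `report` (a
#'   one-row tibble: cycles, final_loss, final_error, converged),
#'   `trajectory` (per-cycle loss and error tibble), and `config`.
#' @export
#' @examples
#' train <- mlp_training_set(50, seed = 1)
#' fit <- mlp_train(train, mlp_config(max_cycles = 5), seed = 1)
#' glance(fit)
mlp_train <- function(data, config = mlp_config(), network = NULL, seed = NULL,
                      mode = c("online", "batch")) {
  mode <- match.arg(mode)
  if (nrow(data) == 0) {
    abort("Training set is empty.", class = "chclevels_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(network)) {
    network <- mlp_network(
      init_range = config$init_range, steepness = config$steepness
    )
  }
  m <- training_matrices(data)
  x <- m$x
  y <- m$y
  n <- nrow(x)
  s <- network$steepness
  w1 <- network$w1; b1 <- network$b1; w2 <- network$w2; b2 <- network$b2
  losses <- numeric(0)
  errors <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  while (cycle < config$max_cycles) {
    cycle <- cycle + 1L
    lr <- schedule_rate(config$schedule, cycle)
    if (mode == "online") {
      for (i in sample.int(n)) {
        xi <- x[i, ]
        a1 <- sigmoid(drop(w1 %*% xi) + b1, s)
        a2 <- sigmoid(drop(w2 %*% a1) + b2, s)
        d2 <- (a2 - y[i, ]) * s * a2 * (1 - a2)
        d1 <- drop(crossprod(w2, d2)) * s * a1 * (1 - a1)
        w2 <- w2 - lr * tcrossprod(d2, a1)
        b2 <- b2 - lr * d2
        w1 <- w1 - lr * tcrossprod(d1, xi)
        b1 <- b1 - lr * d1
      }
    } else {
      net <- network
      net$w1 <- w1; net$b1 <- b1; net$w2 <- w2; net$b2 <- b2
      g <- mlp_gradients(net, x, y)
      w1 <- w1 - lr * g$w1; b1 <- b1 - lr * g$b1
      w2 <- w2 - lr * g$w2; b2 <- b2 - lr * g$b2
    }
    a1 <- sigmoid(tcrossprod(x, w1) + rep(b1, each = n), s)
    a2 <- sigmoid(tcrossprod(a1, w2) + rep(b2, each = n), s)
    sq <- (y - a2)^2
    loss <- sum(sq) / (2 * n)
    err <- mean(sqrt(rowSums(sq)))
    if (!is.finite(loss)) {
      abort("Training loss became non-finite; reduce the learning rate.",
        class = "chclevels_training_error"
      )
    }
    losses[cycle] <- loss
    errors[cycle] <- err
    if (err <= config$threshold) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "Training stopped at max_cycles = %d with total error %.5f > threshold %.5f.",
      config$max_cycles, errors[cycle], config$threshold
    ))
  }
  network$w1 <- w1; network$b1 <- b1; network$w2 <- w2; network$b2 <- b2
  structure(
    list(
      network = network,
      report = tibble(
        cycles = cycle, final_loss = losses[cycle],
        final_error = errors[cycle], converged = converged
      ),
      trajectory = tibble(cycle = seq_len(cycle), loss = losses, error = errors),
      config = config
    ),
    class = "chc_mlp"
  )
}

#' @export
print.chc_mlp <- function(x, ...) {
  t <- x$network$topology
  cat(sprintf(
    "<chc_mlp> %d-%d-%d network, %d cycle(s), final loss %.5f, total error %.5f (%s)\n",
    t[1], t[2], t[3], x$report$cycles, x$report$final_loss, x$report$final_error,
    if (x$report$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Predict saturations or levels with a trained surrogate
#'
#' @param object A `chc_mlp` fit.
#' @param newdata A data frame with the five `*_norm` ACE-R columns.
#' @param type `"saturation"` for the raw network outputs, `"level"` for the
#'   six-segment game levels.
#' @param ... Unused.
#' @return A tibble: non-score columns of `newdata` plus nine CHC columns.
#' @export
predict.chc_mlp <- function(object, newdata,
                            type = c("saturation", "level"), ...) {
  type <- match.arg(type)
  out <- mlp_forward(object$network, acer_profile_matrix(newdata))
  out <- as_tibble(out)
  if (type == "level") {
    out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), saturation_to_level))
  }
  keep <- setdiff(names(newdata), c(chc_domains(), paste0(acer_domains(), "_norm")))
  dplyr::bind_cols(as_tibble(newdata)[keep], out)
}

#' @method tidy chc_mlp
#' @export
tidy.chc_mlp <- function(x, ...) {
  net <- x$network
  layer_tbl <- function(w, b, layer, from_names, to_names) {
    dplyr::bind_rows(
      tidyr::expand_grid(to = to_names, from = from_names) |>
        dplyr::mutate(layer = layer, term = "weight",
          estimate = as.vector(t(w)), .before = 1),
      tibble(layer = layer, term = "bias", to = to_names, from = NA_character_,
        estimate = b)
    )
  }
  hid <- paste0("h", seq_len(net$topology[["n_hidden"]]))
  ins <- paste0(acer_domains(), "_norm")[seq_len(net$topology[["n_inputs"]])]
  outs <- chc_domains()[seq_len(net$topology[["n_outputs"]])]
  dplyr::bind_rows(
    layer_tbl(net$w1, net$b1, "hidden", ins, hid),
    layer_tbl(net$w2, net$b2, "output", hid, outs)
  )[c("layer", "term", "from", "to", "estimate")]
}

#' @method glance chc_mlp
#' @export
glance.chc_mlp <- function(x, ...) {
  t <- x$network$topology
  tibble(
    n_inputs = t[["n_inputs"]], n_hidden = t[["n_hidden"]],
    n_outputs = t[["n_outputs"]], steepness = x$network$steepness,
    cycles = x$report$cycles, final_loss = x$report$final_loss,
    final_error = x$report$final_error, converged = x$report$converged
  )
}

#' Serialise a trained surrogate
#'
#' Writes/restores the network (topology, steepness, weights, biases) and its
#' training report as a JSON document.
#'
#' @param fit A `chc_mlp` object.
#' @param path File path.
#' @return `read_mlp()` returns a `chc_mlp`; `write_mlp()` returns `path`
#'   invisibly.
#' @export
write_mlp <- function(fit, path) {
  stopifnot(inherits(fit, "chc_mlp"))
  net <- fit$network
  doc <- list(
    topology = as.list(net$topology), steepness = net$steepness,
    w1 = net$w1, b1 = net$b1, w2 = net$w2, b2 = net$b2,
    report = as.list(fit$report)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  doc <- jsonlite::fromJSON(path)
  net <- structure(
    list(
      w1 = as.matrix(doc$w1), b1 = as.numeric(doc$b1),
      w2 = as.matrix(doc$w2), b2 = as.numeric(doc$b2),
      steepness = doc$steepness,
      topology = c(
        n_inputs = doc$topology$n_inputs, n_hidden = doc$topology$n_hidden,
        n_outputs = doc$topology$n_outputs
      )
    ),
    class = "mlp_network"
  )
  structure(
    list(
      network = net, report = as_tibble(doc$report),
      trajectory = NULL, config = NULL
    ),
    class = "chc_mlp"
  )
}
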