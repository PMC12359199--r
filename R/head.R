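#' Bin index of an LDDT value
#'
#' The confidence head discretizes LDDT into 50 bins of width 2; bin b
#' (1-based) covers \[2(b-1), 2b), with the top bin closed so that a score
#' of exactly 100 falls in bin 50.
#'
#' @param lddt numeric vector of scores in \[0, 100\].
#' @return integer vector of bin indices in 1..50.
#' @export
lddt_bin <- function(lddt) {
  if (any(lddt < 0 | lddt > 100, na.rm = TRUE)) stop("LDDT must be in [0, 100]")
  pmin(as.integer(floor(lddt / 2)), 49L) + 1L
}

#' Expected pLDDT of a bin distribution
#'
#' Reads a scalar per-residue confidence out of the 50-bin distribution as
#' the expectation over bin centers (1, 3, ..., 99).
#'
#' @param probs L x 50 matrix of row-stochastic bin probabilities.
#' @return numeric vector of length L with values in \[1, 99\].
#' @export
bins_to_plddt <- function(probs) {
  probs <- rbind(probs)
  stopifnot(ncol(probs) == 50)
  centers <- 2 * (0:49) + 1
  as.numeric(probs %*% centers)
}

#' Bin weights from a training LDDT distribution
#'
#' Training sets of near-native models are dominated by high LDDT values;
#' to correct for that, each of the 50 bins receives weight
#' 1 - (fraction of training residues falling in the bin), so
#' overrepresented bins are down-weighted in the loss.
#'
#' @param training_lddt numeric vector of residue LDDT values in \[0, 100\]
#'   (NAs dropped).
#' @return numeric vector of 50 weights in \[0, 1\] summing to 49.
#' @export
compute_bin_weights <- function(training_lddt) {
  v <- training_lddt[!is.na(training_lddt)]
  if (!length(v)) stop("no defined LDDT values")
  f <- tabulate(lddt_bin(v), nbins = 50) / length(v)
  1 - f
}

#' Bin-weighted cross-entropy loss
#'
#' Cross-entropy between the predicted bin distribution and the true-LDDT
#' bin, with each residue weighted by its true bin's weight and the total
#' normalized by the sum of applied weights (so uniform weights reduce to
#' plain mean cross-entropy). Residues with undefined true LDDT are masked
#' out. Log-probabilities are clamped at -30.
#'
#' @param probs L x 50 row-stochastic matrix.
#' @param true_lddt length-L numeric vector (NA = masked).
#' @param weights length-50 weight vector (see [compute_bin_weights()]).
#' @return scalar loss.
#' @export
weighted_bin_loss <- function(probs, true_lddt, weights = rep(1, 50)) {
  probs <- rbind(probs)
  stopifnot(nrow(probs) == length(true_lddt), length(weights) == 50)
  mask <- !is.na(true_lddt)
  if (!any(mask)) stop("all residues masked")
  b <- lddt_bin(true_lddt[mask])
  wi <- weights[b]
  denom <- sum(wi)
  if (denom == 0) return(0)
  logp <- pmax(log(probs[cbind(which(mask), b)]), -30)
  sum(wi * (-logp)) / denom
}

# loss + gradient wrt logits in one pass (training internal)
.loss_and_grad <- function(probs, true_lddt, weights) {
  L <- nrow(probs)
  mask <- which(!is.na(true_lddt))
  b <- lddt_bin(true_lddt[mask])
  wi <- weights[b]
  denom <- sum(wi)
  dlogits <- matrix(0, L, ncol(probs))
  if (denom == 0 || length(mask) == 0) return(list(loss = 0, dlogits = dlogits))
  psel <- probs[cbind(mask, b)]
  logp <- pmax(log(psel), -30)
  loss <- sum(wi * (-logp)) / denom
  a <- wi / denom
  a[logp <= -30] <- 0  # clamped terms carry no gradient
  dlogits[mask, ] <- a * probs[mask, , drop = FALSE]
  dlogits[cbind(mask, b)] <- dlogits[cbind(mask, b)] - a
  list(loss = loss, dlogits = dlogits)
}

.true_vector <- function(graph, lddt) {
  if (inherits(lddt, "lddt_profile")) lddt <- lddt$per_residue
  if (!is.null(names(lddt))) {
    unname(lddt[as.character(graph$residue_indices)])
  } else {
    stopifnot(length(lddt) == nrow(graph$coords))
    as.numeric(lddt)
  }
}

#' Fit the per-residue confidence (pLDDT) head
#'
#' Trains a confidence head that maps a protein graph — raw node and edge
#' feature tensors on a 16 Angstrom CA contact graph — to a 50-bin
#' distribution over the residue's LDDT, by stochastic gradient descent
#' (Adam, one protein per step) on the bin-weighted cross-entropy loss.
#' Two architectures are available: `"egnn"`, four E(n)-equivariant graph
#' convolutional layers (384 input node features, 128 hidden, 50 output)
#' whose messages see squared CA distances and learned edge features; and
#' `"mlp"`, an equally sized per-residue multilayer perceptron that ignores
#' the graph — the baseline the equivariant head is measured against.
#'
#' @param dataset list of records, each a list with elements `graph`
#'   (a [assemble_graph()] result) and `lddt` (an `lddt_profile` or named
#'   numeric vector of true scores on the 0-100 scale).
#' @param architecture `"egnn"` or `"mlp"`.
#' @param n_layers number of graph convolution / MLP blocks.
#' @param hidden hidden node feature width between layers.
#' @param node_dim width of the node transition layer output.
#' @param edge_hidden width of the edge transition layer output.
#' @param n_bins number of LDDT bins (bin width 100 / n_bins).
#' @param learning_rate Adam learning rate (default 1e-4, the rate used to
#'   fine-tune this kind of head).
#' @param weight_decay decoupled (AdamW-style) weight decay; at the small
#'   training sizes this package targets, most feature columns are
#'   uninformative and shrinkage is what keeps the head from memorizing
#'   them.
#' @param input_dropout probability of dropping each raw node/edge feature
#'   column per training step (inverted scaling on the kept columns);
#'   0 disables. Like the weight decay, this targets memorization of
#'   uninformative feature columns; prediction always uses all columns.
#' @param epochs training epochs (one pass over the proteins per epoch).
#' @param seed integer seed controlling initialization and shuffling.
#' @param bin_weights optional length-50 weight vector; default computed
#'   from the training set with [compute_bin_weights()].
#' @param verbose print the loss every few epochs.
#' @return an object of class `qa_head` with components `params`, `config`,
#'   `loss_trace`, `bin_weights` and the training data reference. Supports
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
qa_head <- function(dataset, architecture = c("egnn", "mlp"),
                    n_layers = 4L, hidden = 128L, node_dim = 384L,
                    edge_hidden = 128L, n_bins = 50L,
                    learning_rate = 1e-4, weight_decay = 5,
                    input_dropout = 0.2, epochs = 60L, seed = 1L,
                    bin_weights = NULL, verbose = FALSE) {
  architecture <- match.arg(architecture)
  stopifnot(length(dataset) >= 1, n_bins * (100 / n_bins) == 100)
  graphs <- lapply(dataset, `[[`, "graph")
  truths <- lapply(seq_along(dataset), function(i) {
    .true_vector(graphs[[i]], dataset[[i]]$lddt)
  })
  d_node <- unique(vapply(graphs, function(g) ncol(g$node_input), integer(1)))
  d_edge <- unique(vapply(graphs, function(g) ncol(g$edge_input), integer(1)))
  if (length(d_node) != 1 || length(d_edge) != 1) {
    stop("all graphs must share node/edge feature dimensions")
  }
  if (architecture == "mlp") d_edge <- 0L
  config <- list(architecture = architecture, n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden), node_dim = as.integer(node_dim),
                 edge_hidden = as.integer(edge_hidden),
                 n_bins = as.integer(n_bins),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 input_dropout = input_dropout, epochs = as.integer(epochs),
                 seed = as.integer(seed), d_node = d_node, d_edge = d_edge)
  if (is.null(bin_weights)) {
    bin_weights <- compute_bin_weights(unlist(truths))
  }
  set.seed(seed)
  params <- init_head_params(d_node, d_edge, config)
  state <- adam_init(params)
  n <- length(dataset)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- numeric(n)
    for (k in seq_along(ord)) {
      i <- ord[k]
      gi <- graphs[[i]]
      if (input_dropout > 0) {
        keepn <- stats::rbinom(ncol(gi$node_input), 1, 1 - input_dropout)
        gi$node_input <- sweep(gi$node_input, 2,
                               keepn / (1 - input_dropout), "*")
        if (ncol(gi$edge_input) > 0) {
          keepe <- stats::rbinom(ncol(gi$edge_input), 1, 1 - input_dropout)
          gi$edge_input <- sweep(gi$edge_input, 2,
                                 keepe / (1 - input_dropout), "*")
        }
      }
      fwd <- head_forward(gi, params, config, keep_cache = TRUE)
      lg <- .loss_and_grad(fwd$probs, truths[[i]], bin_weights)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", ep, ", protein ", i,
             "; try a smaller learning rate")
      }
      grads <- head_backward(lg$dlogits, fwd, gi, params, config)
      st <- adam_step(params, grads, state, learning_rate, weight_decay)
      params <- st$params
      state <- st$state
      ep_loss[k] <- lg$loss
    }
    trace[ep] <- mean(ep_loss)
    if (verbose && (ep %% 10 == 0 || ep == 1)) {
      message(sprintf("epoch %4d  loss %.4f", ep, trace[ep]))
    }
  }
  structure(list(params = params, config = config, loss_trace = trace,
                 bin_weights = bin_weights,
                 training = list(graphs = graphs, truths = truths),
                 call = match.call()),
            class = "qa_head")
}

#' @export
print.qa_head <- function(x, ...) {
  npar <- 0
  invisible(tree_map2(function(p, ...) {
    npar <<- npar + length(p); p
  }, x$params, NULL))
  cat(sprintf(
    "<qa_head> %s: %d layers, hidden %d, %d bins; %d parameters\n",
    x$config$architecture, x$config$n_layers, x$config$hidden,
    x$config$n_bins, npar))
  cat(sprintf("  trained %d epochs on %d proteins; loss %.4f -> %.4f\n",
              x$config$epochs, length(x$training$graphs),
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.qa_head <- function(object, ...) {
  fit <- fitted(object)
  errs <- vapply(seq_along(fit), function(i) {
    t <- object$training$truths[[i]]
    ok <- !is.na(t)
    mean(abs(fit[[i]][ok] - t[ok]))
  }, numeric(1))
  out <- list(config = object$config,
              final_loss = object$loss_trace[length(object$loss_trace)],
              training_model_error = errs)
  class(out) <- "summary.qa_head"
  out
}

#' @export
print.summary.qa_head <- function(x, ...) {
  cat(sprintf("Confidence head (%s), final training loss %.4f\n",
              x$config$architecture, x$final_loss))
  cat("Training model-level |pLDDT - LDDT| error:\n")
  print(summary(x$training_model_error))
  invisible(x)
}

#' @export
coef.qa_head <- function(object, ...) object$params

#' Predict per-residue confidence for new protein graphs
#'
#' @param object a fitted [qa_head()].
#' @param newdata a `protein_graph` or a list of them.
#' @param type `"plddt"` for the scalar expected-value readout, `"bins"`
#'   for the full L x 50 bin distribution.
#' @param ... unused.
#' @return numeric vector (or matrix for `"bins"`), or a list of them when
#'   `newdata` is a list; pLDDT values are named by residue index.
#' @export
predict.qa_head <- function(object, newdata, type = c("plddt", "bins"), ...) {
  type <- match.arg(type)
  one <- function(g) {
    stopifnot(inherits(g, "protein_graph"))
    if (ncol(g$node_input) != object$config$d_node) {
      stop("graph node feature dimension ", ncol(g$node_input),
           " does not match the fitted head (", object$config$d_node, ")")
    }
    fwd <- head_forward(g, object$params, object$config)
    if (type == "bins") {
      fwd$probs
    } else {
      setNames(bins_to_plddt(fwd$probs), g$residue_indices)
    }
  }
  if (inherits(newdata, "protein_graph")) one(newdata) else lapply(newdata, one)
}

#' @export
fitted.qa_head <- function(object, ...) {
  lapply(object$training$graphs, function(g) {
    predict(object, g)
  })
}

#' @export
residuals.qa_head <- function(object, ...) {
  fit <- fitted(object)
  lapply(seq_along(fit), function(i) {
    fit[[i]] - object$training$truths[[i]]
  })
}

#' @export
plot.qa_head <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "weighted bin loss",
                 main = sprintf("%s head training", x$config$architecture), ...)
  invisible(x)
}
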