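#' Training configuration for the per-channel classifier
#'
#' Defaults follow the screen's training protocol: Adam with learning rate
#' 1e-4 for 100 epochs, with the best epoch selected by validation loss.
#' For the scaled-down synthetic benchmarks a handful of epochs on 32-px
#' crops is sufficient and runs in seconds.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling; training is deterministic given the seed.
#' @param widths Channel widths of the two convolution blocks.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         batch_size = 32L, seed = 1L, widths = c(8L, 16L)) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            length(widths) == 2L, all(widths >= 1L))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 widths = as.integer(widths)),
            class = "TrainConfig")
}

init_weights <- function(side, widths, seed) {
  set.seed(mix_seed(seed, 31L))
  c1 <- widths[1]
  c2 <- widths[2]
  list(
    W1 = matrix(stats::rnorm(c1 * 9, 0, sqrt(2 / 9)), c1, 9),
    b1 = rep(0, c1),
    W2 = matrix(stats::rnorm(c2 * 9 * c1, 0, sqrt(2 / (9 * c1))), c2, 9 * c1),
    b2 = rep(0, c2),
    wd = stats::rnorm(c2, 0, sqrt(1 / c2)),
    bd = 0
  )
}

#' Train one binary knockout-vs-control classifier
#'
#' A compact convolutional network — two 3x3 convolution + ReLU + 2x2
#' max-pool blocks, global average pooling and a single sigmoid logit —
#' trained with Adam on binary cross-entropy. Per-epoch validation loss is
#' logged and the weights from the epoch with minimum validation loss are the
#' ones the model keeps (best-so-far checkpointing, equivalent to saving all
#' epochs and selecting afterwards).
#'
#' @param train,val Lists with `x` (n x side^2 image matrix) and `y` (0/1
#'   labels), e.g. from [materialize_split()].
#' @param config A [train_config()].
#' @return A `TrainedModel`: weights at the selected epoch, `selected_epoch`,
#'   the full validation/training loss trajectories and the architecture
#'   descriptor.
#' @export
train_classifier <- function(train, val, config = train_config()) {
  stopifnot(inherits(config, "TrainConfig"))
  if (is.null(train$x) || nrow(train$x) == 0L) stop("empty training split")
  if (is.null(val$x) || nrow(val$x) == 0L) stop("empty validation split")
  side <- as.integer(sqrt(ncol(train$x)))
  if (side * side != ncol(train$x)) stop("images must be square")
  if (side %% 4L != 0L) stop("image side must be divisible by 4")
  init <- init_weights(side, config$widths, config$seed)
  set.seed(mix_seed(config$seed, 32L))
  n <- nrow(train$x)
  perms <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                    integer(n)))
  fit <- .cnn_train_cpp(train$x, as.numeric(train$y), val$x,
                        as.numeric(val$y), side, config$epochs,
                        config$batch_size, config$learning_rate, init,
                        perms)
  structure(
    list(weights = fit$weights, final_weights = fit$final_weights,
         selected_epoch = fit$selected_epoch,
         val_loss = as.numeric(fit$val_loss),
         train_loss = as.numeric(fit$train_loss),
         side = side, widths = config$widths, config = config),
    class = "TrainedModel"
  )
}

#' Score images with a trained model
#'
#' @param model A `TrainedModel`.
#' @param x Image matrix (n x side^2), same side and normalization as
#'   training.
#' @return Numeric vector of scores in \[0,1\], one per row, in input order.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "TrainedModel"))
  if (ncol(x) != model$side^2) {
    stop("expected ", model$side^2, " pixels per image, got ", ncol(x))
  }
  as.numeric(.cnn_predict_cpp(model$weights, x, model$side))
}

#' Area under the ROC curve from two score sets
#'
#' Rank-based, threshold-free: the probability that a positive scores above a
#' random negative, with half credit for ties —
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param scores_pos,scores_neg Nonempty numeric score vectors for positives
#'   (knockout) and negatives (control).
#' @return AUC in \[0,1\].
#' @export
compute_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score lists must be nonempty")
  }
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a trained model on a test split
#'
#' @param model A `TrainedModel`.
#' @param test List with `x` and `y` (1 = knockout).
#' @return List with `auc`, `n_test_pos`, `n_test_neg`.
#' @export
evaluate_auc <- function(model, test) {
  s <- predict_scores(model, test$x)
  pos <- s[test$y == 1L]
  neg <- s[test$y == 0L]
  list(auc = compute_auc(pos, neg),
       n_test_pos = length(pos), n_test_neg = length(neg))
}
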