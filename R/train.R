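## Training: seeded mini-batch cross-entropy optimization with Adam or
## momentum SGD, per-epoch history, checkpointing, and transfer-learning
## hooks that load any pretrained tensors whose names and shapes match.

#' Training configuration
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size mini-batch size.
#' @param learning_rate step size (> 0).
#' @param optimizer `"adam"` or `"sgd"` (momentum SGD).
#' @param momentum SGD momentum coefficient.
#' @param seed integer seed controlling shuffling, dropout and
#'   initialization downstream.
#' @param pretrained path to a checkpoint to warm-start from, or `NULL`.
#' @param freeze_backbone_epochs epochs during which loaded (matched)
#'   weights stay frozen.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 32L, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         seed = 1L, pretrained = NULL,
                         freeze_backbone_epochs = 0L) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, optimizer = match.arg(optimizer),
    momentum = momentum, seed = as.integer(seed), pretrained = pretrained,
    freeze_backbone_epochs = as.integer(freeze_backbone_epochs)
  ), class = "train_config")
}

make_optimizer <- function(params, cfg) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list(); st$v <- list()
  step <- function() {
    st$t <- st$t + 1L
    lr <- cfg$learning_rate
    for (nm in names(params)) {
      p <- params[[nm]]
      if (is.null(p$grad) || isTRUE(p$frozen)) next
      g <- p$grad
      if (cfg$optimizer == "adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        if (is.null(st$m[[nm]])) {
          st$m[[nm]] <- g * 0
          st$v[[nm]] <- g * 0
        }
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
        st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
        mh <- st$m[[nm]] / (1 - b1^st$t)
        vh <- st$v[[nm]] / (1 - b2^st$t)
        p$data <- p$data - lr * mh / (sqrt(vh) + eps)
      } else {
        if (is.null(st$m[[nm]])) st$m[[nm]] <- g * 0
        st$m[[nm]] <- cfg$momentum * st$m[[nm]] + g
        p$data <- p$data - lr * st$m[[nm]]
      }
    }
  }
  list(step = step, state = st)
}

zero_grads <- function(model) {
  for (p in model$params) p$grad <- NULL
  invisible(NULL)
}

#' Train a model
#'
#' Cross-entropy training on a loaded image set. If `cfg$pretrained` is
#' set, all checkpoint tensors whose names and shapes match are loaded
#' first (new modules keep their fresh initialization) and optionally
#' frozen for the first `freeze_backbone_epochs` epochs. Fully seeded:
#' identical seeds give identical trajectories.
#'
#' @param model a model object (modified in place).
#' @param train_data,test_data lists with `x`, `y` as from
#'   [load_manifest_images()]; `test_data` may be `NULL`.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return data.frame history: epoch, train_loss, train_acc, test_loss,
#'   test_acc.
#' @export
train <- function(model, train_data, test_data = NULL,
                  cfg = train_config(), verbose = FALSE) {
  N <- length(train_data$y)
  if (N == 0L) stop("empty training set")
  set.seed(cfg$seed)
  frozen_names <- character(0)
  if (!is.null(cfg$pretrained)) {
    res <- load_pretrained(model, cfg$pretrained)
    frozen_names <- res$loaded
    if (cfg$freeze_backbone_epochs > 0L) {
      for (nm in frozen_names) model$params[[nm]]$frozen <- TRUE
    }
  }
  opt <- make_optimizer(model$params, cfg)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), test_loss = numeric(0),
                     test_acc = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    if (ep == cfg$freeze_backbone_epochs + 1L && length(frozen_names)) {
      for (nm in frozen_names) model$params[[nm]]$frozen <- FALSE
    }
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      xb <- train_data$x[, , , idx, drop = FALSE]
      yb <- train_data$y[idx]
      ag_tape_start()
      logits <- model$forward(ag_input(xb), training = TRUE)
      loss <- ag_softmax_xent(logits, yb)
      ag_backward(loss)
      ag_tape_stop()
      ep_loss <- ep_loss + loss$data * length(idx)
      ep_correct <- ep_correct + sum(apply(loss$probs, 2, which.max) == yb)
      opt$step()
      zero_grads(model)
    }
    te <- c(NA_real_, NA_real_)
    if (!is.null(test_data)) te <- eval_loss_acc(model, test_data, cfg$batch_size)
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss / N, train_acc = ep_correct / N,
      test_loss = te[1], test_acc = te[2]))
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f  test loss %s acc %s",
        ep, ep_loss / N, ep_correct / N,
        ifelse(is.na(te[1]), "-", sprintf("%.4f", te[1])),
        ifelse(is.na(te[2]), "-", sprintf("%.4f", te[2]))))
    }
  }
  hist
}

eval_loss_acc <- function(model, data, batch_size = 32L) {
  sc <- predict_scores(model, data$x, batch_size)
  sel <- cbind(data$y, seq_along(data$y))
  loss <- -mean(log(pmax(sc$probs[sel], 1e-12)))
  acc <- mean(apply(sc$probs, 2, which.max) == data$y)
  c(loss, acc)
}

## --- checkpoints and transfer learning ------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the model spec, all parameter tensors and the
#' batch-norm running moments.
#'
#' @param model a model object.
#' @param path file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the checkpoint list; `restore_model` a freshly built model with the
#'   checkpoint weights.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(
    spec = model$spec,
    params = lapply(model$params, function(p) p$data),
    states = lapply(model$states, function(s) list(mean = s$mean, var = s$var))
  )
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @rdname save_checkpoint
#' @export
restore_model <- function(path) {
  ck <- load_checkpoint(path)
  model <- build_model(ck$spec)
  load_pretrained(model, ck)
  model
}

#' Load matching pretrained tensors into a model
#'
#' Copies every checkpoint tensor whose name and shape match a model
#' parameter; mismatched or missing tensors are skipped and summarized.
#' Batch-norm running moments are copied for matching names.
#'
#' @param model a model object (modified in place).
#' @param checkpoint a checkpoint list or an RDS path.
#' @return list with `loaded` and `skipped` character vectors of parameter
#'   names.
#' @export
load_pretrained <- function(model, checkpoint) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  loaded <- character(0); skipped <- character(0)
  for (nm in names(model$params)) {
    src <- ck$params[[nm]]
    dst <- model$params[[nm]]
    if (!is.null(src) && identical(dim_of(src), dim_of(dst$data))) {
      dst$data <- src
      loaded <- c(loaded, nm)
    } else {
      skipped <- c(skipped, nm)
    }
  }
  for (nm in names(model$states)) {
    src <- ck$states[[nm]]
    if (!is.null(src) && length(src$mean) == length(model$states[[nm]]$mean)) {
      model$states[[nm]]$mean <- src$mean
      model$states[[nm]]$var <- src$var
    }
  }
  message(sprintf("transfer: loaded %d tensors, kept fresh init for %d",
                  length(loaded), length(skipped)))
  list(loaded = loaded, skipped = skipped)
}
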