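#' Plant-part classes recognised by the patch classifiers
#'
#' Class codes follow the label order 0 = silique base, 1 = silique body,
#' 2 = stem, 3 = silique tip; 255 marks background in label images.
#' @export
POD_CLASSES <- c("base", "body", "stem", "tip")

#' Background code used in masks and label images
#' @export
POD_BACKGROUND <- 255L

#' LeNet patch-classifier configuration
#'
#' The baseline architecture: two convolution + max-pooling stages followed by
#' two fully connected layers and a softmax head. Filter counts (20/50/500)
#' follow the canonical small-image LeNet.
#'
#' @param conv1_filters,conv2_filters filters in the two 5x5 convolutions
#' @param fc_units units in the first fully connected layer
#' @param n_classes output classes
#' @return a config list with class `"lenet_config"`
#' @export
lenet_config <- function(conv1_filters = 20, conv2_filters = 50,
                         fc_units = 500, n_classes = 4) {
  structure(list(arch = "lenet", conv1_filters = conv1_filters,
                 conv2_filters = conv2_filters, fc_units = fc_units,
                 n_classes = n_classes),
            class = "lenet_config")
}

#' DenseNet patch-classifier configuration
#'
#' Three dense blocks operating at 32x32, 16x16 and 8x8 feature maps, joined
#' by transition layers (batch norm, 1x1 convolution preserving channel count,
#' dropout, 2x2 average pooling), ending in global average pooling and a
#' softmax over the four classes. Within a block every layer receives the
#' concatenation of the block input and all preceding layers' outputs and adds
#' `growth` feature maps (growth rate k = 12 throughout by default).
#'
#' @param layers_per_block densely connected layers per block (12 gives the
#'   standard depth-40 configuration; tests and the scaled-down benchmark use
#'   a shallow variant)
#' @param growth growth rate k, identical for all blocks
#' @param init_channels filters of the initial 3x3 convolution
#' @param dropout dropout rate after each convolution
#' @param n_classes output classes
#' @return a config list with class `"densenet_config"`
#' @export
densenet_config <- function(layers_per_block = 12, growth = 12,
                            init_channels = 16, dropout = 0.2, n_classes = 4) {
  stopifnot(layers_per_block >= 1, growth >= 1)
  structure(list(arch = "densenet", layers_per_block = layers_per_block,
                 growth = growth, init_channels = init_channels,
                 dropout = dropout, n_classes = n_classes),
            class = "densenet_config")
}

#' Training protocol configuration
#'
#' Stochastic gradient descent with momentum 0.9, weight decay 1e-5, base
#' learning rate 0.001 and a step-down policy that multiplies the rate by
#' `lr_gamma` at each third of training (see [lr_schedule()]). Default batch
#' size and epoch count depend on the architecture: 64/15 for LeNet, 8/30 for
#' DenseNet.
#'
#' @param arch `"lenet"` or `"densenet"` (sets batch/epoch defaults)
#' @param base_lr initial learning rate
#' @param lr_gamma multiplicative step-down factor
#' @param momentum SGD momentum
#' @param weight_decay L2 penalty on weight matrices
#' @param batch_size minibatch size
#' @param epochs training epochs
#' @param seed integer seed controlling shuffling, dropout and initialisation
#' @param init optional path to a serialized parameter list used to initialise
#'   weights (e.g. weights pretrained elsewhere); default random
#' @return a config list with class `"train_config"`
#' @export
train_config <- function(arch = c("densenet", "lenet"), base_lr = 0.001,
                         lr_gamma = 0.1, momentum = 0.9, weight_decay = 1e-5,
                         batch_size = NULL, epochs = NULL, seed = 1,
                         init = NULL) {
  arch <- match.arg(arch)
  if (is.null(batch_size)) batch_size <- if (arch == "lenet") 64L else 8L
  if (is.null(epochs)) epochs <- if (arch == "lenet") 15L else 30L
  structure(list(arch = arch, base_lr = base_lr, lr_gamma = lr_gamma,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init = init),
            class = "train_config")
}

#' Step-down learning-rate schedule
#'
#' Piecewise-constant thirds: the learning rate is
#' `base_lr * lr_gamma^s` with `s = floor(3 * epoch / epochs)` capped at 2,
#' i.e. steps down at 33% and 66% of training.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`
#' @param cfg a [train_config()]
#' @return the learning rate for that epoch
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch < cfg$epochs)
  s <- min(floor(3 * epoch / cfg$epochs), 2)
  cfg$base_lr * cfg$lr_gamma^s
}

#' Build a patch classifier
#'
#' Instantiates the network for a [lenet_config()] or [densenet_config()],
#' with He-initialised weights drawn from `seed`, or weights loaded from
#' `init_file` when given.
#'
#' @param config architecture configuration
#' @param seed seed for random initialisation
#' @param init_file optional RDS file holding a compatible parameter list
#' @return a model object (list with `arch`, `config`, `params`, `classes`)
#' @export
build_model <- function(config, seed = 1, init_file = NULL) {
  params <- withr::with_seed(as.integer(seed), {
    if (inherits(config, "lenet_config")) init_lenet_params(config)
    else if (inherits(config, "densenet_config")) init_densenet_params(config)
    else stop("config must be a lenet_config or densenet_config")
  })
  if (!is.null(init_file)) {
    loaded <- readRDS(init_file)
    if (!setequal(names(loaded), names(params)))
      stop("pretrained parameter list does not match the architecture")
    params <- loaded
  }
  structure(list(arch = config$arch, config = config, params = params,
                 classes = POD_CLASSES),
            class = "pod_model")
}

init_lenet_params <- function(cfg) {
  list(
    conv1 = nn_init_conv(3, cfg$conv1_filters, 5),
    conv2 = nn_init_conv(cfg$conv1_filters, cfg$conv2_filters, 5),
    fc1 = nn_init_fc(5 * 5 * cfg$conv2_filters, cfg$fc_units),
    fc2 = nn_init_fc(cfg$fc_units, cfg$n_classes)
  )
}

init_densenet_params <- function(cfg) {
  k <- cfg$growth
  L <- cfg$layers_per_block
  p <- list(init = nn_init_conv(3, cfg$init_channels, 3))
  ch <- cfg$init_channels
  for (b in 1:3) {
    for (l in seq_len(L)) {
      p[[sprintf("b%d.l%d.bn", b, l)]] <- nn_init_bn(ch)
      p[[sprintf("b%d.l%d.conv", b, l)]] <- nn_init_conv(ch, k, 3)
      ch <- ch + k
    }
    if (b < 3) {
      p[[sprintf("t%d.bn", b)]] <- nn_init_bn(ch)
      p[[sprintf("t%d.conv", b)]] <- nn_init_conv(ch, ch, 1)
    }
  }
  p[["head.bn"]] <- nn_init_bn(ch)
  p[["head.fc"]] <- nn_init_fc(ch, cfg$n_classes)
  p
}

cat_channels <- function(a, b) cpp_concat_channels(a, dim(a), b, dim(b))

# Forward pass. Returns logits (N x K), the caches needed for the backward
# pass, the (possibly updated, for batch-norm running moments) model, and the
# spatial size at the input of each dense block.
model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) != 4 || dim(x)[1] != 32 || dim(x)[2] != 32 || dim(x)[3] != 3)
    stop("input must be a 32x32x3xN batch")
  if (model$arch == "lenet") lenet_forward(model, x, training)
  else densenet_forward(model, x, training)
}

lenet_forward <- function(model, x, training) {
  P <- model$params
  cc <- list()
  r <- conv_f(x, P$conv1, pad = 0, keep_im2col = training); cc$conv1 <- r$cache
  r <- maxpool_f(r$y); cc$pool1 <- r$cache
  r <- conv_f(r$y, P$conv2, pad = 0, keep_im2col = training); cc$conv2 <- r$cache
  r <- maxpool_f(r$y); cc$pool2 <- r$cache
  r <- flatten_f(r$y); cc$flat <- r$cache
  r <- fc_f(r$y, P$fc1); cc$fc1 <- r$cache
  r <- relu_f(r$y); cc$relu <- r$cache
  r <- fc_f(r$y, P$fc2); cc$fc2 <- r$cache
  list(logits = r$y, caches = cc, model = model, shapes = NULL)
}

lenet_backward <- function(model, caches, dlogits) {
  P <- model$params
  G <- list()
  r <- fc_b(P$fc2, caches$fc2, dlogits); G$fc2 <- r$grads
  dy <- relu_b(caches$relu, r$dx)
  r <- fc_b(P$fc1, caches$fc1, dy); G$fc1 <- r$grads
  dy <- flatten_b(caches$flat, r$dx)
  dy <- maxpool_b(caches$pool2, dy)
  r <- conv_b(P$conv2, caches$conv2, dy); G$conv2 <- r$grads
  dy <- maxpool_b(caches$pool1, r$dx)
  r <- conv_b(P$conv1, caches$conv1, dy); G$conv1 <- r$grads
  G
}

densenet_forward <- function(model, x, training) {
  cfg <- model$config
  P <- model$params
  L <- cfg$layers_per_block
  cc <- list()
  shapes <- integer(3)
  r <- conv_f(x, P$init, pad = 1, keep_im2col = training)
  cc$init <- r$cache
  x <- r$y
  for (b in 1:3) {
    shapes[b] <- dim(x)[1]
    for (l in seq_len(L)) {
      bnid <- sprintf("b%d.l%d.bn", b, l)
      cvid <- sprintf("b%d.l%d.conv", b, l)
      bn <- bn_f(x, P[[bnid]], training, relu = TRUE, need_cache = training); P[[bnid]] <- bn$p
      cv <- conv_f(bn$y, P[[cvid]], pad = 1, keep_im2col = training)
      dp <- dropout_f(cv$y, cfg$dropout, training)
      cc[[sprintf("b%d.l%d", b, l)]] <-
        list(bn = bn$cache, conv = cv$cache, drop = dp$cache,
             in_ch = dim(x)[3])
      x <- cat_channels(x, dp$y)
    }
    if (b < 3) {
      bnid <- sprintf("t%d.bn", b)
      cvid <- sprintf("t%d.conv", b)
      bn <- bn_f(x, P[[bnid]], training, need_cache = training); P[[bnid]] <- bn$p
      cv <- conv_f(bn$y, P[[cvid]], pad = 0, keep_im2col = training)
      dp <- dropout_f(cv$y, cfg$dropout, training)
      ap <- avgpool_f(dp$y)
      cc[[sprintf("t%d", b)]] <-
        list(bn = bn$cache, conv = cv$cache, drop = dp$cache, pool = ap$cache)
      x <- ap$y
    }
  }
  bn <- bn_f(x, P[["head.bn"]], training, relu = TRUE, need_cache = training); P[["head.bn"]] <- bn$p
  gp <- gap_f(bn$y)
  fc <- fc_f(gp$y, P[["head.fc"]])
  cc$head <- list(bn = bn$cache, gap = gp$cache, fc = fc$cache)
  model$params <- P
  list(logits = fc$y, caches = cc, model = model, shapes = shapes)
}

densenet_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  P <- model$params
  L <- cfg$layers_per_block
  G <- list()
  h <- caches$head
  r <- fc_b(P[["head.fc"]], h$fc, dlogits); G[["head.fc"]] <- r$grads
  dy <- gap_b(h$gap, r$dx)
  r <- bn_b(P[["head.bn"]], h$bn, dy); G[["head.bn"]] <- r$grads
  dx <- r$dx
  for (b in 3:1) {
    if (b < 3) {
      tc <- caches[[sprintf("t%d", b)]]
      dy <- avgpool_b(tc$pool, dx)
      dy <- dropout_b(tc$drop, dy)
      r <- conv_b(P[[sprintf("t%d.conv", b)]], tc$conv, dy)
      G[[sprintf("t%d.conv", b)]] <- r$grads
      r2 <- bn_b(P[[sprintf("t%d.bn", b)]], tc$bn, r$dx)
      G[[sprintf("t%d.bn", b)]] <- r2$grads
      dx <- r2$dx
    }
    for (l in rev(seq_len(L))) {
      lc <- caches[[sprintf("b%d.l%d", b, l)]]
      sp <- cpp_split_channels(dx, dim(dx), lc$in_ch)
      dx <- sp$head
      dy <- dropout_b(lc$drop, sp$tail)
      r <- conv_b(P[[sprintf("b%d.l%d.conv", b, l)]], lc$conv, dy)
      G[[sprintf("b%d.l%d.conv", b, l)]] <- r$grads
      r2 <- bn_b(P[[sprintf("b%d.l%d.bn", b, l)]], lc$bn, r$dx)
      G[[sprintf("b%d.l%d.bn", b, l)]] <- r2$grads
      dx <- dx + r2$dx
    }
  }
  r <- conv_b(P$init, caches$init, dx)
  G$init <- r$grads
  G
}

model_backward <- function(model, caches, dlogits) {
  if (model$arch == "lenet") lenet_backward(model, caches, dlogits)
  else densenet_backward(model, caches, dlogits)
}

#' Class probabilities for a batch of patches
#'
#' Runs the network in inference mode (batch-norm running moments, no
#' dropout) and returns softmax probabilities in class order
#' base, body, stem, tip. Patches must carry the same normalisation as the
#' training patches.
#'
#' @param model a trained model from [train_classifier()] or [build_model()]
#' @param patches a 32x32x3xN array (a single 32x32x3 patch is accepted)
#' @param chunk internal batching size
#' @return an N x 4 matrix of probabilities, rows summing to 1
#' @export
predict_proba <- function(model, patches, chunk = 64L) {
  if (length(dim(patches)) == 3) dim(patches) <- c(dim(patches), 1)
  n <- dim(patches)[4]
  out <- matrix(0, n, model$config$n_classes,
                dimnames = list(NULL, model$classes))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- model_forward(model, patches[, , , i:j, drop = FALSE],
                        training = FALSE)
    out[i:j, ] <- softmax_rows(fw$logits)
    i <- j + 1L
  }
  out
}

#' Train a patch classifier
#'
#' Minibatch SGD with momentum, weight decay and the step-down learning-rate
#' schedule of [lr_schedule()]; the loss is softmax cross-entropy. After each
#' epoch the model is evaluated on the validation split (accuracy = fraction
#' of correct argmax, loss = mean cross-entropy) and the weights with the best
#' validation accuracy are retained. Fully deterministic for a fixed
#' `cfg$seed`.
#'
#' @param model a model from [build_model()]
#' @param train,val lists with `x` (32x32x3xN array of normalised patches) and
#'   `y` (0-based class codes)
#' @param cfg a [train_config()]
#' @param verbose print per-epoch progress
#' @return list with `model` (best weights), `history` (per-epoch data frame
#'   with train loss, validation loss and accuracy), `best_epoch`
#' @export
train_classifier <- function(model, train, val, cfg, verbose = FALSE) {
  n <- length(train$y)
  if (n == 0 || length(val$y) == 0) stop("empty training or validation split")
  stopifnot(dim(train$x)[4] == n)
  withr::with_seed(cfg$seed, {
    velocity <- list()
    best_acc <- -Inf
    best_params <- model$params
    best_epoch <- NA_integer_
    hist <- vector("list", cfg$epochs)
    for (epoch in 0:(cfg$epochs - 1)) {
      lr <- lr_schedule(epoch, cfg)
      ord <- sample.int(n)
      losses <- numeric(0)
      i <- 1L
      while (i <= n) {
        take <- ord[i:min(i + cfg$batch_size - 1L, n)]
        fw <- model_forward(model, train$x[, , , take, drop = FALSE],
                            training = TRUE)
        model <- fw$model
        ls <- softmax_xent(fw$logits, train$y[take])
        if (!is.finite(ls$loss))
          stop(sprintf("non-finite loss at epoch %d (lr=%g); training aborted",
                       epoch, lr))
        grads <- model_backward(model, fw$caches, ls$dlogits)
        st <- sgd_step(model$params, grads, velocity, lr, cfg$momentum,
                       cfg$weight_decay)
        model$params <- st$params
        velocity <- st$velocity
        losses <- c(losses, ls$loss)
        i <- i + cfg$batch_size
      }
      ev <- evaluate_classifier(model, val)
      hist[[epoch + 1]] <- data.frame(epoch = epoch, lr = lr,
                                      train_loss = mean(losses),
                                      val_loss = ev$loss,
                                      val_accuracy = ev$accuracy)
      if (ev$accuracy >= best_acc) {
        best_acc <- ev$accuracy
        best_params <- model$params
        best_epoch <- epoch
      }
      if (verbose)
        message(sprintf("epoch %2d lr %.5f train loss %.4f val loss %.4f val acc %.4f",
                        epoch, lr, mean(losses), ev$loss, ev$accuracy))
    }
    model$params <- best_params
    list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch)
  })
}

#' Accuracy and mean cross-entropy on a labelled patch set
#'
#' @param model a model
#' @param data list with `x` (32x32x3xN array) and `y` (0-based codes)
#' @param chunk internal batching size
#' @return list with `accuracy`, `loss`, `predicted` (0-based codes)
#' @export
evaluate_classifier <- function(model, data, chunk = 64L) {
  probs <- predict_proba(model, data$x, chunk = chunk)
  pred <- max.col(probs, ties.method = "first") - 1L
  picked <- probs[cbind(seq_along(data$y), data$y + 1L)]
  list(accuracy = mean(pred == data$y),
       loss = -mean(log(pmax(picked, 1e-12))),
       predicted = pred)
}

#' Save / load a model
#'
#' The serialized file embeds the architecture configuration, all parameters
#' (including batch-norm running moments) and, when attached, the
#' normalisation statistics the model was trained with.
#'
#' @param model a model object
#' @param path file path
#' @return `load_model` returns the model object
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  class(obj$config) <- paste0(obj$arch, "_config")
  structure(obj, class = "pod_model")
}
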