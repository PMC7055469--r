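#' @useDynLib podquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median cor setNames
#' @importFrom utils read.csv write.csv read.delim
#' @importFrom graphics abline plot
NULL

# ---------------------------------------------------------------------------
# Layer primitives.
#
# Batches are numeric arrays with dim c(H, W, C, N); fully connected
# activations are N x d matrices. Each parameterised layer keeps its tensors
# in a plain list; forward functions return list(y, cache), backward functions
# return list(dx, grads). Batch-norm additionally carries running moments for
# inference. Convolution and pooling call the compiled kernels.
# ---------------------------------------------------------------------------

nn_init_conv <- function(in_ch, out_ch, k) {
  list(W = matrix(rnorm(k * k * in_ch * out_ch, sd = sqrt(2 / (k * k * in_ch))),
                  nrow = k * k * in_ch, ncol = out_ch),
       b = numeric(out_ch), k = k)
}

nn_init_fc <- function(d_in, d_out) {
  list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

nn_init_bn <- function(ch) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch))
}

conv_f <- function(x, p, pad, keep_im2col = FALSE) {
  r <- cpp_conv2d_forward(x, dim(x), p$W, p$b, p$k, p$k, pad, keep_im2col)
  list(y = r$y, cache = list(x = x, pad = pad, kt = r$kt))
}

conv_b <- function(p, cache, dy) {
  g <- cpp_conv2d_backward(cache$x, dim(cache$x), p$W, dy, p$k, p$k, cache$pad,
                           cache$kt)
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}

maxpool_f <- function(x) {
  r <- cpp_maxpool2_forward(x, dim(x))
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

maxpool_b <- function(cache, dy) cpp_maxpool2_backward(dy, cache$idx, cache$xdim)

avgpool_f <- function(x) list(y = cpp_avgpool2_forward(x, dim(x)), cache = dim(x))

avgpool_b <- function(cache, dy) cpp_avgpool2_backward(dy, cache)

relu_f <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}

relu_b <- function(cache, dy) dy * cache

# Channel-wise batch normalisation over (H, W, N); compiled kernels carry the
# heavy passes, R keeps the running moments. eps follows the usual 1e-5.
bn_f <- function(x, p, training, momentum = 0.9, eps = 1e-5, relu = FALSE,
                 need_cache = training) {
  r <- cpp_bn_forward(x, dim(x), p$gamma, p$beta, p$run_mean, p$run_var,
                      training, momentum, eps, relu, need_cache)
  p$run_mean <- r$run_mean
  p$run_var <- r$run_var
  list(y = r$y,
       cache = if (need_cache)
         list(xhat = r$xhat, istd = r$istd, d = dim(x), training = training,
              relu_y = if (relu) r$y else NULL),
       p = p)
}

bn_b <- function(p, cache, dy) {
  r <- cpp_bn_backward(cache$xhat, cache$d, dy, p$gamma, cache$istd,
                       cache$training, cache$relu_y)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# Inverted dropout; identity when not training.
dropout_f <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  r <- cpp_dropout_forward(x, rate)
  list(y = r$y, cache = r$mask)
}

dropout_b <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# Global average pooling: (H,W,C,N) -> N x C
gap_f <- function(x) {
  d <- dim(x)
  # reshape to (H*W) x (C*N), column means, then C x N -> N x C
  m <- matrix(x, nrow = d[1] * d[2])
  y <- t(matrix(colMeans(m), d[3], d[4]))
  list(y = y, cache = d)
}

gap_b <- function(cache, dy) {
  d <- cache
  g <- t(dy) / (d[1] * d[2])                      # C x N
  array(rep(as.numeric(g), each = d[1] * d[2]), d)
}

# Flatten (H,W,C,N) -> N x (H*W*C)
flatten_f <- function(x) {
  d <- dim(x)
  list(y = t(matrix(x, nrow = prod(d[1:3]))), cache = d)
}

flatten_b <- function(cache, dy) array(t(dy), cache)

fc_f <- function(x, p) list(y = sweep(x %*% p$W, 2, p$b, "+"), cache = x)

fc_b <- function(p, cache, dy) {
  list(dx = dy %*% t(p$W),
       grads = list(W = t(cache) %*% dy, b = colSums(dy)))
}

# Softmax cross-entropy on logits (N x K); labels are 0-based class codes.
softmax_xent <- function(logits, labels) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  n <- nrow(logits)
  picked <- probs[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), labels + 1L)] <-
    dlogits[cbind(seq_len(n), labels + 1L)] - 1
  dlogits <- dlogits / n
  list(loss = loss, probs = probs, dlogits = dlogits)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# SGD with momentum and decoupled-from-nothing classic L2 weight decay on
# weight matrices (biases and batch-norm affine terms are not decayed).
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      if (nm == "W") g <- g + weight_decay * params[[id]][[nm]]
      key <- paste(id, nm, sep = ".")
      v <- if (is.null(velocity[[key]])) 0 else velocity[[key]]
      v <- momentum * v - lr * g
      velocity[[key]] <- v
      params[[id]][[nm]] <- params[[id]][[nm]] + v
    }
  }
  list(params = params, velocity = velocity)
}
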