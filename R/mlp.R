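## Multilayer-perceptron core with hand-written reverse-mode derivatives.
##
## Every operation used here (matrix product, bias add, per-sample
## normalization, Swish-1, the exponential branch of SELU) is analytic, and
## the code is written to be polymorphic over real and complex inputs: the
## per-sample variance is computed as mean((z - m)^2) without conjugation, so
## the whole forward + backward pass is an analytic continuation. Running the
## backward pass at inputs X + i * eps * V and taking Im(grad) / eps therefore
## yields machine-precision derivatives of the input-gradient contraction
## with respect to the parameters (complex-step differentiation), which is
## what training on forces requires.

#' Swish-1 activation
#'
#' \eqn{x \cdot \sigma(x)} with \eqn{\sigma} the logistic function; smooth
#' (infinitely differentiable), which keeps predicted forces continuous and
#' higher derivatives of the energy well defined.
#'
#' @param x Numeric (or complex) vector.
#' @return Activated values.
#' @examples
#' swish1(0)      # 0
#' swish1(1)      # 0.731059
#' @export
swish1 <- function(x) x / (1 + exp(-x))

swish1_prime <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' Scaled exponential linear unit (SELU)
#'
#' \eqn{\lambda x} for \eqn{x > 0} and \eqn{\lambda \alpha (e^x - 1)}
#' otherwise, with the self-normalizing constants \eqn{\alpha = 1.6732},
#' \eqn{\lambda = 1.0507}. Continuous but not continuously differentiable at
#' the origin: models built on it can show small jump discontinuities in the
#' forces, which is the documented trade-off of this variant.
#'
#' @param x Numeric (or complex) vector; complex values select the branch by
#'   their real part.
#' @param alpha,lambda The SELU constants.
#' @return Activated values.
#' @export
selu <- function(x, alpha = 1.6732, lambda = 1.0507) {
  pos <- Re(x) > 0
  out <- x
  out[pos] <- lambda * x[pos]
  out[!pos] <- lambda * alpha * (exp(x[!pos]) - 1)
  out
}

selu_prime <- function(x, alpha = 1.6732, lambda = 1.0507) {
  pos <- Re(x) > 0
  out <- x
  out[pos] <- lambda
  out[!pos] <- lambda * alpha * exp(x[!pos])
  out
}

.activation <- function(name) {
  switch(name,
         swish1 = list(f = swish1, fp = swish1_prime),
         selu = list(f = selu, fp = selu_prime),
         stop("unknown activation: ", name))
}

## Per-sample (row-wise) normalization without trainable statistics:
## y = (z - mean(z)) / sqrt(mean((z - mean(z))^2) + eps).
.layernorm_eps <- 1e-6

layernorm_rows <- function(Z) {
  m <- rowMeans(Z)
  Zc <- Z - m
  s <- sqrt(rowMeans(Zc^2) + .layernorm_eps)
  list(Y = Zc / s, Zc = Zc, s = s)
}

## Forward pass through hidden layers + final linear layer.
## layers: list of list(W = out x in, b = out); the last entry is the linear
## output layer (width 1, no activation, no normalization).
mlp_forward <- function(layers, X, activation = "swish1", layernorm = TRUE) {
  act <- .activation(activation)
  n_hidden <- length(layers) - 1L
  tape <- vector("list", n_hidden)
  H <- X
  nr <- nrow(X)
  for (k in seq_len(n_hidden)) {
    L <- layers[[k]]
    Z <- H %*% t(L$W)
    Z <- Z + rep(L$b, each = nr)
    if (layernorm) {
      ln <- layernorm_rows(Z)
      Y <- ln$Y
    } else {
      ln <- NULL
      Y <- Z
    }
    tape[[k]] <- list(H_prev = H, Y = Y, ln = ln)
    H <- act$f(Y)
    tape[[k]]$H <- H
  }
  L <- layers[[n_hidden + 1L]]
  out <- H %*% t(L$W)
  out <- out + rep(L$b, each = nr)
  list(out = drop(out), tape = tape, H_last = H)
}

## Reverse pass. d_out: sensitivity of the scalar objective to each row's
## output (length nrow(X)). Returns the gradient with respect to the inputs
## and to every weight/bias, in the same real-or-complex field as the tape.
mlp_backward <- function(layers, tape, H_last, d_out,
                         activation = "swish1", layernorm = TRUE) {
  act <- .activation(activation)
  n_hidden <- length(layers) - 1L
  dW <- vector("list", n_hidden + 1L)
  db <- vector("list", n_hidden + 1L)
  L <- layers[[n_hidden + 1L]]
  dZ <- matrix(d_out, ncol = 1L)
  dW[[n_hidden + 1L]] <- crossprod(dZ, H_last)
  db[[n_hidden + 1L]] <- colSums(dZ)
  dH <- dZ %*% L$W
  for (k in rev(seq_len(n_hidden))) {
    tp <- tape[[k]]
    dY <- dH * act$fp(tp$Y)
    if (layernorm) {
      ln <- tp$ln
      n <- ncol(dY)
      t1 <- dY / ln$s
      S <- rowSums(dY * ln$Zc)
      dZc <- t1 - (S / (n * ln$s^3)) * ln$Zc
      dZ <- dZc - rowMeans(dZc)
    } else {
      dZ <- dY
    }
    dW[[k]] <- crossprod(dZ, tp$H_prev)
    db[[k]] <- colSums(dZ)
    dH <- dZ %*% layers[[k]]$W
  }
  list(dX = dH, dW = dW, db = db)
}

## Convenience wrapper: value, input gradient and parameter gradients of
## sum(d_out * out) for a batch of input rows.
mlp_value_and_grad <- function(layers, X, d_out = NULL,
                               activation = "swish1", layernorm = TRUE) {
  fw <- mlp_forward(layers, X, activation, layernorm)
  if (is.null(d_out)) d_out <- rep(1, nrow(X))
  bw <- mlp_backward(layers, fw$tape, fw$H_last, d_out, activation, layernorm)
  list(out = fw$out, dX = bw$dX, dW = bw$dW, db = bw$db)
}

## Run a seeded computation without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Random layer stack: weights ~ N(0, 1 / sqrt(fan_in)), biases zero.
init_layers <- function(d_in, widths, d_out = 1L) {
  dims <- c(d_in, widths, d_out)
  lapply(seq_len(length(dims) - 1L), function(k) {
    fan_in <- dims[k]
    list(W = matrix(stats::rnorm(dims[k + 1L] * fan_in, sd = 1 / sqrt(fan_in)),
                    dims[k + 1L], fan_in),
         b = rep(0, dims[k + 1L]))
  })
}
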