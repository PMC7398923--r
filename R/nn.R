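# Minimal CPU neural-network layers with explicit forward/backward passes.
# Activations are cubes (H, W, C); convolution weights are (k*k*Cin) x Cout
# matrices (R flattening of dim c(k, k, Cin, Cout)); dense weights are
# (in x out) matrices.  Backward passes are hand-chained by the callers.

he_uniform <- function(fan_in, n) {
  lim <- sqrt(6 / fan_in)
  runif(n, -lim, lim)
}

conv_param <- function(cin, cout, k = 3, stride = 1L) {
  pad <- (k - 1) %/% 2
  list(w = matrix(he_uniform(k * k * cin, k * k * cin * cout), k * k * cin, cout),
       b = numeric(cout), k = k, stride = stride, pad = pad)
}

dense_param <- function(nin, nout) {
  list(w = matrix(he_uniform(nin, nin * nout), nin, nout), b = numeric(nout))
}

conv_fwd <- function(p, x) .nn_conv2d_fwd(x, p$w, p$b, p$k, p$stride, p$pad)

conv_bwd <- function(p, x, dy) .nn_conv2d_bwd(x, p$w, dy, p$k, p$stride, p$pad)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

dense_fwd <- function(p, x) as.numeric(crossprod(p$w, x) + p$b)

dense_bwd <- function(p, x, dy) {
  list(dx = as.numeric(p$w %*% dy), dw = outer(x, dy), db = dy)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

zeros_like_params <- function(params) {
  rapply(params, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

# Flatten/accumulate gradient structures that mirror the parameter tree.
acc_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  if (is.numeric(g1)) return(g1 + g2)
  out <- g1
  for (nm in names(g2)) out[[nm]] <- acc_grads(g1[[nm]], g2[[nm]])
  out
}

# SGD with momentum and (decoupled-from-bias) weight decay; returns the
# updated (params, velocity) pair.  Gradients are clipped at a global norm.
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay,
                     clip_norm = 10) {
  flat <- function(g) {
    if (is.numeric(g)) return(sum(g^2))
    sum(vapply(g, flat, 0))
  }
  gn <- sqrt(flat(grads))
  scale <- if (is.finite(gn) && gn > clip_norm) clip_norm / gn else 1
  step <- function(p, g, v, is_bias = FALSE) {
    if (is.numeric(p)) {
      wd <- if (is_bias) 0 else weight_decay
      v <- momentum * v - lr * (g * scale + wd * p)
      return(list(p = p + v, v = v))
    }
    for (nm in names(p)) {
      if (!is.numeric(p[[nm]]) || nm %in% c("w", "b")) {
        r <- step(p[[nm]], g[[nm]], v[[nm]], is_bias = identical(nm, "b"))
        p[[nm]] <- r$p
        v[[nm]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  step(params, grads, velocity)
}

grad_global_norm <- function(grads) {
  flat <- function(g) {
    if (is.numeric(g)) return(sum(g^2))
    sum(vapply(g, flat, 0))
  }
  sqrt(flat(grads))
}
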