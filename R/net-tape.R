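# Minimal reverse-mode automatic differentiation tape.
#
# Feature maps are numeric arrays of dim (H, W, C). Each op records its
# inputs and a backward closure on the tape; tape_backward() walks the tape
# in reverse creation order accumulating gradients. This is deliberately
# small: just the ops the attention-augmented nested U-net needs (same-pad
# convolution with dilation, ReLU/sigmoid, 2x2 max pooling, bilinear
# resize, channel concat, matrix products, row softmax, binary
# cross-entropy). Everything is internal to the package.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

node_new <- function(tape, value, parents = list(), param_name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$param_name <- param_name
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

t_const <- function(tape, value) node_new(tape, value)

t_param <- function(tape, value, name) node_new(tape, value, param_name = name)

accumulate_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

tape_backward <- function(tape, loss_node, seed = 1) {
  loss_node$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    for (p in nd$parents) {
      accumulate_grad(p$node, p$bw(nd$grad))
    }
  }
  invisible(NULL)
}

# Named list of gradients for all parameter nodes on the tape.
tape_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param_name)) {
      g <- nd$grad
      if (is.null(g)) g <- array(0, dim(nd$value))
      if (is.null(out[[nd$param_name]])) out[[nd$param_name]] <- g
      else out[[nd$param_name]] <- out[[nd$param_name]] + g
    }
  }
  out
}

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Same-padding stride-1 convolution via im2col; odd kernel sizes only.
conv2d_raw <- function(x, wt, b, dilation = 1L) {
  kh <- dim(wt)[1]; kw <- dim(wt)[2]; ci <- dim(wt)[3]; co <- dim(wt)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  ph <- dilation * (kh - 1L) %/% 2L
  pw <- dilation * (kw - 1L) %/% 2L
  xp <- array(0, c(h + 2 * ph, w + 2 * pw, ci))
  xp[ph + seq_len(h), pw + seq_len(w), ] <- x
  cols <- array(0, c(h * w, kh, kw, ci))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    cols[, i, j, ] <- xp[(i - 1L) * dilation + seq_len(h),
                         (j - 1L) * dilation + seq_len(w), ]
  }
  dim(cols) <- c(h * w, kh * kw * ci)
  wm <- matrix(wt, kh * kw * ci, co)
  y <- cols %*% wm + rep(b, each = h * w)
  dim(y) <- c(h, w, co)
  list(y = y, cols = cols, wm = wm)
}

t_conv2d <- function(tape, x, w_node, b_node, dilation = 1L) {
  fw <- conv2d_raw(x$value, w_node$value, b_node$value, dilation)
  kh <- dim(w_node$value)[1]; kw <- dim(w_node$value)[2]
  ci <- dim(w_node$value)[3]; co <- dim(w_node$value)[4]
  h <- dim(x$value)[1]; w <- dim(x$value)[2]
  ph <- dilation * (kh - 1L) %/% 2L
  pw <- dilation * (kw - 1L) %/% 2L
  node_new(tape, fw$y, parents = list(
    list(node = x, bw = function(g) {
      gm <- matrix(g, h * w, co)
      dcols <- gm %*% t(fw$wm)
      dim(dcols) <- c(h * w, kh, kw, ci)
      dxp <- array(0, c(h + 2 * ph, w + 2 * pw, ci))
      for (i in seq_len(kh)) for (j in seq_len(kw)) {
        ri <- (i - 1L) * dilation + seq_len(h)
        cj <- (j - 1L) * dilation + seq_len(w)
        dxp[ri, cj, ] <- dxp[ri, cj, , drop = FALSE] +
          array(dcols[, i, j, ], c(h, w, ci))
      }
      dxp[ph + seq_len(h), pw + seq_len(w), , drop = FALSE]
    }),
    list(node = w_node, bw = function(g) {
      gm <- matrix(g, h * w, co)
      dw <- crossprod(fw$cols, gm)
      array(dw, c(kh, kw, ci, co))
    }),
    list(node = b_node, bw = function(g) {
      colSums(matrix(g, h * w, co))
    })
  ))
}

t_relu <- function(tape, x) {
  mask <- x$value > 0
  node_new(tape, x$value * mask, parents = list(
    list(node = x, bw = function(g) g * mask)
  ))
}

t_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  node_new(tape, y, parents = list(
    list(node = x, bw = function(g) g * y * (1 - y))
  ))
}

t_add <- function(tape, a, b) {
  node_new(tape, a$value + b$value, parents = list(
    list(node = a, bw = function(g) g),
    list(node = b, bw = function(g) g)
  ))
}

t_maxpool2 <- function(tape, x) {
  h <- dim(x$value)[1]; w <- dim(x$value)[2]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  ro <- seq(1L, h, 2L); co_ <- seq(1L, w, 2L)
  a <- x$value[ro, co_, , drop = FALSE]
  b <- x$value[ro + 1L, co_, , drop = FALSE]
  cc <- x$value[ro, co_ + 1L, , drop = FALSE]
  d <- x$value[ro + 1L, co_ + 1L, , drop = FALSE]
  y <- pmax(a, b, cc, d)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  node_new(tape, y, parents = list(
    list(node = x, bw = function(g) {
      dx <- array(0, dim(x$value))
      dx[ro, co_, ] <- g * m1
      dx[ro + 1L, co_, ] <- dx[ro + 1L, co_, ] + g * m2
      dx[ro, co_ + 1L, ] <- dx[ro, co_ + 1L, ] + g * m3
      dx[ro + 1L, co_ + 1L, ] <- dx[ro + 1L, co_ + 1L, ] + g * m4
      dx
    })
  ))
}

t_resize <- function(tape, x, h2, w2) {
  h <- dim(x$value)[1]; w <- dim(x$value)[2]; ch <- dim(x$value)[3]
  if (h == h2 && w == w2) return(x)
  rm_ <- resize_weights(h2, h)
  cm_ <- resize_weights(w2, w)
  y <- array(0, c(h2, w2, ch))
  for (k in seq_len(ch)) y[, , k] <- rm_ %*% x$value[, , k] %*% t(cm_)
  node_new(tape, y, parents = list(
    list(node = x, bw = function(g) {
      dx <- array(0, c(h, w, ch))
      for (k in seq_len(ch)) dx[, , k] <- t(rm_) %*% g[, , k] %*% cm_
      dx
    })
  ))
}

t_concat <- function(tape, a, b) {
  ca <- dim(a$value)[3]; cb <- dim(b$value)[3]
  y <- array(0, c(dim(a$value)[1], dim(a$value)[2], ca + cb))
  y[, , seq_len(ca)] <- a$value
  y[, , ca + seq_len(cb)] <- b$value
  node_new(tape, y, parents = list(
    list(node = a, bw = function(g) g[, , seq_len(ca), drop = FALSE]),
    list(node = b, bw = function(g) g[, , ca + seq_len(cb), drop = FALSE])
  ))
}

t_reshape <- function(tape, x, dims) {
  old <- dim(x$value)
  y <- x$value
  dim(y) <- dims
  node_new(tape, y, parents = list(
    list(node = x, bw = function(g) { dim(g) <- old; g })
  ))
}

t_matmul <- function(tape, a, b) {
  node_new(tape, a$value %*% b$value, parents = list(
    list(node = a, bw = function(g) g %*% t(b$value)),
    list(node = b, bw = function(g) t(a$value) %*% g)
  ))
}

t_transpose <- function(tape, x) {
  node_new(tape, t(x$value), parents = list(
    list(node = x, bw = function(g) t(g))
  ))
}

t_softmax_rows <- function(tape, x) {
  z <- x$value - apply(x$value, 1, max)
  e <- exp(z)
  y <- e / rowSums(e)
  node_new(tape, y, parents = list(
    list(node = x, bw = function(g) y * (g - rowSums(g * y)))
  ))
}

# Mean pixelwise binary cross-entropy against a fixed target in [0, 1].
t_bce_mean <- function(tape, pred, target, eps = 1e-7) {
  p <- pred$value
  n <- length(p)
  val <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  node_new(tape, val, parents = list(
    list(node = pred, bw = function(g) {
      g * (-target / (p + eps) + (1 - target) / (1 - p + eps)) / n
    })
  ))
}

# Weighted sum of scalar nodes.
t_weighted_sum <- function(tape, nodes, weights) {
  val <- 0
  parents <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    val <- val + weights[i] * nodes[[i]]$value
    local({
      ii <- i
      parents[[ii]] <<- list(node = nodes[[ii]], bw = function(g) g * weights[ii])
    })
  }
  node_new(tape, val, parents = parents)
}
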