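# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records every intermediate value produced during a forward pass;
# ad_backward() walks the tape in reverse, calling each node's backward
# closure to accumulate gradients into its parents. Values are always
# numeric matrices (scalars are 1x1). Gradients are only accumulated into
# nodes whose `needs` flag is set (parameters, or anything downstream of
# one), so constants cost nothing at backward time.
#
# This engine is internal: the model code builds tapes, user-facing
# functions extract plain values.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_register <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ad_new <- function(tape, value, needs, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$needs <- needs
  nd$backward <- backward
  ad_register(tape, nd)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' @noRd
ad_const <- function(tape, value) ad_new(tape, as_mat(value), needs = FALSE)

#' @noRd
ad_param <- function(tape, value) ad_new(tape, as_mat(value), needs = TRUE)

ad_accum <- function(node, g) {
  if (!node$needs) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#' @noRd
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- primitive operations ----

ad_mm <- function(tape, a, b) {
  v <- a$value %*% b$value
  ad_new(tape, v, a$needs || b$needs, function(g) {
    if (a$needs) ad_accum(a, tcrossprod(g, b$value))
    if (b$needs) ad_accum(b, crossprod(a$value, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_new(tape, a$value + b$value, a$needs || b$needs, function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_new(tape, a$value - b$value, a$needs || b$needs, function(g) {
    ad_accum(a, g); ad_accum(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_new(tape, a$value * b$value, a$needs || b$needs, function(g) {
    if (a$needs) ad_accum(a, g * b$value)
    if (b$needs) ad_accum(b, g * a$value)
  })
}

# multiply by a plain scalar constant
ad_scale <- function(tape, a, k) {
  ad_new(tape, a$value * k, a$needs, function(g) ad_accum(a, g * k))
}

# elementwise multiply matrix a [n x d] by column-vector node v [n x 1]
ad_mul_colvec <- function(tape, a, v) {
  vv <- as.vector(v$value)
  ad_new(tape, a$value * vv, a$needs || v$needs, function(g) {
    if (a$needs) ad_accum(a, g * vv)
    if (v$needs) ad_accum(v, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

# multiply matrix node a by a 1x1 scalar node s
ad_mul_scalar <- function(tape, a, s) {
  sv <- s$value[1L]
  ad_new(tape, a$value * sv, a$needs || s$needs, function(g) {
    if (a$needs) ad_accum(a, g * sv)
    if (s$needs) ad_accum(s, matrix(sum(g * a$value), 1L, 1L))
  })
}

# add a 1 x d bias row to every row of a
ad_add_bias <- function(tape, a, bias) {
  bv <- as.vector(bias$value)
  ad_new(tape, sweep(a$value, 2L, bv, "+"), a$needs || bias$needs, function(g) {
    if (a$needs) ad_accum(a, g)
    if (bias$needs) ad_accum(bias, matrix(colSums(g), 1L))
  })
}

ad_relu <- function(tape, a) {
  v <- a$value
  v[v < 0] <- 0
  ad_new(tape, v, a$needs, function(g) ad_accum(a, g * (a$value > 0)))
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  x <- a$value
  v <- ifelse(x > 0, x, slope * x)
  ad_new(tape, v, a$needs, function(g) {
    ad_accum(a, g * ifelse(x > 0, 1, slope))
  })
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_new(tape, s, a$needs, function(g) ad_accum(a, g * s * (1 - s)))
}

# log with a floor so log(0) never appears; gradient is zero in the
# clamped region
ad_log <- function(tape, a, floor = 1e-12) {
  x <- a$value
  ad_new(tape, log(pmax(x, floor)), a$needs, function(g) {
    ad_accum(a, g * ifelse(x >= floor, 1 / x, 0))
  })
}

ad_transpose <- function(tape, a) {
  ad_new(tape, t(a$value), a$needs, function(g) ad_accum(a, t(g)))
}

# row-wise softmax; `mask` (logical matrix, TRUE = participates) restricts
# the support, e.g. to graph neighbourhoods. Rows must have at least one
# unmasked entry.
ad_row_softmax <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x[!mask] <- -Inf
  mx <- apply(x, 1L, max)
  e <- exp(x - mx)
  if (!is.null(mask)) e[!mask] <- 0
  y <- e / rowSums(e)
  ad_new(tape, y, a$needs, function(g) {
    dot <- rowSums(g * y)
    ad_accum(a, y * (g - dot))
  })
}

ad_cbind <- function(tape, a, b) {
  ka <- ncol(a$value)
  ad_new(tape, cbind(a$value, b$value), a$needs || b$needs, function(g) {
    if (a$needs) ad_accum(a, g[, seq_len(ka), drop = FALSE])
    if (b$needs) ad_accum(b, g[, -seq_len(ka), drop = FALSE])
  })
}

# gather rows at idx (idx must have no duplicates)
ad_rows <- function(tape, a, idx) {
  ad_new(tape, a$value[idx, , drop = FALSE], a$needs, function(g) {
    gg <- matrix(0, nrow(a$value), ncol(a$value))
    gg[idx, ] <- g
    ad_accum(a, gg)
  })
}

# scatter the rows of a into an n-row zero matrix at positions idx
ad_scatter_rows <- function(tape, a, idx, n) {
  v <- matrix(0, n, ncol(a$value))
  v[idx, ] <- a$value
  ad_new(tape, v, a$needs, function(g) ad_accum(a, g[idx, , drop = FALSE]))
}

# select columns j
ad_cols <- function(tape, a, j) {
  ad_new(tape, a$value[, j, drop = FALSE], a$needs, function(g) {
    gg <- matrix(0, nrow(a$value), ncol(a$value))
    gg[, j] <- g
    ad_accum(a, gg)
  })
}

ad_sum <- function(tape, a) {
  ad_new(tape, matrix(sum(a$value), 1L, 1L), a$needs, function(g) {
    ad_accum(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

# mean of squared entries (the MSE building block)
ad_mean_sq <- function(tape, a) {
  len <- length(a$value)
  ad_new(tape, matrix(mean(a$value^2), 1L, 1L), a$needs, function(g) {
    ad_accum(a, g[1L] * 2 * a$value / len)
  })
}

# elementwise power of a 1x1 scalar node (used for 1/sqrt norms)
ad_pow_scalar <- function(tape, a, p) {
  x <- a$value[1L]
  ad_new(tape, matrix(x^p, 1L, 1L), a$needs, function(g) {
    ad_accum(a, matrix(g[1L] * p * x^(p - 1), 1L, 1L))
  })
}

# scatter a per-edge column vector [E x 1] into a dense n x n matrix at
# positions (edge_index[1,], edge_index[2,]); off-edge entries are 0
ad_edge_to_dense <- function(tape, a, edge_index, n) {
  ij <- cbind(edge_index[1L, ], edge_index[2L, ])
  v <- matrix(0, n, n)
  v[ij] <- a$value
  ad_new(tape, v, a$needs, function(g) {
    ad_accum(a, matrix(g[ij], ncol = 1L))
  })
}

# inverted dropout; `mask_seed` keeps training reproducible. No-op when
# rate = 0 or training = FALSE.
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= rate) / (1 - rate)
  ad_new(tape, a$value * keep, a$needs, function(g) ad_accum(a, g * keep))
}
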