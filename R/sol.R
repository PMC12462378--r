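#' Structured-objective (SOL) configuration
#'
#' The training loss combines residue-level cross-entropy with two
#' structural terms: a boundary ("01"/"10") term and a singular-point
#' ("010"/"101") term, each the summed MSE between multi-scale 1-D
#' convolutional responses of the predicted probability signal and the
#' true label signal, taken along the chain sequence.
#'
#' @param lambda_sol weight of the structural part (default 0.2).
#' @param edge_kernels list of 3 zero-sum 1-D kernels for boundary
#'   detection; defaults from [default_kernels()].
#' @param singular_kernels list of 3 zero-sum kernels for isolated-site
#'   detection.
#' @param positive_weight optional weight on the positive class inside
#'   the cross-entropy term (1 = off).
#' @return object of class `sol_config`.
#' @export
sol_config <- function(lambda_sol = 0.2, edge_kernels = NULL,
                       singular_kernels = NULL, positive_weight = 1) {
  dk <- default_kernels()
  if (is.null(edge_kernels)) edge_kernels <- dk$edge_kernels
  if (is.null(singular_kernels)) singular_kernels <- dk$singular_kernels
  stopifnot(lambda_sol >= 0, length(edge_kernels) == 3L,
            length(singular_kernels) == 3L, positive_weight > 0)
  for (k in c(edge_kernels, singular_kernels)) {
    if (abs(sum(k)) > 1e-12) stop("every kernel must sum to 0")
  }
  structure(list(lambda_sol = lambda_sol, edge_kernels = edge_kernels,
                 singular_kernels = singular_kernels,
                 positive_weight = positive_weight),
            class = "sol_config")
}

#' Default structural-detection kernel families
#'
#' Three scales per family, each summing to zero so constant label
#' stretches give zero response. The edge family is difference-of-step
#' (first-derivative-like) at widths 2/3/5; the singular family is
#' discrete-Laplacian-like (centre-surround) at widths 3/5/7.
#'
#' @return list with `edge_kernels` and `singular_kernels`.
#' @export
default_kernels <- function() {
  list(
    edge_kernels = list(
      c(-1, 1),
      c(-1, 0, 1),
      c(-1, -1, 0, 1, 1) / 2
    ),
    singular_kernels = list(
      c(-1, 2, -1),
      c(-1, -1, 4, -1, -1) / 2,
      c(-1, -1, -1, 6, -1, -1, -1) / 3
    )
  )
}

# band matrix C such that C %*% signal == pattern_conv(signal, kernel);
# "same" zero padding, kernel centre at ceiling(k/2) (even kernels
# anchored left-of-centre).
conv_matrix <- function(kernel, n) {
  k <- length(kernel)
  centre <- ceiling(k / 2)
  C <- matrix(0, n, n)
  for (tap in seq_len(k)) {
    off <- tap - centre
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1L && j <= n) C[i, j] <- C[i, j] + kernel[tap]
    }
  }
  C
}

#' 1-D pattern convolution with "same" zero padding
#'
#' Cross-correlation of a per-residue signal with a short kernel; output
#' length equals input length, positions beyond the chain are zero.
#' Even-length kernels are anchored left-of-centre.
#'
#' @param signal numeric vector.
#' @param kernel numeric vector (any length; kernels longer than the
#'   signal just see more padding).
#' @return numeric vector, same length as `signal`.
#' @export
pattern_conv <- function(signal, kernel) {
  n <- length(signal)
  stopifnot(n >= 1L)
  as.vector(conv_matrix(kernel, n) %*% signal)
}

#' Residue-level cross-entropy
#'
#' `L = -(1/n) sum_i sum_c t_ic log(y_ic)` with one-hot true labels and
#' the log floored at 1e-12.
#'
#' @param probs `[n x 2]` row-stochastic class probabilities.
#' @param labels binary vector of length n.
#' @param positive_weight optional positive-class weight.
#' @return scalar loss.
#' @export
correctness_loss <- function(probs, labels, positive_weight = 1) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(labels)) stop("length mismatch")
  tp <- ad_tape()
  tape_correctness(tp, ad_const(tp, probs), as.integer(labels),
                   positive_weight)$value[1L]
}

tape_correctness <- function(tape, probs, labels, positive_weight = 1) {
  n <- length(labels)
  onehot <- cbind(1 - labels, labels, deparse.level = 0)
  w <- ifelse(labels == 1L, positive_weight, 1)
  picked <- ad_mul(tape, ad_log(tape, probs), ad_const(tape, onehot * w))
  ad_scale(tape, ad_sum(tape, picked), -1 / n)
}

tape_structural <- function(tape, p_node, labels, kernels) {
  n <- length(labels)
  total <- NULL
  for (k in kernels) {
    C <- conv_matrix(k, n)
    resp_p <- ad_mm(tape, ad_const(tape, C), p_node)
    resp_t <- C %*% labels
    term <- ad_mean_sq(tape, ad_sub(tape, resp_p, ad_const(tape, resp_t)))
    total <- if (is.null(total)) term else ad_add(tape, total, term)
  }
  total
}

#' Boundary-structure loss
#'
#' `sum_{i=1..3} MSE(conv(K_edge_i, p), conv(K_edge_i, T))` where p is
#' the predicted positive-class probability and T the true 0/1 labels,
#' both in sequence order; MSE is the mean over the n positions.
#'
#' @param p numeric vector of positive-class probabilities.
#' @param labels binary vector.
#' @param config a [sol_config()].
#' @return scalar loss.
#' @export
edge_loss <- function(p, labels, config = sol_config()) {
  stopifnot(length(p) == length(labels))
  tp <- ad_tape()
  tape_structural(tp, ad_const(tp, matrix(p, ncol = 1L)), as.numeric(labels),
                  config$edge_kernels)$value[1L]
}

#' Singular-structure loss
#'
#' Same structure as [edge_loss()] with the singular (centre-surround)
#' kernel family, penalising mismatch on isolated-site patterns.
#'
#' @inheritParams edge_loss
#' @return scalar loss.
#' @export
singular_loss <- function(p, labels, config = sol_config()) {
  stopifnot(length(p) == length(labels))
  tp <- ad_tape()
  tape_structural(tp, ad_const(tp, matrix(p, ncol = 1L)), as.numeric(labels),
                  config$singular_kernels)$value[1L]
}

tape_total_loss <- function(tape, probs_node, labels, config) {
  p_node <- ad_cols(tape, probs_node, 2L)
  l_corr <- tape_correctness(tape, probs_node, labels, config$positive_weight)
  l_edge <- tape_structural(tape, p_node, as.numeric(labels),
                            config$edge_kernels)
  l_sing <- tape_structural(tape, p_node, as.numeric(labels),
                            config$singular_kernels)
  structural <- ad_scale(tape, ad_add(tape, l_edge, l_sing), 0.5)
  total <- ad_add(tape, l_corr, ad_scale(tape, structural, config$lambda_sol))
  list(total = total, correctness = l_corr, edge = l_edge, singular = l_sing)
}

#' Combined structured objective
#'
#' `L_total = L_correctness + lambda_sol * (0.5 L_edge + 0.5 L_singular)`.
#' With `lambda_sol = 0` this reduces exactly to cross-entropy-only
#' training (the no-SOL ablation).
#'
#' @param probs `[n x 2]` class probabilities.
#' @param labels binary vector.
#' @param config a [sol_config()].
#' @return named list: `total`, `correctness`, `edge`, `singular`.
#' @export
total_loss <- function(probs, labels, config = sol_config()) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(labels)) stop("length mismatch")
  tp <- ad_tape()
  out <- tape_total_loss(tp, ad_const(tp, probs), as.integer(labels), config)
  lapply(out, function(nd) nd$value[1L])
}
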