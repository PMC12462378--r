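# the structured objective: cross-entropy + multi-scale boundary and
# singular-pattern convolution losses

# independent sliding-window cross-correlation (zero padded, centre at
# ceiling(k/2)) used as oracle throughout
slide_conv <- function(signal, kernel) {
  n <- length(signal); k <- length(kernel)
  centre <- ceiling(k / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tp in seq_len(k)) {
      j <- i + tp - centre
      if (j >= 1 && j <= n) out[i] <- out[i] + kernel[tp] * signal[j]
    }
  }
  out
}

test_that("cross-entropy term matches a per-residue summation oracle", {
  # perfect one-hot predictions -> 0
  expect_equal(correctness_loss(rbind(c(1, 0), c(0, 1)), c(0, 1)), 0)
  # maximal uncertainty -> ln 2
  expect_equal(correctness_loss(matrix(0.5, 1, 2), 1), log(2))
  set.seed(101)
  for (rep in 1:20) {
    n <- 20
    p <- runif(n, 0.01, 0.99)
    probs <- cbind(1 - p, p)
    labels <- rbinom(n, 1, 0.4)
    oracle <- 0
    for (i in 1:n) {
      t_i <- c(1 - labels[i], labels[i])
      oracle <- oracle - sum(t_i * log(probs[i, ]))
    }
    expect_close(correctness_loss(probs, labels), oracle / n, 1e-12)
  }
  expect_error(correctness_loss(matrix(0.5, 3, 2), c(0, 1)), "length mismatch")
})

test_that("default kernels are zero-sum with the expected point responses", {
  dk <- default_kernels()
  expect_length(dk$edge_kernels, 3)
  expect_length(dk$singular_kernels, 3)
  for (k in c(dk$edge_kernels, dk$singular_kernels)) {
    expect_equal(sum(k), 0)
  }
  # rising boundary "01" under the width-2 edge kernel
  expect_equal(pattern_conv(c(0, 1), dk$edge_kernels[[1]])[1], 1)
  # isolated site "010" under the width-3 singular kernel
  expect_equal(pattern_conv(c(0, 1, 0), dk$singular_kernels[[1]])[2], 2)
  # constant stretch: zero response at the valid centre
  expect_equal(pattern_conv(c(1, 1, 1), dk$singular_kernels[[1]])[2], 0)
})

test_that("pattern convolution matches the sliding-window oracle", {
  dk <- default_kernels()
  # boundary signal under the difference kernel
  expect_equal(pattern_conv(c(0, 0, 1, 1, 0), c(-1, 1)),
               slide_conv(c(0, 0, 1, 1, 0), c(-1, 1)))
  # n = 1 with a centre-surround kernel: pure padding, response 2 s
  expect_equal(pattern_conv(0.7, c(-1, 2, -1)), 1.4)
  # kernel longer than the signal is pure padding, not an error
  expect_equal(pattern_conv(c(1, 0), c(-1, -1, -1, 6, -1, -1, -1) / 3),
               slide_conv(c(1, 0), c(-1, -1, -1, 6, -1, -1, -1) / 3))
  set.seed(102)
  for (rep in 1:25) {
    n <- sample(1:30, 1)
    sig <- rnorm(n)
    for (k in c(dk$edge_kernels, dk$singular_kernels)) {
      expect_close(pattern_conv(sig, k), slide_conv(sig, k), 1e-12)
    }
    # constant signals give zero interior response for zero-sum kernels
    if (n >= 7) {
      for (k in c(dk$edge_kernels, dk$singular_kernels)) {
        interior <- 4:(n - 3)
        expect_close(pattern_conv(rep(3.3, n), k)[interior],
                     rep(0, length(interior)), 1e-12)
      }
    }
  }
})

test_that("boundary and singular losses match scalar oracles", {
  cfg <- sol_config()
  mse_oracle <- function(p, T, kernels) {
    sum(vapply(kernels,
               function(k) mean((slide_conv(p, k) - slide_conv(T, k))^2), 0))
  }
  # identical signals -> 0
  expect_equal(edge_loss(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(singular_loss(c(0, 1, 0), c(0, 1, 0)), 0)
  # anti-predictions on a boundary
  expect_close(edge_loss(c(1, 0), c(0, 1)), mse_oracle(c(1, 0), c(0, 1), cfg$edge_kernels), 1e-12)
  # constant prediction vs constant truth: zero-sum kernels see no
  # structure in the interior; only the zero-padded chain ends respond,
  # so the loss equals a boundary-only oracle
  p_const <- rep(0.5, 12); T_const <- rep(0, 12)
  expect_close(edge_loss(p_const, T_const),
               mse_oracle(p_const, T_const, cfg$edge_kernels), 1e-12)
  interior_resp <- vapply(cfg$edge_kernels,
                          function(k) max(abs(slide_conv(p_const, k)[4:9])), 0)
  expect_close(interior_resp, rep(0, 3), 1e-12)
  expect_equal(singular_loss(rep(0, 5), rep(0, 5)), 0)
  # missed isolated site
  expect_close(singular_loss(c(0, 0, 0), c(0, 1, 0)),
               mse_oracle(c(0, 0, 0), c(0, 1, 0), cfg$singular_kernels), 1e-12)
  set.seed(103)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    p <- runif(n); T <- rbinom(n, 1, 0.3)
    expect_close(edge_loss(p, T), mse_oracle(p, T, cfg$edge_kernels), 1e-10)
    expect_close(singular_loss(p, T), mse_oracle(p, T, cfg$singular_kernels), 1e-10)
    expect_gte(edge_loss(p, T), 0)
    expect_gte(singular_loss(p, T), 0)
  }
})

test_that("total loss recombines its components with the 0.2 default weight", {
  set.seed(104)
  # lambda = 0 reduces exactly to cross-entropy
  n <- 15
  p <- runif(n); probs <- cbind(1 - p, p); T <- rbinom(n, 1, 0.4)
  out0 <- total_loss(probs, T, sol_config(lambda_sol = 0))
  expect_identical(out0$total, out0$correctness)
  expect_equal(out0$correctness, correctness_loss(probs, T))
  # perfect prediction -> all components 0
  perf <- total_loss(cbind(1 - T, T), T)
  expect_equal(unlist(perf), c(total = 0, correctness = 0, edge = 0, singular = 0))
  # components recombine under the stated weights
  cfg <- sol_config()
  expect_equal(cfg$lambda_sol, 0.2)
  for (rep in 1:10) {
    p <- runif(n); probs <- cbind(1 - p, p); T <- rbinom(n, 1, 0.4)
    out <- total_loss(probs, T, cfg)
    expect_close(out$total,
                 out$correctness + 0.2 * (0.5 * out$edge + 0.5 * out$singular),
                 1e-12)
    expect_close(out$correctness, correctness_loss(probs, T), 1e-12)
    expect_close(out$edge, edge_loss(p, T, cfg), 1e-12)
    expect_close(out$singular, singular_loss(p, T, cfg), 1e-12)
  }
})

test_that("structural losses are invariant to a shared constant shift", {
  set.seed(105)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    p <- runif(n); T <- as.numeric(rbinom(n, 1, 0.3)); c0 <- rnorm(1)
    expect_close(edge_loss(p + c0, T + c0), edge_loss(p, T), 1e-10)
    expect_close(singular_loss(p + c0, T + c0), singular_loss(p, T), 1e-10)
  }
})

test_that("moving predictions toward the truth strictly decreases the boundary loss", {
  T <- c(0, 0, 1, 1, 0, 0)
  steps <- seq(0, 1, by = 0.1)
  losses <- vapply(steps, function(s) edge_loss(0.5 + s * (T - 0.5), T), 0)
  expect_true(all(diff(losses) < 0))
})

test_that("the objective is differentiable with a nonzero gradient off the truth", {
  set.seed(106)
  n <- 12
  p <- runif(n, 0.05, 0.95); probs <- cbind(1 - p, p); T <- rbinom(n, 1, 0.4)
  tp <- ppi("ad_tape")()
  probs_node <- ppi("ad_param")(tp, probs)
  out <- ppi("tape_total_loss")(tp, probs_node, T, sol_config())
  ppi("ad_backward")(tp, out$total)
  expect_true(all(is.finite(probs_node$grad)))
  expect_gt(max(abs(probs_node$grad)), 0)
  # and the gradient matches finite differences
  fd <- fd_grad(function(x) {
    tp2 <- ppi("ad_tape")()
    ppi("tape_total_loss")(tp2, ppi("ad_const")(tp2, x), T, sol_config())$total$value[1]
  }, probs)
  expect_lt(max(abs(fd - probs_node$grad)), 1e-5)
})

test_that("kernel families are validated", {
  expect_error(sol_config(edge_kernels = list(c(1, 1), c(-1, 1), c(-1, 0, 1))),
               "sum to 0")
  expect_error(sol_config(edge_kernels = list(c(-1, 1))), NULL)
  expect_error(sol_config(lambda_sol = -1))
})
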