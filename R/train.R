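#' Fit the interaction-site model
#'
#' Trains the dual-view residue-graph network under the structured
#' objective by Adam, one protein per optimisation step. The best
#' parameters by validation MCC are retained (falling back to the final
#' epoch when no validation set is given). Fully reproducible given
#' `seed` (parameter initialisation is seeded separately from
#' `config$seed`).
#'
#' @param train list of labelled [residue_graph()] objects.
#' @param val optional validation list (early stopping and checkpoint
#'   selection use its MCC).
#' @param config a [ppis_config()].
#' @param sol a [sol_config()]; `use_sol = FALSE` forces its weight to
#'   zero (cross-entropy-only training).
#' @param epochs maximum epochs; 0 returns the initialised model with an
#'   empty history.
#' @param learning_rate,weight_decay Adam step size and L2 weight decay.
#' @param patience early-stopping patience on validation MCC.
#' @param use_sol enable the structural loss terms.
#' @param threshold call threshold carried into prediction.
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose print a line per epoch.
#' @return object of class `ppis_fit`: trained `params`, `config`,
#'   `sol`, `history` (`$steps` per-step loss components, `$epochs`
#'   per-epoch summaries), `best_epoch`, `d_node`.
#' @export
ppis_fit <- function(train, val = NULL, config = ppis_config(),
                     sol = sol_config(), epochs = 30L,
                     learning_rate = 1e-3, weight_decay = 1e-5,
                     patience = 10L, use_sol = TRUE, threshold = 0.5,
                     seed = 1L, verbose = FALSE) {
  stopifnot(length(train) >= 1L)
  for (g in train) {
    if (is.null(g$labels)) stop("all training graphs need labels")
  }
  if (!use_sol) sol$lambda_sol <- 0
  d_node <- ncol(train[[1L]]$node_features)
  params <- init_parameters(d_node, config)
  adam <- adam_state(params)

  step_log <- list()
  epoch_log <- list()
  best <- list(params = params, epoch = 0L, mcc = -Inf)
  wait <- 0L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  step_i <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(train))
    comp_sums <- c(total = 0, correctness = 0, edge = 0, singular = 0)
    for (gi in ord) {
      g <- train[[gi]]
      step_i <- step_i + 1L
      tp <- ad_tape()
      leaves <- lapply(params, function(p) ad_param(tp, p))
      fw <- tape_forward(tp, g, leaves, config, training = TRUE)
      losses <- tape_total_loss(tp, fw$probs, g$labels, sol)
      lv <- vapply(losses, function(nd) nd$value[1L], 0)
      if (!all(is.finite(lv))) {
        stop(sprintf("non-finite loss at epoch %d, step %d (protein %s)",
                     ep, step_i, g$name))
      }
      ad_backward(tp, losses$total)
      params <- adam_update(params, leaves, adam, learning_rate, weight_decay)
      comp_sums <- comp_sums + lv[c("total", "correctness", "edge", "singular")]
      step_log[[step_i]] <- c(epoch = ep, step = step_i, lv)
    }
    ep_row <- as.list(comp_sums / length(train))
    names(ep_row) <- paste0("train_", names(ep_row))
    ep_row$epoch <- ep
    if (!is.null(val)) {
      rep_val <- evaluate_params(params, config, val, threshold)
      ep_row$val_mcc <- rep_val$MCC
      ep_row$val_f1 <- rep_val$F1
      if (rep_val$MCC > best$mcc) {
        best <- list(params = params, epoch = ep, mcc = rep_val$MCC)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    epoch_log[[ep]] <- ep_row
    if (verbose) {
      cat(sprintf("epoch %d: train loss %.4f%s\n", ep, ep_row$train_total,
                  if (!is.null(val)) sprintf(", val MCC %.3f", ep_row$val_mcc) else ""))
    }
    if (!is.null(val) && wait >= patience) break
  }

  final_params <- if (!is.null(val) && best$epoch > 0L) best$params else params
  structure(list(
    params = final_params,
    last_params = params,
    config = config,
    sol = sol,
    d_node = d_node,
    threshold = threshold,
    best_epoch = if (!is.null(val)) best$epoch else length(epoch_log),
    history = list(
      steps = if (length(step_log)) as.data.frame(do.call(rbind, step_log))
              else data.frame(),
      epochs = if (length(epoch_log))
        do.call(rbind, lapply(epoch_log, as.data.frame)) else data.frame()
    ),
    seed = seed
  ), class = "ppis_fit")
}

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

adam_update <- function(params, leaves, st, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- leaves[[nm]]$grad
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g + wd * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

evaluate_params <- function(params, config, graphs, threshold) {
  true <- lapply(graphs, `[[`, "labels")
  probs <- lapply(graphs, function(g) {
    ppis_forward(g, params, config, threshold)$probs[, 2L]
  })
  evaluate_predictions(true, probs, threshold)
}

#' Evaluate a fitted model on labelled graphs
#'
#' Runs the forward pass in eval mode per protein, pools all residues
#' (micro aggregation) for the seven standard metrics and computes the
#' four structural-pattern accuracies with per-protein windows.
#'
#' @param fit a `ppis_fit` (or a checkpoint loaded by
#'   [load_checkpoint()]).
#' @param graphs list of labelled [residue_graph()] objects.
#' @param threshold call threshold (defaults to the fit's).
#' @return report list from [evaluate_predictions()].
#' @export
evaluate_model <- function(fit, graphs, threshold = fit$threshold) {
  stopifnot(inherits(fit, "ppis_fit"))
  evaluate_params(fit$params, fit$config, graphs, threshold)
}

#' @export
predict.ppis_fit <- function(object, newdata, type = c("prob", "class"),
                             threshold = object$threshold, ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "residue_graph")
  graphs <- if (single) list(newdata) else newdata
  out <- lapply(graphs, function(g) {
    pr <- ppis_forward(g, object$params, object$config, threshold)
    if (type == "prob") pr$probs[, 2L] else pr$calls
  })
  if (single) out[[1L]] else out
}

#' @export
print.ppis_fit <- function(x, ...) {
  cat(sprintf("ppis_fit: d_node %d, d_hidden %d, %d subgraph + %d attention layers\n",
              x$d_node, x$config$d_hidden, x$config$n_layers_sub,
              x$config$n_layers_agat))
  cat(sprintf("  trained %d epochs (best epoch %d), lambda_sol %g\n",
              nrow(x$history$epochs), x$best_epoch, x$sol$lambda_sol))
  invisible(x)
}

#' @export
summary.ppis_fit <- function(object, ...) {
  print(object)
  ep <- object$history$epochs
  if (nrow(ep)) {
    cat(sprintf("  final train loss %.4f (correctness %.4f, edge %.4f, singular %.4f)\n",
                ep$train_total[nrow(ep)], ep$train_correctness[nrow(ep)],
                ep$train_edge[nrow(ep)], ep$train_singular[nrow(ep)]))
    if (!is.null(ep$val_mcc)) {
      cat(sprintf("  best validation MCC %.3f at epoch %d\n",
                  max(ep$val_mcc), object$best_epoch))
    }
  }
  invisible(object)
}

#' @export
coef.ppis_fit <- function(object, ...) object$params

#' @export
plot.ppis_fit <- function(x, ...) {
  ep <- x$history$epochs
  if (!nrow(ep)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  has_val <- !is.null(ep$val_mcc)
  graphics::par(mfrow = c(1, if (has_val) 2 else 1))
  graphics::plot(ep$epoch, ep$train_total, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "total loss", ...)
  if (has_val) {
    graphics::plot(ep$epoch, ep$val_mcc, type = "b", xlab = "epoch",
                   ylab = "validation MCC", main = "validation MCC", ...)
  }
  invisible(x)
}

CHECKPOINT_FORMAT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Single JSON file holding all parameters, the model and loss
#' configuration and a format version; doubles at full precision so a
#' save/load round trip reproduces evaluation reports bit-for-bit.
#' Loading refuses containers whose format version does not match.
#'
#' @param fit a `ppis_fit`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `ppis_fit` (without training history).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ppis_fit"))
  obj <- list(format_version = CHECKPOINT_FORMAT_VERSION,
              d_node = fit$d_node, threshold = fit$threshold,
              best_epoch = fit$best_epoch,
              config = unclass(fit$config), sol = unclass(fit$sol),
              params = fit$params)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop(sprintf(
                    "not a readable checkpoint: %s", conditionMessage(e))))
  if (is.null(obj$format_version) ||
      obj$format_version != CHECKPOINT_FORMAT_VERSION) {
    stop(sprintf("unsupported checkpoint format version %s (this build reads %d)",
                 obj$format_version, CHECKPOINT_FORMAT_VERSION))
  }
  cfg <- obj$config
  config <- ppis_config(
    d_hidden = cfg$d_hidden, n_layers_sub = cfg$n_layers_sub,
    n_layers_agat = cfg$n_layers_agat, alpha_prop = cfg$alpha_prop,
    lambda_decay = cfg$lambda_decay, beta_form = cfg$beta_form,
    pool_ratio = cfg$pool_ratio, n_heads = cfg$n_heads,
    leaky_slope = cfg$leaky_slope, d_edge_hidden = cfg$d_edge_hidden,
    dropout = cfg$dropout, n_classes = cfg$n_classes,
    use_subgraph_channel = cfg$use_subgraph_channel,
    use_agat_channel = cfg$use_agat_channel,
    use_att_fusion = cfg$use_att_fusion, seed = cfg$seed
  )
  solc <- sol_config(lambda_sol = obj$sol$lambda_sol,
                     edge_kernels = lapply(seq_len(nrow_or_len(obj$sol$edge_kernels)),
                                           pick_kernel, obj$sol$edge_kernels),
                     singular_kernels = lapply(seq_len(nrow_or_len(obj$sol$singular_kernels)),
                                               pick_kernel, obj$sol$singular_kernels),
                     positive_weight = obj$sol$positive_weight)
  params <- lapply(obj$params, function(p) unname(as.matrix(p)))
  # 1-row matrices survive JSON as plain vectors; restore bias shapes
  for (nm in names(params)) {
    if (ncol(params[[nm]]) == 1L && grepl("^(mlp_b|b_in)", nm)) {
      params[[nm]] <- t(params[[nm]])
    }
  }
  structure(list(params = params, config = config, sol = solc,
                 d_node = obj$d_node, threshold = obj$threshold,
                 best_epoch = obj$best_epoch,
                 history = list(steps = data.frame(), epochs = data.frame())),
            class = "ppis_fit")
}

nrow_or_len <- function(x) if (is.list(x)) length(x) else nrow(x)
pick_kernel <- function(i, x) {
  k <- if (is.list(x)) x[[i]] else x[i, ]
  as.numeric(k[!is.na(k)])
}

#' Train and compare ablation variants on one synthetic dataset
#'
#' Generates a dataset from `spec` once, trains the requested variants
#' on the identical train/val split with the same seed, and evaluates
#' all of them on the identical test split. Variants: `full`, `no_sol`,
#' `no_att_fusion`, `agat_only`, `subgraph_only`. An optional
#' `lambda_grid` adds rows retraining the full model at each structural
#' loss weight.
#'
#' @param spec a [synthetic_spec()].
#' @param config base [ppis_config()].
#' @param sol base [sol_config()].
#' @param variants character vector of variant names.
#' @param lambda_grid optional numeric vector of `lambda_sol` values.
#' @param seed training seed shared by all variants.
#' @param ... passed on to [ppis_fit()] (e.g. `epochs`).
#' @return data.frame, one row per variant, with the seven metrics and
#'   the four pattern accuracies; the test-set protein names are stored
#'   in `attr(, "test_proteins")`, the fitted models in
#'   `attr(, "fits")`.
#' @export
run_ablation_suite <- function(spec, config = ppis_config(),
                               sol = sol_config(),
                               variants = c("full", "no_sol", "no_att_fusion",
                                            "agat_only", "subgraph_only"),
                               lambda_grid = NULL, seed = 1L, ...) {
  ds <- generate_dataset(spec)
  jobs <- lapply(variants, function(v) list(name = v))
  for (lam in lambda_grid) {
    jobs[[length(jobs) + 1L]] <- list(name = sprintf("lambda_%g", lam),
                                      lambda = lam)
  }
  rows <- list()
  fits <- list()
  for (job in jobs) {
    cfg <- config; sl <- sol; usol <- TRUE
    switch(job$name,
           no_sol = { usol <- FALSE },
           no_att_fusion = { cfg$use_att_fusion <- FALSE },
           agat_only = { cfg$use_subgraph_channel <- FALSE },
           subgraph_only = { cfg$use_agat_channel <- FALSE })
    if (!is.null(job$lambda)) sl$lambda_sol <- job$lambda
    fit <- ppis_fit(ds$train, ds$val, config = cfg, sol = sl,
                    use_sol = usol, seed = seed, ...)
    rep <- evaluate_model(fit, ds$test)
    rows[[job$name]] <- data.frame(
      variant = job$name, ACC = rep$ACC, Precision = rep$Precision,
      Recall = rep$Recall, F1 = rep$F1, MCC = rep$MCC,
      AUROC = rep$AUROC, AUPRC = rep$AUPRC,
      acc_01 = rep$patterns[["01"]]$accuracy,
      acc_10 = rep$patterns[["10"]]$accuracy,
      acc_010 = rep$patterns[["010"]]$accuracy,
      acc_101 = rep$patterns[["101"]]$accuracy,
      edge_hits = rep$patterns[["01"]]$hits + rep$patterns[["10"]]$hits,
      edge_occurrences = rep$patterns[["01"]]$occurrences +
        rep$patterns[["10"]]$occurrences,
      stringsAsFactors = FALSE
    )
    fits[[job$name]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "test_proteins") <- vapply(ds$test, `[[`, "", "name")
  attr(out, "fits") <- fits
  out
}
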