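#' Specification for synthetic residue graphs
#'
#' Desk-scale protein-like fixtures: a self-avoiding-biased 3-D backbone
#' walk (Calpha-like 3.8 Angstrom steps, 3.0 Angstrom clash floor) gives
#' cutoff-graph neighbourhoods of realistic size (roughly 10-30
#' neighbours at 14 Angstrom); interacting-residue segments are planted
#' along the sequence (supplying "01"/"10" boundaries and, via
#' `singular_rate`, isolated "010" sites); node features carry a
#' label-dependent, graph-smoothed signal at a controllable
#' signal-to-noise ratio.
#'
#' @param n_proteins number of proteins to generate.
#' @param length_range integer `[min, max]` residues per protein.
#' @param step_length mean backbone spacing in Angstrom (default 3.8).
#' @param segment_rate expected interacting segments per 100 residues.
#' @param segment_length_mean mean planted segment length (geometric).
#' @param singular_rate probability a planted segment has length 1.
#' @param snr feature signal-to-noise ratio (>= 0; 0 = labels carry no
#'   feature signal).
#' @param d_node node-feature width (62 by default).
#' @param cutoff contact cutoff in Angstrom.
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 40L, length_range = c(60L, 120L),
                           step_length = 3.8, segment_rate = 4,
                           segment_length_mean = 5, singular_rate = 0.1,
                           snr = 5, d_node = 62L, cutoff = 14, seed = 1L) {
  stopifnot(n_proteins >= 1L, length_range[1] >= 3L,
            length_range[2] >= length_range[1], step_length > 0,
            segment_rate >= 0, segment_length_mean >= 1,
            singular_rate >= 0, singular_rate <= 1, snr >= 0, d_node >= 1L)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 step_length = step_length, segment_rate = segment_rate,
                 segment_length_mean = segment_length_mean,
                 singular_rate = singular_rate, snr = snr,
                 d_node = as.integer(d_node), cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}

#' Backbone-like 3-D random walk
#'
#' Fixed-step random walk with a clash floor: each new point is
#' `step_length` from its predecessor and at least `min_dist` from every
#' earlier point (rejection sampling; if a step exhausts its proposal
#' budget the whole walk restarts with a fresh sub-seed, with a
#' warning).
#'
#' @param length number of residues (>= 1).
#' @param step_length step size in Angstrom.
#' @param seed RNG seed.
#' @param min_dist minimum pairwise distance in Angstrom.
#' @return numeric `[length x 3]` coordinate matrix.
#' @export
generate_backbone <- function(length, step_length = 3.8, seed = 1L,
                              min_dist = 3.0) {
  stopifnot(length >= 1L)
  with_seed(seed, {
    for (attempt in seq_len(50L)) {
      coords <- try_walk(length, step_length, min_dist)
      if (!is.null(coords)) return(coords)
      warning(sprintf("backbone walk attempt %d exhausted its rejection budget; retrying with a fresh sub-seed", attempt))
      set.seed(seed + 1000003L * attempt)
    }
    stop("backbone generation failed after 50 restarts")
  })
}

try_walk <- function(length, step_length, min_dist) {
  coords <- matrix(0, length, 3L)
  if (length == 1L) return(coords)
  for (i in 2L:length) {
    placed <- FALSE
    for (tries in seq_len(200L)) {
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + step_length * dir
      prev <- coords[seq_len(i - 2L), , drop = FALSE]
      ok <- nrow(prev) == 0L ||
        min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_dist
      if (ok) { coords[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Plant interacting-residue segments
#'
#' `Poisson(segment_rate * L / 100)` segments are placed uniformly at
#' random without overlap (and with at least one non-interacting residue
#' between segments, so planted segments stay distinct). Each segment
#' has length 1 with probability `singular_rate` (an isolated "010"
#' site), otherwise `1 + Geometric(1 / segment_length_mean)`. Segments
#' that cannot be placed after a bounded number of tries are dropped.
#'
#' @param length chain length.
#' @param spec a [synthetic_spec()] (rates are read from it).
#' @param seed RNG seed.
#' @return integer 0/1 vector of length `length`.
#' @export
plant_labels <- function(length, spec, seed = 1L) {
  with_seed(seed, {
    labels <- integer(length)
    n_seg <- stats::rpois(1L, spec$segment_rate * length / 100)
    blocked <- logical(length)   # occupied or buffer positions
    for (s in seq_len(n_seg)) {
      len <- if (stats::runif(1L) < spec$singular_rate) 1L else
        1L + stats::rgeom(1L, 1 / spec$segment_length_mean)
      if (len > length) next
      for (tries in seq_len(50L)) {
        start <- sample.int(length - len + 1L, 1L)
        span <- start:(start + len - 1L)
        if (!any(blocked[span])) {
          labels[span] <- 1L
          lo <- max(1L, start - 1L); hi <- min(length, start + len)
          blocked[lo:hi] <- TRUE
          break
        }
      }
    }
    labels
  })
}

#' Label-correlated node features
#'
#' Each protein draws a class-contrast vector; the per-residue signal
#' `labels * contrast` is smoothed by one lazy averaging pass over the
#' cutoff graph (half self, half neighbourhood mean, so the signal is
#' informative both per-node and through graph context), scaled by
#' `snr`, and buried in standard-normal noise; columns are then min-max
#' normalised to `[0, 1]`. With `snr = 0` features are statistically
#' independent of the labels.
#'
#' @param labels binary vector.
#' @param coords `[n x 3]` coordinates (the smoothing graph comes from
#'   them).
#' @param snr signal-to-noise ratio.
#' @param d_node feature width.
#' @param seed RNG seed.
#' @param cutoff contact cutoff in Angstrom.
#' @param contrast optional class-contrast vector (length `d_node`).
#'   Proteins of one dataset must share it so the feature-label law is
#'   learnable across proteins; [generate_dataset()] draws it once per
#'   dataset. Default: drawn from `seed`.
#' @return numeric `[n x d_node]` matrix with entries in `[0, 1]`.
#' @export
generate_features <- function(labels, coords, snr, d_node = 62L, seed = 1L,
                              cutoff = 14, contrast = NULL) {
  n <- length(labels)
  stopifnot(nrow(coords) == n)
  if (is.null(contrast)) {
    contrast <- with_seed(seed + 1L, stats::rnorm(d_node))
  }
  stopifnot(length(contrast) == d_node)
  with_seed(seed, {
    M <- outer(as.numeric(labels), contrast)
    A <- build_adjacency(coords, cutoff)$adjacency * 1
    Anorm <- A / rowSums(A)
    M_smooth <- 0.5 * M + 0.5 * (Anorm %*% M)
    X <- snr * M_smooth + matrix(stats::rnorm(n * d_node), n, d_node)
    minmax_scale(X)
  })
}

#' Generate a synthetic dataset with train/val/test splits
#'
#' Runs backbone, label and feature generation for each protein,
#' assembles [residue_graph()] objects, and splits by protein
#' 70/15/15 (rounded). Deterministic in `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `train`, `val`, `test` (lists of `residue_graph`)
#'   and `manifest` (data.frame: name, length, n_positive, split).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_proteins
  sub <- with_seed(spec$seed, {
    list(seeds = matrix(sample.int(.Machine$integer.max - 1L, 3L * n), ncol = 3L),
         lengths = sample(seq.int(spec$length_range[1], spec$length_range[2]),
                          n, replace = TRUE),
         contrast = stats::rnorm(spec$d_node))
  })
  graphs <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sub$lengths[i]
    coords <- generate_backbone(L, spec$step_length, sub$seeds[i, 1L])
    labels <- plant_labels(L, spec, sub$seeds[i, 2L])
    feats <- generate_features(labels, coords, spec$snr, spec$d_node,
                               sub$seeds[i, 3L], spec$cutoff,
                               contrast = sub$contrast)
    graphs[[i]] <- residue_graph(feats, coords, labels = labels,
                                 name = sprintf("synth%03d", i),
                                 cutoff = spec$cutoff)
  }
  n_train <- round(0.7 * n)
  n_val <- round(0.15 * n)
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0 && n_train < n) {
    split[(n_train + 1L):min(n, n_train + n_val)] <- "val"
  }
  manifest <- data.frame(
    name = vapply(graphs, `[[`, "", "name"),
    length = vapply(graphs, `[[`, 0L, "n_residues"),
    n_positive = vapply(graphs, function(g) sum(g$labels), 0L),
    split = split,
    stringsAsFactors = FALSE
  )
  list(train = graphs[split == "train"], val = graphs[split == "val"],
       test = graphs[split == "test"], manifest = manifest)
}
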