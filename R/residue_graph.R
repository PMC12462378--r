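#' Residue graphs for interaction-site prediction
#'
#' A protein chain is represented as an undirected graph: nodes are
#' residues (each carrying a feature vector and the 3D coordinate of its
#' side-chain centroid), and two residues are connected when their
#' centroids lie within a distance cutoff (14 Angstrom by default).
#' Self-loops are always present (a residue is at distance 0 from
#' itself). Edges carry a 2-dimensional feature: normalised distance and
#' capped sequence separation.
#'
#' @param node_features numeric matrix, one row per residue.
#' @param coords numeric matrix `[n x 3]` of side-chain centroid
#'   coordinates in Angstrom.
#' @param labels optional binary vector (1 = interacting residue), in
#'   chain sequence order.
#' @param ids optional character vector of residue identifiers.
#' @param name protein/chain tag.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return An object of class `residue_graph` with fields
#'   `n_residues`, `node_features`, `coords`, `adjacency`, `edge_index`
#'   (2 x E, both directions and self-loops), `edge_features`, `labels`,
#'   `ids`, `name`, `cutoff`.
#' @export
residue_graph <- function(node_features, coords, labels = NULL, ids = NULL,
                          name = "protein", cutoff = 14) {
  node_features <- as.matrix(node_features)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3L, nrow(node_features) == n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- build_adjacency(coords, cutoff)
  ef <- build_edge_features(coords, ids, adj$adjacency, cutoff = cutoff)
  g <- structure(list(
    n_residues = n,
    node_features = node_features,
    coords = coords,
    adjacency = adj$adjacency,
    edge_index = ef$edge_index,
    edge_features = ef$edge_features,
    labels = if (!is.null(labels)) as.integer(labels) else NULL,
    ids = as.character(ids),
    name = name,
    cutoff = cutoff
  ), class = "residue_graph")
  validate_residue_graph(g)
  g
}

#' Validate residue-graph invariants
#'
#' Checks symmetry and self-loops of the adjacency, consistency of the
#' adjacency with the distance rule, finiteness of the node features and
#' well-formedness of the labels. Called by the constructor; exported so
#' generated or deserialised graphs can be re-checked.
#'
#' @param g a `residue_graph`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_residue_graph <- function(g) {
  stopifnot(inherits(g, "residue_graph"))
  n <- g$n_residues
  A <- g$adjacency
  if (!isTRUE(all(A == t(A)))) stop("adjacency is not symmetric")
  if (!all(diag(A))) stop("adjacency is missing self-loops")
  D <- as.matrix(stats::dist(g$coords))
  if (!isTRUE(all(A == (D < g$cutoff)))) {
    stop("adjacency inconsistent with the distance cutoff rule")
  }
  if (any(!is.finite(g$node_features))) stop("non-finite node features")
  if (!is.null(g$labels)) {
    if (length(g$labels) != n) stop("labels length != n_residues")
    if (!all(g$labels %in% c(0L, 1L))) stop("labels must be 0/1")
  }
  if (length(g$ids) != n) stop("ids length != n_residues")
  invisible(g)
}

#' @export
print.residue_graph <- function(x, ...) {
  npos <- if (is.null(x$labels)) NA_integer_ else sum(x$labels)
  cat(sprintf(
    "residue_graph '%s': %d residues, %d directed edges (cutoff %g A), %d node features%s\n",
    x$name, x$n_residues, ncol(x$edge_index), x$cutoff, ncol(x$node_features),
    if (is.na(npos)) ", unlabeled" else sprintf(", %d interacting", npos)
  ))
  invisible(x)
}

#' Side-chain centroid coordinates from a PDB file
#'
#' Parses the ATOM records of one chain and returns, per residue, the
#' arithmetic mean of its side-chain heavy-atom coordinates. Residues
#' without side-chain heavy atoms (glycine, truncated side chains) fall
#' back to the alpha-carbon position; residues with no resolvable atoms
#' at all are skipped with a warning. Output order is ascending residue
#' sequence number, insertion codes after their base number.
#'
#' @param pdb_path path to a PDB file.
#' @param chain chain identifier (single letter).
#' @return list with `coords` (`[n x 3]` matrix) and `ids` (character).
#' @export
read_pdb_centroids <- function(pdb_path, chain) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("chain not found: '%s'", chain))
  # drop hydrogens
  elem <- at$elesy
  if (!is.null(elem)) {
    hy <- !is.na(elem) & trimws(elem) %in% c("H", "D")
    at <- at[!hy, , drop = FALSE]
  }
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste0(at$resno, ins)
  ord_key <- unique(key[order(at$resno, ins)])
  backbone <- c("N", "CA", "C", "O", "OXT")
  coords <- matrix(NA_real_, length(ord_key), 3L)
  keep <- logical(length(ord_key))
  for (k in seq_along(ord_key)) {
    rows <- at[key == ord_key[k], , drop = FALSE]
    xyz <- cbind(rows$x, rows$y, rows$z)
    ok <- is.finite(rowSums(xyz))
    rows <- rows[ok, , drop = FALSE]
    xyz <- xyz[ok, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning(sprintf("residue %s has no resolvable atoms; skipped", ord_key[k]))
      next
    }
    side <- !(trimws(rows$elety) %in% backbone)
    if (any(side)) {
      coords[k, ] <- colMeans(xyz[side, , drop = FALSE])
    } else {
      ca <- trimws(rows$elety) == "CA"
      if (any(ca)) {
        coords[k, ] <- xyz[which(ca)[1L], ]
      } else {
        coords[k, ] <- colMeans(xyz)
      }
    }
    keep[k] <- TRUE
  }
  list(coords = coords[keep, , drop = FALSE], ids = ord_key[keep])
}

#' Distance-cutoff adjacency
#'
#' `adjacency(i, j)` is `TRUE` iff the Euclidean distance between
#' centroids i and j is strictly below `cutoff`. Self-pairs are included
#' (distance 0), which also guarantees every degree is positive.
#'
#' @param coords `[n x 3]` coordinate matrix (Angstrom).
#' @param cutoff distance cutoff in Angstrom (default 14).
#' @return list with logical `adjacency` `[n x n]` and the full numeric
#'   `dist` matrix (edge distances are read off it).
#' @export
build_adjacency <- function(coords, cutoff = 14) {
  coords <- as.matrix(coords)
  bad <- which(!is.finite(rowSums(coords)))
  if (length(bad)) {
    stop(sprintf("non-finite coordinates at residue index %s",
                 paste(bad, collapse = ", ")))
  }
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  list(adjacency = D < cutoff, dist = D)
}

#' Per-edge features: normalised distance and capped sequence separation
#'
#' For each ordered adjacent pair (i, j) the edge feature is
#' `c(distance / cutoff, min(|i - j|, sep_cap) / sep_cap)`; both
#' components lie in `[0, 1]`, the feature is symmetric in (i, j), and
#' self-loops get `c(0, 0)`. Sequence separation is measured in residue
#' positions along the chain.
#'
#' @param coords `[n x 3]` coordinates the adjacency was built from.
#' @param ids residue identifiers (length n; recorded order defines
#'   sequence positions).
#' @param adjacency logical `[n x n]` adjacency with self-loops.
#' @param cutoff the cutoff used to build `adjacency`.
#' @param sep_cap cap on sequence separation (default 64).
#' @return list with `edge_index` (integer `[2 x E]`, both directions,
#'   column-major enumeration) and `edge_features` (`[E x 2]`).
#' @export
build_edge_features <- function(coords, ids = NULL, adjacency, cutoff = 14,
                                sep_cap = 64) {
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  w <- which(adjacency)
  n <- nrow(adjacency)
  i <- ((w - 1L) %% n) + 1L
  j <- ((w - 1L) %/% n) + 1L
  dist_feat <- D[cbind(i, j)] / cutoff
  sep_feat <- pmin(abs(i - j), sep_cap) / sep_cap
  list(edge_index = rbind(i, j),
       edge_features = cbind(dist_feat, sep_feat, deparse.level = 0))
}

#' Bundle the five per-residue feature blocks
#'
#' The 62-dimensional handcrafted node representation is the
#' concatenation of PSSM (20), HMM profile (20), DSSP descriptors (14),
#' mean atomic properties (5: atomic mass, B-factor, side-chain
#' membership, electronic charge, van der Waals radius) and the centred
#' side-chain-centroid coordinates (3).
#'
#' @param pssm,hmm,dssp,atomic,pef numeric matrices with widths
#'   20/20/14/5/3 and a common row count.
#' @return an object of class `feature_bundle`.
#' @export
feature_bundle <- function(pssm, hmm, dssp, atomic, pef) {
  blocks <- list(pssm = as.matrix(pssm), hmm = as.matrix(hmm),
                 dssp = as.matrix(dssp), atomic = as.matrix(atomic),
                 pef = as.matrix(pef))
  widths <- c(pssm = 20L, hmm = 20L, dssp = 14L, atomic = 5L, pef = 3L)
  for (nm in names(widths)) {
    if (ncol(blocks[[nm]]) != widths[[nm]]) {
      stop(sprintf("block '%s' has width %d, expected %d",
                   nm, ncol(blocks[[nm]]), widths[[nm]]))
    }
  }
  ns <- vapply(blocks, nrow, 0L)
  if (length(unique(ns)) != 1L) stop("feature blocks disagree on residue count")
  structure(blocks, class = "feature_bundle")
}

#' Assemble and normalise the node feature matrix
#'
#' Concatenates the blocks in the order pssm | hmm | dssp | atomic | pef
#' (width 62) and min-max scales every column to `[0, 1]` using the
#' per-protein column minimum and maximum; constant columns map to 0.
#'
#' @param bundle a [feature_bundle()].
#' @return numeric matrix `[n x 62]` with entries in `[0, 1]`.
#' @export
assemble_node_features <- function(bundle) {
  stopifnot(inherits(bundle, "feature_bundle"))
  X <- cbind(bundle$pssm, bundle$hmm, bundle$dssp, bundle$atomic, bundle$pef)
  minmax_scale(X)
}

# column-wise min-max scaling; constant columns -> 0
minmax_scale <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  out <- sweep(X, 2L, lo, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  dimnames(out) <- NULL
  out
}

GRAPH_FORMAT_VERSION <- 1L

#' Save / load a residue graph
#'
#' The on-disk layout is a single JSON file holding the named arrays
#' (`node_features`, `coords`, `edge_index`, `edge_features`, `labels`,
#' `ids`) plus a header (`format_version`, `cutoff`, `d_node`, `name`).
#' Doubles are written at full IEEE precision so the round-trip is
#' bit-identical.
#'
#' @param g a `residue_graph`.
#' @param path file path.
#' @return `save_graph` returns `path` invisibly; `load_graph` returns
#'   the reconstructed `residue_graph`.
#' @export
save_graph <- function(g, path) {
  stopifnot(inherits(g, "residue_graph"))
  obj <- list(
    format_version = GRAPH_FORMAT_VERSION,
    cutoff = g$cutoff,
    d_node = ncol(g$node_features),
    name = g$name,
    ids = g$ids,
    node_features = g$node_features,
    coords = g$coords,
    edge_index = g$edge_index,
    edge_features = g$edge_features,
    labels = g$labels
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("not a readable graph container: %s",
                                 conditionMessage(e)))
                  })
  if (is.null(obj$format_version)) stop("graph container missing format_version")
  if (obj$format_version != GRAPH_FORMAT_VERSION) {
    stop(sprintf("unsupported graph format version %s (this build reads %d)",
                 obj$format_version, GRAPH_FORMAT_VERSION))
  }
  needed <- c("cutoff", "name", "ids", "node_features", "coords",
              "edge_index", "edge_features")
  miss <- setdiff(needed, names(obj))
  if (length(miss)) {
    stop(sprintf("graph container missing fields: %s", paste(miss, collapse = ", ")))
  }
  g <- structure(list(
    n_residues = nrow(as.matrix(obj$coords)),
    node_features = unname(as.matrix(obj$node_features)),
    coords = unname(as.matrix(obj$coords)),
    adjacency = NULL,
    edge_index = unname(matrix(as.integer(obj$edge_index), nrow = 2L)),
    edge_features = unname(as.matrix(obj$edge_features)),
    labels = if (is.null(obj$labels)) NULL else as.integer(obj$labels),
    ids = as.character(obj$ids),
    name = obj$name,
    cutoff = as.numeric(obj$cutoff)
  ), class = "residue_graph")
  g$adjacency <- build_adjacency(g$coords, g$cutoff)$adjacency
  validate_residue_graph(g)
  g
}

#' Read a per-residue feature table
#'
#' Expects a TSV with a header whose column names carry block prefixes
#' `pssm`, `hmm`, `dssp`, `atomic`, `pef` (e.g. `pssm1..pssm20`), one row
#' per residue in chain order.
#'
#' @param path TSV path.
#' @return a [feature_bundle()].
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(tab), value = TRUE)
    as.matrix(tab[, cols, drop = FALSE])
  }
  feature_bundle(pssm = pick("pssm"), hmm = pick("hmm"), dssp = pick("dssp"),
                 atomic = pick("atomic"), pef = pick("pef"))
}

#' Read per-residue binary labels
#'
#' Two-column TSV: residue id, label (0/1).
#'
#' @param path TSV path.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  lab <- as.integer(tab[[2L]])
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1")
  names(lab) <- as.character(tab[[1L]])
  lab
}
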