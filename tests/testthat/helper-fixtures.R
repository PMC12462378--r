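# shared fixtures: random residue graphs, a hand-written PDB chain, and
# a finite-difference gradient checker for the autodiff engine

random_coords <- function(n, scale = max(8, 4 * n^(1 / 3))) {
  matrix(runif(n * 3, 0, scale), n, 3)
}

# a labelled residue graph with random features/coords; box size keeps
# the 14 A adjacency mixed (neither empty nor complete) for n >= ~5
random_graph <- function(n, d = 8, cutoff = 14, name = "rg") {
  residue_graph(matrix(runif(n * d), n, d), random_coords(n),
                labels = rbinom(n, 1, 0.3), name = name, cutoff = cutoff)
}

# re-index a residue graph by `perm` carrying edge features over (the
# model should be equivariant to this relabelling)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  ei <- rbind(inv[g$edge_index[1L, ]], inv[g$edge_index[2L, ]])
  structure(list(
    n_residues = g$n_residues,
    node_features = g$node_features[perm, , drop = FALSE],
    coords = g$coords[perm, , drop = FALSE],
    adjacency = g$adjacency[perm, perm, drop = FALSE],
    edge_index = ei,
    edge_features = g$edge_features,
    labels = g$labels[perm],
    ids = g$ids[perm],
    name = g$name, cutoff = g$cutoff
  ), class = "residue_graph")
}

# three-residue PDB fixture: ALA (two side-chain positions), GLY
# (backbone only), SER; coordinates chosen so centroids are easy to
# state and also recomputed by a per-atom loop in the test
write_tiny_pdb <- function(path) {
  fmt <- function(serial, name, resn, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, "", resn, chain, resno, "", x, y, z, 1, 0, elem)
  }
  lines <- c(
    fmt(1, "N",  "ALA", "A", 1, -1, 0, 0, "N"),
    fmt(2, "CA", "ALA", "A", 1,  0, 0, 0, "C"),
    fmt(3, "C",  "ALA", "A", 1,  1, 0, 0, "C"),
    fmt(4, "O",  "ALA", "A", 1,  2, 0, 0, "O"),
    fmt(5, "CB", "ALA", "A", 1,  0, 0, 0, "C"),
    fmt(6, "HB1","ALA", "A", 1,  9, 9, 9, "H"),     # hydrogen: ignored
    fmt(7, "CB2","ALA", "A", 1,  2, 0, 0, "C"),     # second side-chain atom
    fmt(8, "N",  "GLY", "A", 2,  4, 0, 0, "N"),
    fmt(9, "CA", "GLY", "A", 2,  5, 5, 5, "C"),
    fmt(10, "C", "GLY", "A", 2,  6, 0, 0, "C"),
    fmt(11, "O", "GLY", "A", 2,  7, 0, 0, "O"),
    fmt(12, "N", "SER", "A", 3,  8, 0, 0, "N"),
    fmt(13, "CA","SER", "A", 3,  9, 0, 0, "C"),
    fmt(14, "C", "SER", "A", 3, 10, 0, 0, "C"),
    fmt(15, "O", "SER", "A", 3, 11, 0, 0, "O"),
    fmt(16, "CB","SER", "A", 3,  9, 1, 0, "C"),
    fmt(17, "OG","SER", "A", 3,  9, 3, 0, "O"),
    "END"
  )
  writeLines(lines, path)
  path
}

# central finite-difference gradient of f (scalar-valued) at matrix x
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# access internal autodiff/tape helpers
ppi <- function(name) getFromNamespace(name, "ppisite")

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
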