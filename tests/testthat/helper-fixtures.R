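# small in-code fixtures shared across tests

# CA-only structure from a coordinate matrix
mk_ca_structure <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                            id = "test", element = "C") {
  xyz <- as.matrix(xyz)
  xl_structure(data.frame(
    chain = chain, resno = resno, resid = "ALA", elety = "CA",
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, stringsAsFactors = FALSE), id = id)
}

# seeded random blob of n CA beads in a box
mk_blob <- function(n, centre = c(0, 0, 0), half = 10, chain = "A",
                    id = "blob") {
  xyz <- sweep(matrix(stats::runif(3 * n, -half, half), n, 3), 2L, centre, "+")
  mk_ca_structure(xyz, chain = chain, id = id)
}

# a tiny two-chain PDB file written by hand (fixed columns)
write_fixture_pdb <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   1.000   0.000  1.00  0.00           C",
    "TER       4      GLY A   2",
    "ATOM      5  CA  ALA B  10       0.000   5.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# independent brute-force cross-link scorer working straight off the atom
# table (no package scoring internals)
brute_score <- function(structure, links, chain_map, threshold = 22) {
  at <- structure$atoms[structure$atoms$elety == "CA", ]
  dist_one <- function(lk) {
    ca <- at[at$chain %in% chain_map[[lk$protein_a]] & at$resno == lk$residue_a, ]
    cb <- at[at$chain %in% chain_map[[lk$protein_b]] & at$resno == lk$residue_b, ]
    if (!nrow(ca) || !nrow(cb)) return(NA_real_)
    best <- Inf
    for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
      if (lk$protein_a == lk$protein_b && ca$chain[i] == cb$chain[j] &&
          lk$residue_a == lk$residue_b) next
      d <- sqrt((ca$x[i] - cb$x[j])^2 + (ca$y[i] - cb$y[j])^2 +
                (ca$z[i] - cb$z[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) best else NA_real_
  }
  d <- vapply(seq_len(nrow(links)), function(i) dist_one(links[i, ]), numeric(1))
  mappable <- !is.na(d)
  list(fraction = sum(d[mappable] < threshold) / sum(mappable),
       n_mappable = sum(mappable), distances = d)
}

# interface beads of a reference pair (within radius), shared by recovery tests
ref_interface <- function(ref_a, ref_b, radius = 10) {
  d2 <- outer(rowSums(ref_a^2), rowSums(ref_b^2), "+") - 2 * tcrossprod(ref_a, ref_b)
  list(i1 = which(apply(d2, 1, min) < radius^2),
       i2 = which(apply(d2, 2, min) < radius^2))
}
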