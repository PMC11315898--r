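test_that("rigid transforms compose, invert and validate", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_transform(); b <- random_transform()
    ab <- rt_compose(a, b)
    x <- stats::rnorm(3)
    expect_equal(rt_apply(ab, x), rt_apply(a, rt_apply(b, x)), tolerance = 1e-9)
    inv <- rt_invert(a)
    expect_equal(rt_apply(inv, rt_apply(a, x)), x, tolerance = 1e-9)
    c3 <- random_transform()
    lhs <- rt_compose(rt_compose(a, b), c3)
    rhs <- rt_compose(a, rt_compose(b, c3))
    expect_equal(lhs$R, rhs$R, tolerance = 1e-9)
    expect_equal(lhs$t, rhs$t, tolerance = 1e-9)
  }
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "orthonormal")
})

test_that("PDB parsing resolves altlocs, drops waters, counts chains", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(path)
  s <- read_structure(path)
  expect_s3_class(s, "xl_structure")
  expect_equal(nrow(s$atoms), 4L)
  expect_equal(sort(unique(s$atoms$chain)), c("A", "B"))
  expect_equal(n_residues(s), 3L)

  # altloc: A at occupancy 0.6 beats B at 0.4
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "END"), path2)
  s2 <- read_structure(path2)
  expect_equal(nrow(s2$atoms), 1L)
  expect_equal(s2$atoms$x, 1.0)

  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found|cannot parse")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_structure(empty), "cannot parse|no atoms")
})

test_that("write_structure round-trips and enforces field limits", {
  set.seed(5)
  s <- mk_ca_structure(matrix(round(stats::runif(30, -50, 50), 3), 10, 3))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, p1)
  r1 <- read_structure(p1)
  expect_equal(r1$atoms$chain, s$atoms$chain)
  expect_equal(r1$atoms$resno, s$atoms$resno)
  expect_equal(r1$atoms$elety, s$atoms$elety)
  expect_equal(as.matrix(r1$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 5e-4, ignore_attr = TRUE)
  # byte-stable re-serialisation
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(r1, p2)
  expect_identical(readLines(p1), readLines(p2))
  # TER between chains
  two <- combine_structures(list(
    mk_ca_structure(diag(3), chain = "A"),
    mk_ca_structure(diag(3) + 20, chain = "B")))
  p3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(two, p3)
  expect_equal(sum(grepl("^TER", readLines(p3))), 2L)
  # fixed-width overflow
  bad <- mk_ca_structure(matrix(c(99999.9, 0, 0), 1, 3))
  expect_error(write_structure(bad, withr::local_tempfile(fileext = ".pdb")),
               "10000")
})

test_that("ca_coords honours selections and reports gap residues", {
  xyz <- matrix(seq_len(15), 5, 3)
  s <- mk_ca_structure(xyz, resno = 10:14)
  expect_equal(nrow(ca_coords(s)$xyz), 5L)
  sel <- ca_coords(s, "A:10-12")
  expect_equal(nrow(sel$xyz), 3L)
  expect_equal(sel$index$resno, 10:12)
  expect_error(ca_coords(s, "Z"), "matches no residues")
  # residue without CA lands in the gap report
  at <- s$atoms
  at$elety[2] <- "CB"
  s2 <- xl_structure(at)
  cc <- ca_coords(s2)
  expect_equal(nrow(cc$xyz), 4L)
  expect_equal(cc$gaps$resno, 11L)
})

test_that("apply_transform is an isometry and leaves the input untouched", {
  set.seed(21)
  s <- mk_blob(40)
  d0 <- dist(as.matrix(s$atoms[, c("x", "y", "z")]))
  for (i in 1:10) {
    tr <- random_transform()
    s2 <- apply_transform(s, tr)
    expect_equal(as.numeric(dist(as.matrix(s2$atoms[, c("x", "y", "z")]))),
                 as.numeric(d0), tolerance = 1e-9)
  }
  expect_equal(s$atoms$x, mk_blob_check <- s$atoms$x)  # original unchanged
  s3 <- apply_transform(s, rigid_transform(translation = c(1, 0, 0)))
  expect_equal(s3$atoms$x, s$atoms$x + 1)
  expect_error(apply_transform(s, list(R = diag(3), t = c(0, 0, 0))),
               "rigid_transform")
})

test_that("superposition recovers seeded transforms exactly", {
  set.seed(33)
  for (i in 1:15) {
    X <- matrix(stats::rnorm(60, sd = 15), 20, 3)
    tr <- random_transform()
    Y <- rt_apply(tr, X)
    fit <- superpose(Y, X)   # maps the moved copy back onto the original
    expect_lt(fit$rmsd, 1e-9)
    inv <- rt_invert(tr)
    expect_equal(fit$transform$R, inv$R, tolerance = 1e-6)
    expect_equal(fit$transform$t, inv$t, tolerance = 1e-6)
    expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  }
  self <- superpose(X <- matrix(stats::rnorm(30), 10, 3), X)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$transform$R, diag(3), tolerance = 1e-9)
  expect_error(superpose(X[1:4, ], X), "differ in length")
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate|collinear")
})

test_that("every writable structure is re-readable with identical CA lists", {
  set.seed(7)
  for (i in 1:5) {
    s <- mk_blob(25, centre = stats::runif(3, -20, 20), id = "rt")
    p <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s, p)
    r <- read_structure(p)
    expect_equal(ca_coords(r)$xyz, ca_coords(s)$xyz, tolerance = 5e-4,
                 ignore_attr = TRUE)
  }
})

test_that("subset_structure extracts residue ranges", {
  s <- mk_ca_structure(matrix(1:30, 10, 3), resno = 101:110)
  sub <- subset_structure(s, "A:103-105")
  expect_equal(n_residues(sub), 3L)
  expect_error(subset_structure(s, "B"), "matches nothing")
})
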