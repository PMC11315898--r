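test_that("rotation grid contains the identity, no duplicates, and covers", {
  g90 <- rotation_grid(90)
  expect_lt(length(g90), 60)
  expect_equal(g90[[1]], diag(3))
  # pairwise distinct
  for (i in seq_along(g90)) for (j in seq_len(i - 1L))
    expect_gt(rotation_distance(g90[[i]], g90[[j]]), 1e-6)
  # covering at 15 degrees, checked against 1000 seeded random rotations
  g15 <- rotation_grid(15)
  quat_of <- function(R) {
    # rotation matrix -> unit quaternion (w,x,y,z)
    w <- sqrt(max(0, 1 + R[1,1] + R[2,2] + R[3,3])) / 2
    if (w > 1e-6) {
      c(w, (R[3,2]-R[2,3])/(4*w), (R[1,3]-R[3,1])/(4*w), (R[2,1]-R[1,2])/(4*w))
    } else {
      q <- c(w, sqrt(pmax(0, 1 + diag(R) - sum(diag(R)) + 2*diag(R)))/2)[1:4]
      q / sqrt(sum(q^2))
    }
  }
  G <- t(vapply(g15, quat_of, numeric(4)))
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    ang <- 2 * acos(min(1, max(abs(G %*% q)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lte(worst, 15)
  expect_error(rotation_grid(0), "step")
  expect_error(rotation_grid(120), "step")
})

test_that("optimal translation matches the closed form and a grid search", {
  A <- mk_ca_structure(matrix(c(0, 0, 0), 1, 3), chain = "A")
  B <- mk_ca_structure(matrix(c(5, 0, 0), 1, 3), chain = "B")
  cm <- list(pa = "A", pb = "B")
  lk <- crosslink_table("pa", 1, "pb", 1)
  tr <- optimal_translation(A, B, diag(3), lk, cm)
  expect_equal(tr, c(-5, 0, 0))

  # two incompatible links: translation equals the mean offset, verified by
  # brute-force search over a 0.5 A translation lattice
  A2 <- mk_ca_structure(rbind(c(0, 0, 0), c(10, 0, 0)), chain = "A")
  B2 <- mk_ca_structure(rbind(c(0, 4, 0), c(2, -3, 0)), chain = "B")
  links2 <- crosslink_table("pa", c(1, 2), "pb", c(1, 2))
  got <- optimal_translation(A2, B2, diag(3), links2, cm)
  expect_equal(got, colMeans(rbind(c(0, -4, 0), c(8, 3, 0))))
  obj <- function(t) {
    d1 <- sum((c(0, 0, 0) - (c(0, 4, 0) + t))^2)
    d2 <- sum((c(10, 0, 0) - (c(2, -3, 0) + t))^2)
    (d1 + d2) / 2
  }
  grid <- expand.grid(x = seq(-2, 10, 0.5), y = seq(-6, 6, 0.5),
                      z = seq(-2, 2, 0.5))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  expect_equal(got, best, tolerance = 0.51, ignore_attr = TRUE)
  expect_lte(obj(got), min(vals) + 1e-9)

  # already-satisfied anchors need no translation
  expect_equal(optimal_translation(A, mk_ca_structure(matrix(0, 1, 3),
                                                      chain = "B"),
                                   diag(3), lk, cm), c(0, 0, 0))
})

test_that("clash counting: grid equals brute force; boundary cases", {
  far <- clash_count(mk_ca_structure(matrix(0, 1, 3)),
                     mk_ca_structure(matrix(c(100, 0, 0), 1, 3)))
  expect_equal(far, 0L)
  set.seed(3)
  s <- mk_blob(50)
  expect_equal(clash_count(s, s, method = "grid"),
               clash_count(s, s, method = "brute"))
  expect_gte(clash_count(s, s), 50L)   # every bead pairs with itself at 0
  for (i in 1:10) {
    a <- mk_blob(60, centre = c(0, 0, 0))
    b <- mk_blob(60, centre = stats::runif(3, -8, 8), chain = "B")
    cd <- stats::runif(1, 2, 8)
    expect_equal(clash_count(a, b, cd, method = "grid"),
                 clash_count(a, b, cd, method = "brute"))
  }
})

test_that("docking recovers a synthetic pair and respects retention strictly", {
  set.seed(71)
  tr <- make_mis18_mimic(7)
  tr$edges <- "alpha2--alpha3"
  sim <- simulate_crosslinks(tr, links_per_interface = 10, decoy_fraction = 0,
                             seed = 7)
  pert <- perturb_subunits(tr, seed = 70)
  A <- pert$subunits$alpha2; B <- pert$subunits$alpha3
  cfgs <- dock_pair(A, B, sim$links, tr$chain_map,
                    docking_params(rotation_step = 24, top_k = 30))
  expect_gt(length(cfgs), 0)
  expect_s3_class(cfgs[[1]]$transform, "rigid_transform")
  # sorted by score, retention strict, clash cap respected
  sc <- vapply(cfgs, `[[`, numeric(1), "score")
  expect_true(all(diff(sc) <= 1e-12))
  expect_true(all(vapply(cfgs, `[[`, numeric(1), "fraction_satisfied") > 0.7))
  expect_true(all(vapply(cfgs, `[[`, integer(1), "clash_count") <= 5))
  # the top configuration reproduces the designed interface
  aT <- ca_coords(tr$subunits$alpha2)$xyz
  bT <- ca_coords(tr$subunits$alpha3)$xyz
  iface <- ref_interface(aT, bT)
  aP <- ca_coords(A)$xyz; bP <- ca_coords(B)$xyz
  ir <- interface_rmsd(aP, rt_apply(cfgs[[1]]$transform, bP), aT, bT)
  expect_lt(ir, 8)

  # geometrically unsatisfiable restraints give an empty list, not an error
  big <- crosslink_table("alpha2", c(1, 1), "alpha3", c(1, 2))
  Afar <- mk_ca_structure(rbind(c(0, 0, 0), c(80, 0, 0)), chain = "C",
                          resno = 1:2)
  Bfar <- mk_ca_structure(rbind(c(0, 0, 0), c(-80, 0, 0)), chain = "D",
                          resno = 1:2)
  hopeless <- crosslink_table("x", c(1, 1, 2, 2), "y", c(1, 2, 1, 2))
  expect_message(
    empty <- dock_pair(Afar, Bfar, hopeless, list(x = "C", y = "D"),
                       docking_params(rotation_step = 45)),
    "no configuration")
  expect_length(empty, 0)

  expect_error(dock_pair(A, B, crosslink_table("alpha2", 1, "alpha3", 1),
                         tr$chain_map, docking_params()),
               "at least 2")
})

test_that("with decoys present every retained configuration beats >70% strictly", {
  # 10 links, 3 decoys: >0.7 means at least 8 of 10 satisfied
  set.seed(13)
  tr <- make_mis18_mimic(13)
  tr$edges <- "alpha1--beta1"
  sim <- simulate_crosslinks(tr, links_per_interface = 7, decoy_fraction = 0.3,
                             seed = 13)
  expect_equal(sim$n_true, 7L)
  expect_equal(sim$n_decoy, 3L)
  pert <- perturb_subunits(tr, seed = 131)
  cfgs <- dock_pair(pert$subunits$alpha1, pert$subunits$beta1, sim$links,
                    tr$chain_map, docking_params(rotation_step = 24, top_k = 20))
  for (cf in cfgs) {
    n_sat <- round(cf$fraction_satisfied * 10)
    expect_gte(n_sat, 8)
    expect_gt(cf$fraction_satisfied, 0.7)
  }
})

test_that("docking is deterministic and frame-consistent", {
  set.seed(41)
  tr <- make_mis18_mimic(4)
  tr$edges <- "beta2--alpha4"
  sim <- simulate_crosslinks(tr, links_per_interface = 10, decoy_fraction = 0,
                             seed = 4)
  pert <- perturb_subunits(tr, seed = 40)
  A <- pert$subunits$beta2; B <- pert$subunits$alpha4
  p <- docking_params(rotation_step = 24, top_k = 10)
  c1 <- dock_pair(A, B, sim$links, tr$chain_map, p)
  c2 <- dock_pair(A, B, sim$links, tr$chain_map, p)
  expect_identical(lapply(c1, `[[`, "transform"), lapply(c2, `[[`, "transform"))
  # docking the pair in either direction yields mutually inverse poses:
  # composing the best forward transform with some backward transform must
  # come back near the identity (assessed as body RMSD of the receptor)
  c_ba <- dock_pair(B, A, sim$links, tr$chain_map, p)
  fwd <- c1[[1]]$transform
  aca <- ca_coords(A)$xyz
  round_trip <- vapply(c_ba, function(cf) {
    comp <- rt_compose(fwd, cf$transform)
    sqrt(mean(rowSums((rt_apply(comp, aca) - aca)^2)))
  }, numeric(1))
  expect_lt(min(round_trip), 5)
})
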