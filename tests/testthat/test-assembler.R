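# a compact 3-subunit fixture: one bundle's three helix rods, cut out of the
# mimic so ground truth is known
bundle_fixture <- function(seed, links_per_interface = 8, decoy_fraction = 0) {
  tr <- make_mis18_mimic(seed)
  rods <- list(alpha1 = subset_structure(tr$subunits$alpha1, "A:101-136"),
               alpha2 = subset_structure(tr$subunits$alpha2, "C:101-136"),
               beta1 = subset_structure(tr$subunits$beta1, "B:101-136"))
  truth <- tr
  truth$subunits <- rods
  truth$structure <- combine_structures(rods, id = "bundle")
  truth$edges <- sort(c("alpha1--alpha2", "alpha1--beta1", "alpha2--beta1"))
  truth$chain_map <- list(alpha1 = "A", alpha2 = "C", beta1 = "B")
  truth$manifest <- truth$manifest[truth$manifest$subunit %in% names(rods), ]
  sim <- simulate_crosslinks(truth, links_per_interface = links_per_interface,
                             decoy_fraction = decoy_fraction, seed = seed)
  pert <- perturb_subunits(truth, seed = seed + 500)
  list(truth = truth, sim = sim, pert = pert)
}

test_that("a noise-free three-subunit bundle is recovered near ground truth", {
  fx <- bundle_fixture(2, links_per_interface = 16)
  asms <- assemble(fx$pert$subunits, fx$sim$links, fx$truth$chain_map,
                   assembly_params(beam_width = 30, per_pair_configs = 30,
                                   docking = docking_params(rotation_step = 20)))
  expect_gt(length(asms), 0)
  top <- asms[[1]]
  expect_named(top$placements, names(fx$truth$subunits), ignore.order = TRUE)
  expect_equal(top$global_fraction_satisfied, 1.0)
  # whole-bundle recovery after superposition
  mod <- assembly_structure(top, fx$pert$subunits)
  rmsd <- superpose(ca_coords(mod)$xyz, ca_coords(fx$truth$structure)$xyz)$rmsd
  expect_lt(rmsd, 5)
  # first subunit anchored at identity
  anchored <- vapply(top$placements, function(p)
    rotation_angle(p$R) < 1e-6 && all(abs(p$t) < 1e-6), logical(1))
  expect_true(any(anchored))
})

test_that("assemble rejects disconnected link graphs, naming the components", {
  a <- mk_ca_structure(matrix(stats::rnorm(30), 10, 3), chain = "A")
  b <- mk_ca_structure(matrix(stats::rnorm(30), 10, 3), chain = "B")
  c3 <- mk_ca_structure(matrix(stats::rnorm(30), 10, 3), chain = "C")
  cm <- list(pa = "A", pb = "B", pc = "C")
  links <- crosslink_table("pa", c(1, 2), "pb", c(1, 2))
  expect_error(
    assemble(list(pa = a, pb = b, pc = c3), links, cm),
    "disconnected.*pc|pc.*disconnected")
})

test_that("assembly scoring matches ground-truth bookkeeping and is monotone", {
  tr <- make_mis18_mimic(3)
  sim0 <- simulate_crosslinks(tr, decoy_fraction = 0, seed = 3)
  ident <- lapply(tr$subunits, function(s) rigid_transform())
  asm <- structure(list(placements = ident), class = "xl_assembly")
  rep0 <- score_assembly(asm, tr$subunits, sim0$links, tr$chain_map)
  expect_equal(rep0$fraction_satisfied, 1.0)

  # decoys at 10%: fraction equals the generator's exact bookkeeping
  sim1 <- simulate_crosslinks(tr, decoy_fraction = 0.1, seed = 3)
  rep1 <- score_assembly(asm, tr$subunits, sim1$links, tr$chain_map)
  expect_equal(rep1$fraction_satisfied,
               sim1$n_true / (sim1$n_true + sim1$n_decoy))

  # translating one subunit far away strictly lowers the fraction
  moved <- ident
  moved$alpha1 <- rigid_transform(translation = c(100, 0, 0))
  asm2 <- structure(list(placements = moved), class = "xl_assembly")
  rep2 <- score_assembly(asm2, tr$subunits, sim0$links, tr$chain_map)
  expect_lt(rep2$fraction_satisfied, rep0$fraction_satisfied)
  expect_error(score_assembly(structure(list(placements = ident[-1]),
                                        class = "xl_assembly"),
                              tr$subunits, sim0$links, tr$chain_map),
               "missing placement")
})

test_that("assembly scores are invariant under a global rigid transform", {
  tr <- make_mis18_mimic(5)
  sim <- simulate_crosslinks(tr, decoy_fraction = 0.1, seed = 5)
  ident <- lapply(tr$subunits, function(s) rigid_transform())
  base <- score_assembly(structure(list(placements = ident),
                                   class = "xl_assembly"),
                         tr$subunits, sim$links, tr$chain_map)
  set.seed(50)
  for (i in 1:3) {
    g <- random_transform()
    pl <- lapply(ident, function(p) rt_compose(g, p))
    got <- score_assembly(structure(list(placements = pl),
                                    class = "xl_assembly"),
                          tr$subunits, sim$links, tr$chain_map)
    expect_equal(got$per_link$min_distance, base$per_link$min_distance,
                 tolerance = 1e-9)
  }
})

test_that("assembly clustering deduplicates and is idempotent", {
  tr <- make_mis18_mimic(6)
  subs <- tr$subunits[c("alpha1", "beta1")]
  ident <- lapply(subs, function(s) rigid_transform())
  mk <- function(pl, score) structure(list(placements = pl, score = score),
                                      class = "xl_assembly")
  a1 <- mk(ident, 1.0)
  a2 <- mk(ident, 0.9)                       # duplicate of a1
  shifted <- ident
  shifted$beta1 <- rigid_transform(translation = c(50, 0, 0))
  a3 <- mk(shifted, 0.8)
  reps <- cluster_assemblies(list(a1, a2, a3), subs, cluster_rmsd = 5)
  expect_length(reps, 2)
  expect_equal(reps[[1]]$score, 1.0)
  again <- cluster_assemblies(unclass(reps), subs, cluster_rmsd = 5)
  expect_length(again, 2)
  expect_identical(lapply(again, `[[`, "placements"),
                   lapply(reps, `[[`, "placements"))
})

test_that("the core mimic run recovers the 4:2:2 census deterministically", {
  tr <- make_mis18_mimic(2)
  sim <- simulate_crosslinks(tr, decoy_fraction = 0.1, seed = 2)
  pert <- perturb_subunits(tr, seed = 2)
  pars <- assembly_params(beam_width = 30, per_pair_configs = 30,
                          docking = docking_params(rotation_step = 24))
  asms <- assemble(pert$subunits, sim$links, tr$chain_map, pars)
  expect_gt(length(asms), 0)
  top <- asms[[1]]
  types <- tr$manifest$type[match(names(top$placements), tr$manifest$subunit)]
  expect_equal(sum(types == "alpha"), 4L)
  expect_equal(sum(types == "beta"), 2L)
  expect_equal(sum(types == "bp1"), 2L)
  # consistency: the tracked score agrees with a from-scratch rescore
  rep1 <- score_assembly(top, pert$subunits, sim$links, tr$chain_map)
  expect_equal(rep1$fraction_satisfied, top$global_fraction_satisfied,
               tolerance = 1e-9)
  expect_gt(top$global_fraction_satisfied, 0.7)
  # determinism of the full assembly search
  asms2 <- assemble(pert$subunits, sim$links, tr$chain_map, pars)
  expect_identical(lapply(asms, `[[`, "placements"),
                   lapply(asms2, `[[`, "placements"))
})
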