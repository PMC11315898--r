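#' Synthetic Mis18-mimic assembly fixtures
#'
#' Deterministic generator of a ground-truth multi-subunit assembly with the
#' topology of the hetero-octameric Mis18 core complex: six Yippee-like
#' globular domains stacked in a line in alpha-beta-alpha / alpha-beta-alpha
#' type order, two triple-helix bundles each holding the C-terminal helices
#' of two alpha-type and one beta-type subunit (one helix antiparallel), and
#' two bp1-type adaptor segments, one across each outer alpha/beta globule
#' interface. Each protein copy (4 alpha, 2 beta, 2 bp1) is one rigid
#' subunit carrying one chain: alpha and beta subunits own a globule plus a
#' helix, bp1 subunits a single short helix. Geometry is an idealised
#' coarse-grained stand-in (one CA bead per residue), not a structural
#' prediction.
#'
#' @name synthetic_fixtures
NULL

# ideal alpha-helical CA trace: rise 1.5 A/residue, 100 deg twist, 2.3 A
# helix radius; axis along +x (or -x when reversed), centred at `centre`
helix_trace <- function(n, centre, reverse = FALSE, rise = 1.5,
                        twist = 100, radius = 2.3) {
  i <- seq_len(n) - (n + 1) / 2
  if (reverse) i <- -i
  ang <- (seq_len(n) - 1) * twist * pi / 180
  cbind(centre[1] + i * rise,
        centre[2] + radius * cos(ang),
        centre[3] + radius * sin(ang))
}

# seeded blue-noise bead packing in a sphere (uses current RNG stream)
pack_globule <- function(n, centre, radius = 10, min_sep = 3.6,
                          max_iter = 20000L) {
  pts <- matrix(numeric(0), 0, 3)
  it <- 0L
  while (nrow(pts) < n && it < max_iter) {
    it <- it + 1L
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) > radius^2) next
    if (nrow(pts) && min(rowSums(sweep(pts, 2L, p)^2)) < min_sep^2) next
    pts <- rbind(pts, p)
  }
  if (nrow(pts) < n)
    stop("pack_globule: packing failed (", nrow(pts), "/", n, " beads)")
  sweep(pts, 2L, centre, "+")
}

beads_to_structure <- function(xyz, chain, id, resno_start = 1L) {
  n <- nrow(xyz)
  xl_structure(data.frame(
    chain = chain, resno = seq.int(resno_start, length.out = n),
    resid = "ALA", elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, stringsAsFactors = FALSE), id = id)
}

#' Build the Mis18-mimic ground-truth assembly
#'
#' @param seed integer seed; the construction is a pure function of
#'   `(seed, scale)`.
#' @param scale `"core"` (8 subunits: 4 alpha, 2 beta, 2 bp1) or `"full"`
#'   (core plus 4 short N-terminal-type helix rods with deliberately
#'   ambiguous contacts).
#' @param globule_beads beads per Yippee-like globule (default 45).
#' @param helix_residues residues per C-terminal helix rod (default 36).
#' @return List of class `xl_ground_truth`: `subunits` (named list of
#'   `xl_structure` in the assembled frame), `structure` (the combined
#'   assembly), `transforms` (true placement per subunit; identity, since
#'   subunits are emitted assembled), `manifest` (subunit/chain/type table),
#'   `edges` (designed adjacency, `"a--b"` labels), `chain_map`, `seed`,
#'   `scale`.
#' @export
make_mis18_mimic <- function(seed, scale = c("core", "full"),
                             globule_beads = 45L, helix_residues = 36L) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  nb <- globule_beads; nh <- helix_residues
  spacing <- 25; grad <- 10
  centres <- lapply(0:5, function(k) c(k * spacing, 0, 0))
  glob_owner <- c("alpha1", "beta1", "alpha2", "alpha3", "beta2", "alpha4")
  chains <- c(alpha1 = "A", beta1 = "B", alpha2 = "C", alpha3 = "D",
              beta2 = "E", alpha4 = "F", bp1a = "G", bp1b = "H")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    glob <- lapply(centres, function(ct) pack_globule(nb, ct, radius = grad))
  })
  names(glob) <- glob_owner
  # two triple-helix bundles above the globule line; the beta helix runs
  # antiparallel, matching the crystal-structure arrangement
  tri <- function(centre_x) list(
    a1 = c(centre_x, 29, 0), a2 = c(centre_x, 20, 5.2), b = c(centre_x, 20, -5.2))
  b1 <- tri(1.0 * spacing); b2 <- tri(4.0 * spacing)
  helices <- list(
    alpha1 = helix_trace(nh, b1$a1), alpha2 = helix_trace(nh, b1$a2),
    beta1 = helix_trace(nh, b1$b, reverse = TRUE),
    alpha3 = helix_trace(nh, b2$a1), alpha4 = helix_trace(nh, b2$a2),
    beta2 = helix_trace(nh, b2$b, reverse = TRUE))
  # bp1 adaptors across the outer alpha/beta globule interfaces, offset in z
  bp1 <- list(
    bp1a = helix_trace(22L, c(0.5 * spacing, 0, 17)),
    bp1b = helix_trace(22L, c(4.5 * spacing, 0, 17)))
  subunits <- list()
  manifest <- NULL
  for (s in c("alpha1", "beta1", "alpha2", "alpha3", "beta2", "alpha4")) {
    type <- if (startsWith(s, "alpha")) "alpha" else "beta"
    gs <- beads_to_structure(glob[[s]], chains[[s]], s)
    hs <- beads_to_structure(helices[[s]], chains[[s]], s, resno_start = 101L)
    subunits[[s]] <- xl_structure(rbind(gs$atoms, hs$atoms), id = s)
    manifest <- rbind(manifest,
                      data.frame(subunit = s, chain = chains[[s]],
                                 type = type, stringsAsFactors = FALSE))
  }
  for (s in c("bp1a", "bp1b")) {
    subunits[[s]] <- beads_to_structure(bp1[[s]], chains[[s]], s)
    manifest <- rbind(manifest,
                      data.frame(subunit = s, chain = chains[[s]],
                                 type = "bp1", stringsAsFactors = FALSE))
  }
  edges <- c("alpha1--beta1", "beta1--alpha2", "alpha2--alpha3",
             "alpha3--beta2", "beta2--alpha4",
             "alpha1--alpha2", "alpha3--alpha4",
             "bp1a--alpha1", "bp1a--beta1", "bp1b--beta2", "bp1b--alpha4")
  if (scale == "full") {
    # four short N-terminal-type rods with ambiguous multi-orientation
    # contacts: each touches one bundle and one Yippee globule
    nt_pos <- list(nterm1 = c(0, 25, 8), nterm2 = c(2 * spacing, 25, 8),
                   nterm3 = c(3 * spacing, 25, 8), nterm4 = c(5 * spacing, 25, 8))
    nt_chain <- c(nterm1 = "I", nterm2 = "J", nterm3 = "K", nterm4 = "L")
    for (s in names(nt_pos)) {
      subunits[[s]] <- beads_to_structure(helix_trace(18L, nt_pos[[s]]),
                                          nt_chain[[s]], s)
      manifest <- rbind(manifest,
                        data.frame(subunit = s, chain = nt_chain[[s]],
                                   type = "nterm", stringsAsFactors = FALSE))
    }
    chains <- c(chains, nt_chain)
    edges <- c(edges, "nterm1--alpha1", "nterm1--beta1",
               "nterm2--alpha2", "nterm2--alpha1",
               "nterm3--alpha3", "nterm3--beta2",
               "nterm4--alpha4", "nterm4--beta2")
  }
  edges <- vapply(strsplit(edges, "--", fixed = TRUE), function(p)
    paste(sort(p), collapse = "--"), character(1))
  truth <- list(
    subunits = subunits,
    structure = combine_structures(subunits, id = "mis18_mimic"),
    transforms = stats::setNames(
      replicate(length(subunits), rigid_transform(), simplify = FALSE),
      names(subunits)),
    manifest = manifest, edges = sort(edges),
    chain_map = as.list(chains[names(subunits)]),
    seed = as.integer(seed), scale = scale)
  class(truth) <- "xl_ground_truth"
  truth
}

#' @export
print.xl_ground_truth <- function(x, ...) {
  cat(sprintf("xl_ground_truth (%s, seed %d): %d subunits, %d designed contacts\n",
              x$scale, x$seed, length(x$subunits), length(x$edges)))
  print(table(x$manifest$type))
  invisible(x)
}

#' Simulate a cross-link set from a ground-truth assembly
#'
#' Per designed interface, rejection-samples residue pairs at distances the
#' cross-linking chemistry can actually bridge: EDC is a zero-length
#' carboxyl-amine coupler reporting tight contacts (assembled Calpha-Calpha
#' distance below `edc_max`), sulfo-SDA a short photoactivatable spacer
#' (below `sda_max`); both bounds sit inside the satisfaction threshold, so
#' every true link is satisfied in the ground truth. Decoy pairs (emulating
#' false-positive identifications) are added at distance at least
#' `decoy_min_distance` so that decoys make up `decoy_fraction` of the final
#' table. Rows are shuffled; true/decoy labels are returned in a sidecar
#' only.
#'
#' @param truth an `xl_ground_truth` from [make_mis18_mimic()].
#' @param links_per_interface true links sampled per designed edge.
#' @param decoy_fraction fraction of the emitted table that is decoys, in
#'   `[0, 1)`.
#' @param decoy_min_distance minimum assembled distance of a decoy pair
#'   (Angstrom, must exceed `threshold`).
#' @param threshold satisfaction cutoff (Angstrom).
#' @param edc_max,sda_max maximum assembled distance of a true EDC / sulfo-SDA
#'   link (Angstrom, at most `threshold`).
#' @param seed integer seed.
#' @return List: `links` (`xl_links`, shuffled), `labels` (data.frame with
#'   `is_decoy` aligned to `links`), `n_true`, `n_decoy`.
#' @export
simulate_crosslinks <- function(truth, links_per_interface = 8L,
                                decoy_fraction = 0.1,
                                decoy_min_distance = 35, threshold = 22,
                                edc_max = 12, sda_max = 18,
                                seed = truth$seed) {
  stopifnot(inherits(truth, "xl_ground_truth"),
            decoy_fraction >= 0, decoy_fraction < 1,
            decoy_min_distance > threshold,
            edc_max <= threshold, sda_max <= threshold)
  lookup <- ca_lookup(truth$structure)
  owner <- chain_owner(truth$subunits)
  key_sub <- owner[sub("\\|.*", "", lookup$key)]
  key_res <- as.integer(sub(".*\\|", "", lookup$key))
  pair_rows <- function(su, sv, dmin, dmax) {
    ia <- which(key_sub == su); ib <- which(key_sub == sv)
    xa <- lookup$xyz[ia, , drop = FALSE]; xb <- lookup$xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    hit <- which(d2 >= dmin^2 & d2 < dmax^2, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(protein_a = su, residue_a = key_res[ia[hit[, 1]]],
               protein_b = sv, residue_b = key_res[ib[hit[, 2]]],
               d = sqrt(pmax(d2[hit], 0)), stringsAsFactors = FALSE)
  }
  subs <- names(truth$subunits)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    true_rows <- NULL
    true_linker <- character(0)
    for (e in truth$edges) {
      uv <- strsplit(e, "--", fixed = TRUE)[[1]]
      # roughly even EDC / sulfo-SDA split per interface, each drawn from
      # the pair pool its chemistry can bridge
      n_edc <- links_per_interface %/% 2L
      n_sda <- links_per_interface - n_edc
      cand_sda <- pair_rows(uv[1], uv[2], 0, sda_max)
      if (is.null(cand_sda))
        stop("simulate_crosslinks: designed interface ", e,
             " has no residue pair under ", sda_max, " A")
      edc_idx <- which(cand_sda$d < edc_max)
      if (length(edc_idx) < n_edc) { n_sda <- n_sda + (n_edc - length(edc_idx))
                                     n_edc <- length(edc_idx) }
      take_edc <- if (n_edc) sample(edc_idx, n_edc) else integer(0)
      sda_pool <- setdiff(seq_len(nrow(cand_sda)), take_edc)
      take_sda <- sample(sda_pool, min(n_sda, length(sda_pool)))
      if (length(take_sda) < n_sda)
        warning("simulate_crosslinks: interface ", e, " yields only ",
                nrow(cand_sda), " candidate pairs")
      true_rows <- rbind(true_rows, cand_sda[c(take_edc, take_sda), ])
      true_linker <- c(true_linker, rep("EDC", length(take_edc)),
                       rep("SDA", length(take_sda)))
    }
    n_true <- nrow(true_rows)
    n_decoy <- round(n_true * decoy_fraction / (1 - decoy_fraction))
    decoy_rows <- NULL
    if (n_decoy > 0) {
      pool <- NULL
      pairs <- utils::combn(subs, 2)
      for (k in seq_len(ncol(pairs))) {
        cand <- pair_rows(pairs[1, k], pairs[2, k], decoy_min_distance, Inf)
        if (!is.null(cand))
          pool <- rbind(pool, cand[sample.int(nrow(cand),
                                              min(nrow(cand), 50L)), ])
      }
      decoy_rows <- pool[sample.int(nrow(pool), n_decoy), ]
    }
    rows <- rbind(true_rows, decoy_rows)
    n_dec <- if (is.null(decoy_rows)) 0L else nrow(decoy_rows)
    is_decoy <- c(rep(FALSE, n_true), rep(TRUE, n_dec))
    linker <- c(true_linker, sample(c("EDC", "SDA"), n_dec, replace = TRUE))
    perm <- sample.int(nrow(rows))
  })
  rows <- rows[perm, ]; is_decoy <- is_decoy[perm]; linker <- linker[perm]
  links <- crosslink_table(rows$protein_a, rows$residue_a,
                           rows$protein_b, rows$residue_b, linker = linker)
  list(links = links,
       labels = data.frame(protein_a = links$protein_a,
                           residue_a = links$residue_a,
                           protein_b = links$protein_b,
                           residue_b = links$residue_b,
                           is_decoy = is_decoy, stringsAsFactors = FALSE),
       n_true = sum(!is_decoy), n_decoy = sum(is_decoy))
}

#' Scramble subunits into a docking problem instance
#'
#' Applies an independent seeded random rotation (up to `perturb_rotation`
#' degrees) and translation (up to `perturb_translation` Angstrom, plus a
#' dispersal offset separating consecutive subunits by at least `dispersal`
#' Angstrom) to every subunit, recording the applied transforms so recovery
#' can be scored.
#'
#' @param truth an `xl_ground_truth`.
#' @param perturb_rotation maximum rotation angle in degrees (default 180:
#'   orientations fully scrambled).
#' @param perturb_translation maximum translation per axis (Angstrom).
#' @param dispersal spacing of the subunit line-up after scrambling
#'   (Angstrom; 0 keeps subunits in place).
#' @param seed integer seed.
#' @return List: `subunits` (named list of perturbed `xl_structure`),
#'   `applied` (named list of the `rigid_transform` applied to each).
#' @export
perturb_subunits <- function(truth, perturb_rotation = 180,
                             perturb_translation = 10, dispersal = 60,
                             seed = truth$seed) {
  stopifnot(inherits(truth, "xl_ground_truth"))
  subs <- names(truth$subunits)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    applied <- lapply(seq_along(subs), function(k) {
      R <- if (perturb_rotation > 0)
        rotation_about_axis(stats::rnorm(3),
                            stats::runif(1, 0, perturb_rotation))
      else diag(3)
      t <- if (perturb_translation > 0)
        stats::runif(3, -perturb_translation, perturb_translation)
      else c(0, 0, 0)
      t[1] <- t[1] + (k - 1) * dispersal
      rigid_transform(R, t)
    })
  })
  names(applied) <- subs
  out <- lapply(subs, function(s) apply_transform(truth$subunits[[s]],
                                                  applied[[s]]))
  names(out) <- subs
  list(subunits = out, applied = applied)
}

#' Simulate a noisy SAXS curve from a model
#'
#' Computes the Debye profile on a log-spaced q grid and adds seeded
#' Gaussian noise with `sigma = noise_scale * sqrt(I) * (1 + q / q_max)`.
#' With `noise_scale = 0` the noise-free profile is returned without
#' uncertainties.
#'
#' @param structure an `xl_structure`.
#' @param n_points number of q points.
#' @param q_min,q_max q range in 1/Angstrom.
#' @param noise_scale noise amplitude (0 = noise-free).
#' @param seed integer seed.
#' @return A [saxs_curve()].
#' @export
simulate_saxs_curve <- function(structure, n_points = 500L, q_min = 0.005,
                                q_max = 0.3, noise_scale = 0.5, seed = 1L) {
  q <- exp(seq(log(q_min), log(q_max), length.out = n_points))
  prof <- debye_profile(structure, q)
  if (noise_scale == 0) return(prof)
  sigma <- noise_scale * sqrt(pmax(prof$I, 0)) * (1 + q / q_max)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    noise <- stats::rnorm(n_points, 0, sigma)
  })
  saxs_curve(q, prof$I + noise, sigma)
}

#' Write a generated fixture to disk
#'
#' Emits subunit PDB files, `links.csv`, `chain_map.json`, `manifest.csv`
#' (type tags) and `labels.csv` (true/decoy sidecar) under `dir`.
#'
#' @param truth an `xl_ground_truth`.
#' @param sim result of [simulate_crosslinks()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(truth$subunits))
    write_structure(truth$subunits[[s]], file.path(dir, paste0(s, ".pdb")))
  write_crosslinks(sim$links, file.path(dir, "links.csv"))
  jsonlite::write_json(truth$chain_map, file.path(dir, "chain_map.json"))
  utils::write.csv(truth$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
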