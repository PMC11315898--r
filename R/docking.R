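#' Docking parameters
#'
#' Parameters of cross-link-restrained rigid-body pairwise docking. The
#' retention rule is strict: a configuration survives only when its satisfied
#' fraction strictly exceeds `retention_fraction` (default 0.7, i.e. >70%).
#'
#' @param rotation_step rotation-grid resolution in degrees, in (0, 90].
#' @param retention_fraction minimum satisfied fraction (strict), in (0, 1].
#' @param clash_distance Calpha-Calpha clash cutoff in Angstrom.
#' @param max_clashes maximum tolerated clash count per configuration.
#' @param top_k maximum number of configurations returned.
#' @param refine run deterministic local coordinate-descent refinement.
#' @param threshold cross-link satisfaction cutoff in Angstrom.
#' @param clash_penalty score penalty per clash.
#' @param min_links minimum mappable inter-subunit links required.
#' @param cluster_translation pose-deduplication radius (Calpha RMSD, Angstrom).
#' @param linker_bounds named soft distance bounds (Angstrom) per linker
#'   chemistry, used only as refinement targets (EDC is a zero-length
#'   coupler, sulfo-SDA a short spacer); satisfaction always uses the single
#'   `threshold` rule.
#' @param contact_weight,contact_distance,contact_cap refinement-only capped
#'   reward for inter-subunit Calpha contacts under `contact_distance`
#'   Angstrom: a transparent stand-in for the shape complementarity that
#'   surface-matching docking engines enforce; never enters the reported
#'   configuration score.
#' @return A list of class `docking_params`.
#' @export
docking_params <- function(rotation_step = 15, retention_fraction = 0.7,
                           clash_distance = 4, max_clashes = 5, top_k = 200,
                           refine = TRUE, threshold = 22, clash_penalty = 0.02,
                           min_links = 2, cluster_translation = 3,
                           linker_bounds = c(EDC = 12, SDA = 18),
                           contact_weight = 2e-4, contact_distance = 6,
                           contact_cap = 40L) {
  if (rotation_step <= 0 || rotation_step > 90)
    stop("docking_params: rotation_step must be in (0, 90]")
  if (retention_fraction <= 0 || retention_fraction > 1)
    stop("docking_params: retention_fraction must be in (0, 1]")
  p <- list(rotation_step = rotation_step,
            retention_fraction = retention_fraction,
            clash_distance = clash_distance, max_clashes = max_clashes,
            top_k = top_k, refine = refine, threshold = threshold,
            clash_penalty = clash_penalty, min_links = min_links,
            cluster_translation = cluster_translation,
            linker_bounds = linker_bounds,
            contact_weight = contact_weight,
            contact_distance = contact_distance,
            contact_cap = as.integer(contact_cap))
  class(p) <- "docking_params"
  p
}

#' Deterministic rotation grid
#'
#' Quasi-uniform cover of rotation space by super-Fibonacci quaternion
#' spirals, sized so that every rotation lies within `step` geodesic degrees
#' of some grid member; the identity is always included.
#'
#' @param step covering radius in degrees, in (0, 90].
#' @return List of 3x3 rotation matrices with attribute `step`.
#' @export
rotation_grid <- function(step) {
  if (!is.numeric(step) || step <= 0 || step > 90)
    stop("rotation_grid: step must be in (0, 90] degrees")
  # covering radius of an n-point super-Fibonacci grid is ~225/n^(1/3) deg;
  # the 250 constant gives margin
  n <- max(4L, as.integer(ceiling((250 / step)^3)))
  i <- seq_len(n) - 1
  s <- i + 0.5; t <- s / n; d <- 2 * pi * s
  r <- sqrt(t); R <- sqrt(1 - t)
  phi <- sqrt(2); psi <- 1.533751168755204288118041
  a <- d / phi; b <- d / psi
  quats <- cbind(r * sin(a), r * cos(a), R * sin(b), R * cos(b))
  # put the quaternion scalar first: (w, x, y, z)
  mats <- lapply(seq_len(n), function(k)
    quat_to_matrix(c(quats[k, 4], quats[k, 1], quats[k, 2], quats[k, 3])))
  ang <- vapply(mats, rotation_angle, numeric(1))
  grid <- c(list(diag(3)), mats[ang > 1e-6])
  attr(grid, "step") <- step
  grid
}

# restraint anchors for an A-B pair: all copy combinations per inter link.
# returns NULL-free matrices a, b (combos x 3), combo -> link grouping, and
# the count of usable inter-subunit links.
pair_anchors <- function(A, B, links, chain_map) {
  la <- ca_lookup(A); lb <- ca_lookup(B)
  chains_a <- unique(A$atoms$chain); chains_b <- unique(B$atoms$chain)
  amat <- NULL; bmat <- NULL; gid <- integer(0)
  lnk <- character(0)
  nl <- 0L
  for (i in seq_len(nrow(links))) {
    lk <- links[i, ]
    for (p in c(lk$protein_a, lk$protein_b))
      if (is.null(chain_map[[p]]))
        stop("pair_anchors: protein '", p, "' absent from chain map")
    ca1 <- copy_coords(la, intersect(chain_map[[lk$protein_a]], chains_a),
                       lk$residue_a)
    cb1 <- copy_coords(lb, intersect(chain_map[[lk$protein_b]], chains_b),
                       lk$residue_b)
    ca2 <- copy_coords(la, intersect(chain_map[[lk$protein_b]], chains_a),
                       lk$residue_b)
    cb2 <- copy_coords(lb, intersect(chain_map[[lk$protein_a]], chains_b),
                       lk$residue_a)
    side_a <- NULL; side_b <- NULL
    if (!is.null(ca1) && !is.null(cb1)) { side_a <- ca1$xyz; side_b <- cb1$xyz }
    else if (!is.null(ca2) && !is.null(cb2)) { side_a <- ca2$xyz; side_b <- cb2$xyz }
    if (is.null(side_a)) next
    nl <- nl + 1L
    lnk <- c(lnk, lk$linker)
    combos <- expand.grid(seq_len(nrow(side_a)), seq_len(nrow(side_b)))
    amat <- rbind(amat, side_a[combos[, 1], , drop = FALSE])
    bmat <- rbind(bmat, side_b[combos[, 2], , drop = FALSE])
    gid <- c(gid, rep.int(nl, nrow(combos)))
  }
  if (!nl) return(NULL)
  group <- split(seq_along(gid), gid)
  list(a = amat, b = bmat, group = group, gid = gid, linker = lnk,
       first = vapply(group, `[`, integer(1), 1L), n_links = nl)
}

# per-link soft hinge bound from linker chemistry, capped at threshold - 2
hinge_bounds <- function(linker, params) {
  hb <- rep(params$threshold - 2, length(linker))
  bl <- params$linker_bounds
  if (length(bl) && !is.null(names(bl))) {
    hit <- match(linker, names(bl))
    hb[!is.na(hit)] <- bl[hit[!is.na(hit)]]
  }
  pmin(hb, params$threshold - 2)
}

# restraint evaluation for a placement of B: per-link min distances
anchor_distances <- function(anchors, R, t) {
  bt <- sweep(anchors$b %*% t(R), 2L, t, "+")
  d <- sqrt(rowSums((anchors$a - bt)^2))
  vapply(anchors$group, function(ix) min(d[ix]), numeric(1))
}

# scan of a whole rotation grid: for every rotation, the closed-form
# restraint-optimal translation, satisfied fraction and restraint score
# (compiled kernel)
scan_rotations <- function(anchors, grid, threshold, hb) {
  grid_flat <- vapply(grid, as.numeric, numeric(9))
  .scan_rotations_cpp(anchors$a, anchors$b, anchors$gid - 1L,
                      length(anchors$group), anchors$first - 1L,
                      grid_flat, threshold, hb)
}

# restraint score: satisfied fraction plus a small hinge term so local
# refinement can make progress between threshold crossings; cross-links are
# upper bounds, so distances below the threshold are never rewarded further
restraint_score <- function(dl, threshold, hb = threshold - 2) {
  mean(dl < threshold) - 1e-3 * mean(pmax(dl - hb, 0))
}

#' Closed-form restraint-optimal translation
#'
#' For a fixed rotation of subunit B, the translation minimising the mean
#' squared Calpha-Calpha restraint distance is the mean of the per-link
#' offset vectors from the rotated B anchor to the A anchor.
#'
#' @param A,B `xl_structure` subunits (A fixed, B mobile).
#' @param rotation 3x3 rotation applied to B.
#' @param links an `xl_links` table.
#' @param chain_map named list protein -> chain ids.
#' @return Length-3 translation vector (Angstrom).
#' @export
optimal_translation <- function(A, B, rotation, links, chain_map) {
  anchors <- pair_anchors(A, B, links, chain_map)
  if (is.null(anchors))
    stop("optimal_translation: no mappable links between the subunits")
  first <- vapply(anchors$group, `[`, integer(1), 1L)
  a1 <- anchors$a[first, , drop = FALSE]
  b1 <- anchors$b[first, , drop = FALSE]
  unname(colMeans(a1 - b1 %*% t(rotation)))
}

#' Count inter-subunit steric clashes
#'
#' Number of Calpha pairs between two placed subunits closer than
#' `clash_distance`. The default spatial-grid (cell list) method is
#' near-linear in atom count; `method = "brute"` is the exhaustive
#' double-loop reference.
#'
#' @param A,B_placed `xl_structure` objects in a common frame.
#' @param clash_distance cutoff in Angstrom (strict `<`).
#' @param method "grid" or "brute".
#' @return Integer clash count.
#' @export
clash_count <- function(A, B_placed, clash_distance = 4,
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  pa <- ca_coords(A)$xyz
  pb <- ca_coords(B_placed)$xyz
  if (!nrow(pa) || !nrow(pb)) stop("clash_count: empty structure")
  if (method == "brute") return(clash_count_brute(pa, pb, clash_distance))
  clash_count_grid(pa, pb, clash_distance)
}

clash_count_brute <- function(pa, pb, cd) {
  .clash_count_cpp(pa, pb, cd)
}

clash_count_grid <- function(pa, pb, cd) {
  ia <- floor(pa / cd)
  cells <- split(seq_len(nrow(pa)), paste(ia[, 1], ia[, 2], ia[, 3]))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ib <- floor(pb / cd)
  cd2 <- cd^2 - 1e-12
  n <- 0L
  for (j in seq_len(nrow(pb))) {
    nb <- sweep(offs, 2L, ib[j, ], "+")
    cand <- unlist(cells[paste(nb[, 1], nb[, 2], nb[, 3])], use.names = FALSE)
    if (length(cand)) {
      dx <- sweep(pa[cand, , drop = FALSE], 2L, pb[j, ])
      n <- n + sum(rowSums(dx^2) < cd2)
    }
  }
  n
}

# deterministic local refinement: greedy coordinate descent over small
# body-centred rotation tweaks and axis translations, scored by restraint
# satisfaction minus the lazily evaluated clash penalty so poses relax out
# of steric overlap (compiled kernel; receptor atoms beyond the bounded
# refinement reach are dropped before the call)
refine_pose <- function(anchors, R, t, step, params, aca, bca) {
  bcen <- colMeans(bca)
  bcen0 <- as.numeric(R %*% bcen) + t
  r_b <- sqrt(max(rowSums(sweep(bca, 2L, bcen)^2)))
  reach2 <- (r_b + params$clash_distance + 30)^2
  aca <- aca[rowSums(sweep(aca, 2L, bcen0)^2) < reach2, , drop = FALSE]
  .refine_pose_cpp(anchors$a, anchors$b, anchors$gid - 1L,
                   length(anchors$group), R, t, step, params$threshold,
                   anchors$hb, params$clash_penalty, params$clash_distance,
                   params$contact_weight %||% 2e-4,
                   params$contact_distance %||% 6,
                   as.integer(params$contact_cap %||% 40L),
                   aca, bca, 3L)
}

#' Cross-link-restrained pairwise docking
#'
#' Enumerates a deterministic rotation grid, places mobile subunit B by the
#' closed-form restraint-optimal translation for each rotation, optionally
#' refines locally, and returns the clash-filtered configurations whose
#' satisfied fraction strictly exceeds the retention fraction, ranked by
#' score (satisfied fraction minus a clash penalty). Fully deterministic.
#'
#' @param A fixed receptor `xl_structure`.
#' @param B mobile ligand `xl_structure`.
#' @param links an `xl_links` table.
#' @param chain_map named list protein -> chain ids.
#' @param params a [docking_params()] list.
#' @return List of class `xl_dockings`: each element has `transform` (B -> A
#'   frame), `fraction_satisfied`, `clash_count`, `score`. Empty (with a
#'   message) when nothing passes retention.
#' @export
dock_pair <- function(A, B, links, chain_map, params = docking_params()) {
  stopifnot(is_xl_structure(A), is_xl_structure(B))
  anchors <- pair_anchors(A, B, links, chain_map)
  if (is.null(anchors) || anchors$n_links < params$min_links)
    stop("dock_pair: need at least ", params$min_links,
         " mappable inter-subunit links (found ",
         if (is.null(anchors)) 0L else anchors$n_links, ")")
  grid <- rotation_grid(params$rotation_step)
  anchors$hb <- hinge_bounds(anchors$linker, params)
  scan <- scan_rotations(anchors, grid, params$threshold, anchors$hb)
  keep <- utils::head(order(scan$score, decreasing = TRUE),
                      max(2L * params$top_k, 100L))
  cand <- lapply(keep, function(k)
    list(R = grid[[k]], t = scan$translations[k, ],
         frac = scan$frac[k], score = scan$score[k]))
  bca <- ca_coords(B)$xyz
  aca <- ca_coords(A)$xyz
  if (isTRUE(params$refine)) {
    cand <- lapply(cand, function(cf) {
      r <- refine_pose(anchors, cf$R, cf$t, params$rotation_step, params,
                       aca, bca)
      dl <- anchor_distances(anchors, r$R, r$t)
      list(R = r$R, t = r$t, frac = mean(dl < params$threshold),
           score = r$score)
    })
  }
  # retention (strict) and clash filters
  out <- list()
  placed_ca <- list()
  for (cf in cand[order(vapply(cand, `[[`, numeric(1), "score"),
                        decreasing = TRUE)]) {
    if (cf$frac <= params$retention_fraction) next
    bplaced <- sweep(bca %*% t(cf$R), 2L, cf$t, "+")
    # pose deduplication: skip near-duplicates of an already accepted pose
    dup <- FALSE
    for (pc in placed_ca) {
      if (sqrt(mean(rowSums((bplaced - pc)^2))) < params$cluster_translation) {
        dup <- TRUE; break
      }
    }
    if (dup) next
    ncl <- clash_count_brute(aca, bplaced, params$clash_distance)
    if (ncl > params$max_clashes) next
    out[[length(out) + 1L]] <- list(
      transform = rigid_transform(cf$R, cf$t),
      fraction_satisfied = cf$frac, clash_count = ncl,
      score = cf$frac - params$clash_penalty * ncl)
    placed_ca[[length(placed_ca) + 1L]] <- bplaced
    if (length(out) >= params$top_k) break
  }
  if (!length(out))
    message("dock_pair: no configuration exceeds retention ",
            params$retention_fraction)
  ord <- order(-vapply(out, `[[`, numeric(1), "score"),
               vapply(out, `[[`, integer(1), "clash_count"),
               vapply(out, function(x) transform_key(x$transform), character(1)))
  out <- out[ord]
  class(out) <- "xl_dockings"
  out
}

#' @export
print.xl_dockings <- function(x, ...) {
  cat("xl_dockings:", length(x), "configurations\n")
  for (i in seq_len(min(5L, length(x))))
    cat(sprintf("  #%d score %.3f  satisfied %.2f  clashes %d\n", i,
                x[[i]]$score, x[[i]]$fraction_satisfied, x[[i]]$clash_count))
  invisible(x)
}

#' Serialise docking configurations to JSON
#' @param configs an `xl_dockings` list.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_dockings <- function(configs, path) {
  payload <- lapply(configs, function(cf) list(
    rotation = as.numeric(t(cf$transform$R)),  # row-major
    translation = cf$transform$t,
    fraction_satisfied = cf$fraction_satisfied,
    clash_count = cf$clash_count, score = cf$score))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
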