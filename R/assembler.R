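#' Assembly parameters
#'
#' @param beam_width beam width of the hierarchical search.
#' @param per_pair_configs pairwise docking configurations kept per edge.
#' @param clash_distance Calpha clash cutoff in Angstrom.
#' @param max_total_clashes clash budget for a whole (partial) assembly.
#' @param cluster_rmsd all-Calpha RMSD radius for final clustering (Angstrom).
#' @param retention_fraction strict lower bound on the satisfied fraction of
#'   currently-mappable links during assembly (default 0.7).
#' @param clash_penalty score penalty per clash.
#' @param docking a [docking_params()] list used for the per-edge docking.
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(beam_width = 50, per_pair_configs = 50,
                            clash_distance = 4, max_total_clashes = 20,
                            cluster_rmsd = 5, retention_fraction = 0.7,
                            clash_penalty = 0.02,
                            docking = docking_params()) {
  stopifnot(beam_width >= 1, cluster_rmsd > 0, per_pair_configs >= 1)
  docking$clash_distance <- clash_distance
  p <- list(beam_width = as.integer(beam_width),
            per_pair_configs = as.integer(per_pair_configs),
            clash_distance = clash_distance,
            max_total_clashes = as.integer(max_total_clashes),
            cluster_rmsd = cluster_rmsd,
            retention_fraction = retention_fraction,
            clash_penalty = clash_penalty, docking = docking)
  class(p) <- "assembly_params"
  p
}

# map each chain id to the subunit holding it
chain_owner <- function(subunits) {
  owner <- character(0)
  for (s in names(subunits)) {
    ch <- unique(subunits[[s]]$atoms$chain)
    dup <- intersect(ch, names(owner))
    if (length(dup))
      stop("assemble: chain id(s) shared by several subunits: ",
           paste(dup, collapse = ", "))
    owner[ch] <- s
  }
  owner
}

# per-link anchor combinations resolved to (subunit, local CA coordinate)
link_combos <- function(subunits, links, chain_map, owner) {
  lookups <- lapply(subunits, ca_lookup)
  resolve <- function(protein, resno) {
    chains <- chain_map[[protein]]
    if (is.null(chains))
      stop("assemble: protein '", protein, "' absent from chain map")
    out <- list()
    for (ch in chains) {
      s <- owner[[ch]]
      if (is.null(s)) next
      hit <- match(paste(ch, resno, sep = "|"), lookups[[s]]$key)
      if (!is.na(hit))
        out[[length(out) + 1L]] <- list(sub = s,
                                        xyz = lookups[[s]]$xyz[hit, ])
    }
    out
  }
  lapply(seq_len(nrow(links)), function(i) {
    ea <- resolve(links$protein_a[i], links$residue_a[i])
    eb <- resolve(links$protein_b[i], links$residue_b[i])
    if (!length(ea) || !length(eb)) return(NULL)
    combos <- expand.grid(a = seq_along(ea), b = seq_along(eb))
    list(sub_a = vapply(ea, `[[`, character(1), "sub")[combos$a],
         xa = do.call(rbind, lapply(ea, `[[`, "xyz"))[combos$a, , drop = FALSE],
         sub_b = vapply(eb, `[[`, character(1), "sub")[combos$b],
         xb = do.call(rbind, lapply(eb, `[[`, "xyz"))[combos$b, , drop = FALSE])
  })
}

# flatten per-link combos into parallel matrices for fast partial scoring;
# drops the degenerate pairing of a residue with itself on the same copy
flatten_combos <- function(combos) {
  XA <- NULL; XB <- NULL; SA <- character(0); SB <- character(0)
  LID <- integer(0)
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    if (is.null(cb)) next
    keep <- !(cb$sub_a == cb$sub_b &
              rowSums((cb$xa - cb$xb)^2) < 1e-12)
    if (!any(keep)) next
    XA <- rbind(XA, cb$xa[keep, , drop = FALSE])
    XB <- rbind(XB, cb$xb[keep, , drop = FALSE])
    SA <- c(SA, cb$sub_a[keep]); SB <- c(SB, cb$sub_b[keep])
    LID <- c(LID, rep.int(i, sum(keep)))
  }
  list(XA = XA, XB = XB, SA = SA, SB = SB, LID = LID)
}

# total pairwise Calpha clash count of a placed subunit set
assembly_clashes <- function(placements, local_ca, clash_distance) {
  subs <- names(placements)
  glob <- lapply(subs, function(s) rt_apply(placements[[s]], local_ca[[s]]))
  n <- 0L
  if (length(subs) < 2L) return(n)
  for (i in seq_len(length(subs) - 1L)) for (j in seq((i + 1L), length(subs)))
    n <- n + clash_count_brute(glob[[i]], glob[[j]], clash_distance)
  n
}

# anchors of subunit v against the placed set: v-side coordinates in v's
# local frame, partner anchors fixed in the global frame
build_context_anchors <- function(v, placements, flat) {
  placed <- setdiff(names(placements), v)
  ia <- flat$SA == v & flat$SB %in% placed
  ib <- flat$SB == v & flat$SA %in% placed
  if (!any(ia) && !any(ib)) return(NULL)
  bloc <- rbind(flat$XA[ia, , drop = FALSE], flat$XB[ib, , drop = FALSE])
  afix <- rbind(flat$XB[ia, , drop = FALSE], flat$XA[ib, , drop = FALSE])
  asub <- c(flat$SB[ia], flat$SA[ib])
  lid <- c(flat$LID[ia], flat$LID[ib])
  for (s in unique(asub)) {
    k <- asub == s
    afix[k, ] <- rt_apply(placements[[s]], afix[k, , drop = FALSE])
  }
  gid <- as.integer(factor(lid))
  group <- split(seq_along(gid), gid)
  list(a = afix, b = bloc, group = group, gid = gid,
       linker = flat$linker[as.integer(levels(factor(lid)))],
       first = vapply(group, `[`, integer(1), 1L))
}

# refine the placement of one subunit against every link it shares with the
# already-placed set (deterministic coordinate descent, clash-aware)
refine_in_context <- function(v, placements, flat, local_ca, step, threshold,
                              clash_penalty, clash_distance,
                              linker_bounds = c(EDC = 12, SDA = 18)) {
  anchors <- build_context_anchors(v, placements, flat)
  if (is.null(anchors)) return(placements[[v]])
  placed <- setdiff(names(placements), v)
  aca <- do.call(rbind, lapply(placed, function(s)
    rt_apply(placements[[s]], local_ca[[s]])))
  pr <- list(threshold = threshold, clash_penalty = clash_penalty,
             clash_distance = clash_distance, linker_bounds = linker_bounds)
  anchors$hb <- hinge_bounds(anchors$linker, pr)
  Tv <- placements[[v]]
  r <- refine_pose(anchors, Tv$R, Tv$t, step, pr, aca, local_ca[[v]])
  rigid_transform(r$R, r$t)
}

# re-dock one subunit against the whole placed assembly: full rotation-grid
# scan with every context link as a restraint, then clash-aware refinement
# of the best distinct poses; returns the best placement found (including
# the incumbent, so the result never degrades)
context_redock <- function(v, placements, flat, local_ca, grid, step,
                           threshold, clash_penalty, clash_distance,
                           linker_bounds = c(EDC = 12, SDA = 18),
                           n_refine = 6L) {
  anchors <- build_context_anchors(v, placements, flat)
  if (is.null(anchors)) return(placements[[v]])
  placed <- setdiff(names(placements), v)
  aca <- do.call(rbind, lapply(placed, function(s)
    rt_apply(placements[[s]], local_ca[[s]])))
  bca <- local_ca[[v]]
  pr <- list(threshold = threshold, clash_penalty = clash_penalty,
             clash_distance = clash_distance, linker_bounds = linker_bounds)
  anchors$hb <- hinge_bounds(anchors$linker, pr)
  objective <- function(R, t) {
    restraint_score(anchor_distances(anchors, R, t), threshold, anchors$hb) -
      clash_penalty * clash_count_brute(
        aca, sweep(bca %*% t(R), 2L, t, "+"), clash_distance)
  }
  scan <- scan_rotations(anchors, grid, threshold, anchors$hb)
  cand <- utils::head(order(scan$score, decreasing = TRUE), n_refine)
  Tv <- placements[[v]]
  best_R <- Tv$R; best_t <- Tv$t
  best <- objective(best_R, best_t)
  starts <- c(list(list(R = Tv$R, t = Tv$t)),
              lapply(cand, function(k)
                list(R = grid[[k]], t = scan$translations[k, ])))
  for (st in starts) {
    r <- refine_pose(anchors, st$R, st$t, step, pr, aca, bca)
    if (r$score > best + 1e-12) { best <- r$score; best_R <- r$R; best_t <- r$t }
  }
  rigid_transform(best_R, best_t)
}

# satisfied fraction over links mappable within the placed subunit set
partial_fraction <- function(flat, placements, threshold) {
  placed <- names(placements)
  ok <- flat$SA %in% placed & flat$SB %in% placed
  if (!any(ok)) return(list(fraction = 1, n_mappable = 0L, n_satisfied = 0L))
  XA <- flat$XA[ok, , drop = FALSE]; XB <- flat$XB[ok, , drop = FALSE]
  SA <- flat$SA[ok]; SB <- flat$SB[ok]; LID <- flat$LID[ok]
  PA <- XA; PB <- XB
  for (s in placed) {
    ia <- SA == s
    if (any(ia)) PA[ia, ] <- rt_apply(placements[[s]], XA[ia, , drop = FALSE])
    ib <- SB == s
    if (any(ib)) PB[ib, ] <- rt_apply(placements[[s]], XB[ib, , drop = FALSE])
  }
  d <- sqrt(rowSums((PA - PB)^2))
  dmin <- tapply(d, LID, min)
  n_map <- length(dmin)
  n_sat <- sum(dmin < threshold)
  list(fraction = n_sat / n_map, n_mappable = n_map, n_satisfied = n_sat,
       hinge = mean(pmax(dmin - (threshold - 2), 0)))
}

#' Hierarchical combinatorial assembly from pairwise dockings
#'
#' Builds a connectivity graph whose edges are subunit pairs sharing at
#' least `min_links` cross-links, docks every edge of a maximum-link-support
#' spanning tree, and beam-searches over join orders, composing pairwise
#' transforms into N-subunit placements. Partial assemblies are pruned when
#' their satisfied fraction over currently-mappable links does not strictly
#' exceed the retention fraction or their clash count exceeds the budget.
#' Non-tree edges act as validation constraints: their links enter every
#' partial and global score but are never used as join moves. Final
#' assemblies are rescored from scratch and deduplicated by RMSD clustering.
#' Deterministic given inputs and parameters.
#'
#' @param subunits named list of `xl_structure` objects (chain ids unique
#'   across subunits).
#' @param links an `xl_links` table.
#' @param chain_map named list protein -> chain ids.
#' @param params an [assembly_params()] list.
#' @param threshold cross-link satisfaction cutoff in Angstrom.
#' @return List of class `xl_assemblies` of `xl_assembly` objects ranked by
#'   score, each with `placements` (named [rigid_transform()] per subunit,
#'   first subunit at identity), `global_fraction_satisfied`,
#'   `total_clashes`, `score` and `provenance`.
#' @export
assemble <- function(subunits, links, chain_map, params = assembly_params(),
                     threshold = 22) {
  stopifnot(length(subunits) >= 2L, nrow(links) >= 1L)
  if (is.null(names(subunits)) || any(!nzchar(names(subunits))))
    stop("assemble: subunits must be named")
  owner <- chain_owner(subunits)
  combos <- link_combos(subunits, links, chain_map, owner)
  flat <- flatten_combos(combos)
  flat$linker <- links$linker
  # link support per subunit pair
  pair_count <- list()
  for (cb in combos) {
    if (is.null(cb)) next
    prs <- unique(paste(pmin(cb$sub_a, cb$sub_b), pmax(cb$sub_a, cb$sub_b),
                        sep = "\r"))
    prs <- prs[sub("\r.*", "", prs) != sub(".*\r", "", prs)]
    for (p in prs) pair_count[[p]] <- (pair_count[[p]] %||% 0L) + 1L
  }
  edges <- data.frame(
    a = sub("\r.*", "", names(pair_count)),
    b = sub(".*\r", "", names(pair_count)),
    n = unlist(pair_count), stringsAsFactors = FALSE)
  edges <- edges[edges$n >= params$docking$min_links, , drop = FALSE]
  edges <- edges[order(-edges$n, edges$a, edges$b), , drop = FALSE]
  # connectivity check
  comp <- connected_components(names(subunits), edges)
  if (length(unique(comp)) > 1L) {
    parts <- split(names(comp), comp)
    stop("assemble: link graph is disconnected; components: ",
         paste(vapply(parts, paste, character(1), collapse = "+"),
               collapse = " | "))
  }
  # spanning tree (Kruskal over edges pre-sorted by support)
  tree <- spanning_tree(names(subunits), edges)
  # join order: grow from the strongest edge, strongest available first
  anchor_sub <- tree$a[1]
  placed_set <- anchor_sub
  join_order <- integer(0)
  remaining <- seq_len(nrow(tree))
  while (length(remaining)) {
    touch <- which(tree$a[remaining] %in% placed_set |
                   tree$b[remaining] %in% placed_set)
    k <- remaining[touch[1]]
    join_order <- c(join_order, k)
    placed_set <- union(placed_set, c(tree$a[k], tree$b[k]))
    remaining <- setdiff(remaining, k)
  }
  # pairwise docking per tree edge, receptor = the end placed first
  local_ca <- lapply(subunits, function(s) ca_coords(s)$xyz)
  dockings <- vector("list", nrow(tree))
  placed_set <- anchor_sub
  edge_dir <- character(nrow(tree))
  pp <- params$docking
  pp$top_k <- params$per_pair_configs
  for (k in join_order) {
    u <- if (tree$a[k] %in% placed_set) tree$a[k] else tree$b[k]
    v <- setdiff(c(tree$a[k], tree$b[k]), u)
    cfgs <- dock_pair(subunits[[u]], subunits[[v]], links, chain_map, pp)
    dockings[[k]] <- cfgs
    edge_dir[k] <- paste(u, v, sep = "\r")
    placed_set <- union(placed_set, v)
  }
  # beam search over configuration choices along the join order
  grid <- rotation_grid(params$docking$rotation_step)
  pr <- list(threshold = threshold, clash_penalty = params$clash_penalty,
             clash_distance = params$clash_distance,
             linker_bounds = params$docking$linker_bounds)
  beam <- list(list(placements = stats::setNames(list(rigid_transform()),
                                                 anchor_sub),
                    clashes = 0L, provenance = character(0),
                    placed_ca = local_ca[[anchor_sub]]))
  prune_note <- NULL
  for (k in join_order) {
    u <- sub("\r.*", "", edge_dir[k]); v <- sub(".*\r", "", edge_dir[k])
    cfgs <- dockings[[k]]
    if (!length(cfgs)) {
      prune_note <- sprintf("edge %s-%s produced no docking configuration", u, v)
      beam <- list(); break
    }
    nxt <- list()
    for (st in beam) {
      # candidate placements: composed pairwise configurations, plus poses
      # from re-docking v against the whole partial assembly (all context
      # links, including non-tree validation edges)
      cand <- lapply(seq_along(cfgs), function(ci) list(
        Tv = rt_compose(st$placements[[u]], cfgs[[ci]]$transform),
        tag = as.character(ci)))
      ctxa <- build_context_anchors(v, st$placements, flat)
      if (!is.null(ctxa)) {
        ctxa$hb <- hinge_bounds(ctxa$linker, pr)
        scan <- scan_rotations(ctxa, grid, threshold, ctxa$hb)
        top <- utils::head(order(scan$score, decreasing = TRUE), 8L)
        for (j in seq_along(top)) {
          kk <- top[j]
          r <- refine_pose(ctxa, grid[[kk]], scan$translations[kk, ],
                           params$docking$rotation_step, pr,
                           st$placed_ca, local_ca[[v]])
          cand[[length(cand) + 1L]] <- list(
            Tv = rigid_transform(r$R, r$t), tag = paste0("ctx", j))
        }
      }
      seen_cen <- NULL
      vcen <- colMeans(local_ca[[v]])
      for (cf in cand) {
        Tv <- cf$Tv
        # drop near-duplicate candidate placements (same pose basin)
        cen <- rt_apply(Tv, vcen)
        if (!is.null(seen_cen)) {
          close <- which(rowSums(sweep(seen_cen[, 1:3, drop = FALSE], 2L,
                                       cen)^2) < 4)
          if (length(close) &&
              any(vapply(close, function(i)
                rotation_distance(matrix(seen_cen[i, 4:12], 3, 3), Tv$R) < 8,
                logical(1)))) next
        }
        seen_cen <- rbind(seen_cen, c(cen, as.numeric(Tv$R)))
        vca <- rt_apply(Tv, local_ca[[v]])
        ncl <- st$clashes +
          clash_count_brute(st$placed_ca, vca, params$clash_distance)
        if (ncl > params$max_total_clashes) next
        pl <- st$placements
        pl[[v]] <- Tv
        pf <- partial_fraction(flat, pl, threshold)
        if (pf$n_mappable > 0L && pf$fraction <= params$retention_fraction)
          next
        nxt[[length(nxt) + 1L]] <- list(
          placements = pl, clashes = ncl,
          fraction = pf$fraction, hinge = pf$hinge,
          provenance = c(st$provenance,
                         stats::setNames(cf$tag, paste(u, v, sep = "-"))),
          placed_ca = rbind(st$placed_ca, vca))
      }
    }
    if (!length(nxt)) {
      prune_note <- sprintf(
        "all partial assemblies pruned at edge %s-%s (retention %.2f, clash budget %d)",
        u, v, params$retention_fraction, params$max_total_clashes)
      beam <- list(); break
    }
    # hinge tiebreak mirrors the docking score: among equal-fraction partials
    # prefer those whose violated links are closest to the threshold
    sc <- vapply(nxt, function(s) s$fraction - params$clash_penalty * s$clashes -
                   1e-3 * s$hinge, numeric(1))
    key <- vapply(nxt, function(s) paste(s$provenance, collapse = ","),
                  character(1))
    beam <- nxt[utils::head(order(-sc, key), params$beam_width)]
    # contextual refinement: the new subunit sees every link to the placed
    # set, correcting pairwise drift
    beam <- lapply(beam, function(st) {
      st$placements[[v]] <- refine_in_context(
        v, st$placements, flat, local_ca, params$docking$rotation_step,
        threshold, params$clash_penalty, params$clash_distance,
        params$docking$linker_bounds)
      st$clashes <- assembly_clashes(st$placements, local_ca,
                                     params$clash_distance)
      pf <- partial_fraction(flat, st$placements, threshold)
      st$fraction <- pf$fraction; st$hinge <- pf$hinge
      st$placed_ca <- do.call(rbind, lapply(names(st$placements), function(s)
        rt_apply(st$placements[[s]], local_ca[[s]])))
      st
    })
  }
  if (!length(beam)) {
    message("assemble: no surviving assembly (", prune_note, ")")
    out <- list(); class(out) <- "xl_assemblies"
    return(out)
  }
  # cyclic whole-assembly refinement of the best candidates, then re-anchor
  # the first subunit at the identity
  n_polish <- min(10L, length(beam))
  sc <- vapply(beam, function(s) s$fraction - params$clash_penalty * s$clashes -
                 1e-3 * s$hinge, numeric(1))
  beam <- beam[order(-sc, vapply(beam, function(s)
    paste(s$provenance, collapse = ","), character(1)))]
  for (i in seq_len(n_polish)) {
    st <- beam[[i]]
    for (sweep_i in 1:2) for (s in names(st$placements))
      st$placements[[s]] <- context_redock(
        s, st$placements, flat, local_ca, grid,
        params$docking$rotation_step, threshold,
        params$clash_penalty, params$clash_distance,
        params$docking$linker_bounds)
    st$clashes <- assembly_clashes(st$placements, local_ca,
                                   params$clash_distance)
    pf <- partial_fraction(flat, st$placements, threshold)
    st$fraction <- pf$fraction; st$hinge <- pf$hinge
    beam[[i]] <- st
  }
  beam <- lapply(beam, function(st) {
    Ta_inv <- rt_invert(st$placements[[anchor_sub]])
    st$placements <- lapply(st$placements, function(Tp) rt_compose(Ta_inv, Tp))
    st
  })
  # global rescoring from scratch
  finals <- lapply(beam, function(st) {
    asm <- list(placements = st$placements, provenance = st$provenance)
    class(asm) <- "xl_assembly"
    rep <- score_assembly(asm, subunits, links, chain_map, threshold)
    asm$global_fraction_satisfied <- rep$fraction_satisfied
    asm$n_mappable <- rep$n_mappable
    asm$total_clashes <- st$clashes
    asm$score <- rep$fraction_satisfied - params$clash_penalty * st$clashes
    asm
  })
  ord <- order(-vapply(finals, `[[`, numeric(1), "score"),
               vapply(finals, `[[`, integer(1), "total_clashes"),
               vapply(finals, function(a) paste(a$provenance, collapse = ","),
                      character(1)))
  finals <- finals[ord]
  out <- cluster_assemblies(finals, subunits, params$cluster_rmsd)
  class(out) <- "xl_assemblies"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

connected_components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (i in seq_len(nrow(edges))) {
    ca <- comp[[edges$a[i]]]; cb <- comp[[edges$b[i]]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  comp
}

spanning_tree <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ca <- comp[[edges$a[i]]]; cb <- comp[[edges$b[i]]]
    if (ca != cb) { keep[i] <- TRUE; comp[comp == cb] <- ca }
  }
  edges[keep, , drop = FALSE]
}

#' Materialise an assembly as a single structure
#'
#' @param assembly an `xl_assembly`.
#' @param subunits the named subunit list given to [assemble()].
#' @return An `xl_structure` with every subunit placed.
#' @export
assembly_structure <- function(assembly, subunits) {
  miss <- setdiff(names(subunits), names(assembly$placements))
  if (length(miss))
    stop("assembly_structure: missing placement for subunit(s): ",
         paste(miss, collapse = ", "))
  placed <- lapply(names(assembly$placements), function(s)
    apply_transform(subunits[[s]], assembly$placements[[s]]))
  combine_structures(placed, id = "assembly")
}

#' Score a full assembly against the cross-link set
#'
#' Materialises the placed complex and delegates to [score_crosslinks()];
#' copy ambiguity is resolved across the whole assembly.
#'
#' @inheritParams assembly_structure
#' @param links,chain_map,threshold as in [score_crosslinks()].
#' @return An `xl_satisfaction` report.
#' @export
score_assembly <- function(assembly, subunits, links, chain_map,
                           threshold = 22) {
  score_crosslinks(assembly_structure(assembly, subunits), links, chain_map,
                   threshold = threshold)
}

#' Cluster assemblies by all-Calpha RMSD
#'
#' Greedy leader clustering after optimal superposition; the representative
#' of each cluster is its best-scoring member and output order follows
#' representative score.
#'
#' @param assemblies list of `xl_assembly` objects (assumed score-sorted).
#' @param subunits the named subunit list.
#' @param cluster_rmsd cluster radius in Angstrom.
#' @return List of cluster representatives (class `xl_assemblies`).
#' @export
cluster_assemblies <- function(assemblies, subunits, cluster_rmsd = 5) {
  stopifnot(length(assemblies) >= 1L)
  local_ca <- lapply(subunits, function(s) ca_coords(s)$xyz)
  all_ca <- function(asm)
    do.call(rbind, lapply(names(subunits), function(s)
      rt_apply(asm$placements[[s]], local_ca[[s]])))
  reps <- list(); rep_ca <- list()
  for (asm in assemblies) {
    x <- all_ca(asm)
    dup <- FALSE
    for (rc in rep_ca) {
      if (superpose(x, rc)$rmsd < cluster_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      reps[[length(reps) + 1L]] <- asm
      rep_ca[[length(rep_ca) + 1L]] <- x
    }
  }
  class(reps) <- "xl_assemblies"
  reps
}

#' @export
print.xl_assemblies <- function(x, ...) {
  cat("xl_assemblies:", length(x), "ranked assemblies\n")
  for (i in seq_len(min(5L, length(x))))
    cat(sprintf("  #%d score %.3f  satisfied %.3f  clashes %d\n", i,
                x[[i]]$score, x[[i]]$global_fraction_satisfied,
                x[[i]]$total_clashes))
  invisible(x)
}

#' Contact adjacency of an assembly
#'
#' Subunit pairs supported by at least `min_support` satisfied cross-links
#' in the placed model, for comparison with a designed topology. The default
#' support of 2 mirrors the assembler's own edge rule and makes the contact
#' graph robust to isolated false-positive links.
#'
#' @inheritParams score_assembly
#' @param min_support minimum satisfied links per reported contact.
#' @return Character vector of sorted `"a--b"` pair labels.
#' @export
assembly_adjacency <- function(assembly, subunits, links, chain_map,
                               threshold = 22, min_support = 2L) {
  rep <- score_assembly(assembly, subunits, links, chain_map, threshold)
  owner <- chain_owner(subunits)
  pl <- rep$per_link[rep$per_link$satisfied, , drop = FALSE]
  sa <- owner[pl$chain_a]; sb <- owner[pl$chain_b]
  keep <- sa != sb
  tab <- table(paste(pmin(sa[keep], sb[keep]), pmax(sa[keep], sb[keep]),
                     sep = "--"))
  sort(names(tab)[tab >= min_support])
}

#' Interface RMSD between a placed pair and its reference
#'
#' Interface residues are the Calpha beads of either subunit within
#' `contact_radius` of the partner in the reference pair; the model pair is
#' superposed onto the reference on those beads and their RMSD reported
#' (the convention used for docking interface quality).
#'
#' @param model_a,model_b placed n x 3 Calpha matrices of the two subunits.
#' @param ref_a,ref_b reference (ground-truth) Calpha matrices, same sizes.
#' @param contact_radius interface definition radius in Angstrom (default 10).
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(model_a, model_b, ref_a, ref_b,
                           contact_radius = 10) {
  d2 <- outer(rowSums(ref_a^2), rowSums(ref_b^2), "+") -
    2 * tcrossprod(ref_a, ref_b)
  i1 <- which(apply(d2, 1, min) < contact_radius^2)
  i2 <- which(apply(d2, 2, min) < contact_radius^2)
  if (length(i1) + length(i2) < 3L)
    stop("interface_rmsd: reference subunits share no interface within ",
         contact_radius, " A")
  superpose(rbind(model_a[i1, , drop = FALSE], model_b[i2, , drop = FALSE]),
            rbind(ref_a[i1, , drop = FALSE], ref_b[i2, , drop = FALSE]))$rmsd
}
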