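#' Side-chain and terminal pKa tables
#'
#' Named pKa sets for the ionisable groups used in isoelectric-point
#' calculation: side chains D, E, C, Y, H, K, R plus the N- and C-terminus.
#' Available tables: `"EMBOSS"` (default), `"Sillero"`, `"Bjellqvist"`.
#'
#' @param name table name.
#' @return A list of class `pka_table` with elements `Nterm`, `Cterm`, `D`,
#'   `E`, `C`, `Y`, `H`, `K`, `R` and `name`.
#' @export
pka_table <- function(name = c("EMBOSS", "Sillero", "Bjellqvist")) {
  name <- match.arg(name)
  tab <- switch(name,
    EMBOSS = list(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
                  Y = 10.1, H = 6.5, K = 10.8, R = 12.5),
    Sillero = list(Nterm = 8.2, Cterm = 3.2, D = 4.0, E = 4.5, C = 9.0,
                   Y = 10.0, H = 6.4, K = 10.4, R = 12.0),
    Bjellqvist = list(Nterm = 7.5, Cterm = 3.55, D = 4.05, E = 4.45,
                      C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0))
  stopifnot(all(unlist(tab) > 0), all(unlist(tab) < 14))
  tab$name <- name
  class(tab) <- "pka_table"
  tab
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sums: positive groups (N-terminus, H, K, R)
#' contribute `1 / (1 + 10^(pH - pKa))`, negative groups (C-terminus, D, E,
#' C, Y) contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param pH pH value(s).
#' @param pka a [pka_table()].
#' @param include_termini include terminal groups (default TRUE).
#' @return Net charge, same length as `pH`.
#' @export
net_charge <- function(sequence, pH, pka = pka_table(),
                       include_termini = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(aa, valid)
  if (length(bad)) stop("net_charge: unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  counts <- table(factor(aa, levels = valid))
  pos <- c(H = pka$H, K = pka$K, R = pka$R)
  neg <- c(D = pka$D, E = pka$E, C = pka$C, Y = pka$Y)
  vapply(pH, function(p) {
    z <- 0
    if (include_termini)
      z <- 1 / (1 + 10^(p - pka$Nterm)) - 1 / (1 + 10^(pka$Cterm - p))
    for (r in names(pos)) z <- z + counts[[r]] / (1 + 10^(p - pos[[r]]))
    for (r in names(neg)) z <- z - counts[[r]] / (1 + 10^(neg[[r]] - p))
    z
  }, numeric(1))
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on [0, 14]; the net charge is monotone decreasing in pH, so the
#' root is unique.
#'
#' @inheritParams net_charge
#' @param tol charge tolerance at the returned pI (default 1e-4).
#' @return The pI (numeric).
#' @export
isoelectric_point <- function(sequence, pka = pka_table(),
                              include_termini = TRUE, tol = 1e-4) {
  if (!nzchar(sequence)) stop("isoelectric_point: empty sequence")
  has_ionisable <- include_termini ||
    any(strsplit(toupper(sequence), "")[[1]] %in% c("D", "E", "C", "Y", "H", "K", "R"))
  if (!has_ionisable)
    stop("isoelectric_point: sequence has no ionisable groups and termini are excluded")
  lo <- 0; hi <- 14
  zlo <- net_charge(sequence, lo, pka, include_termini)
  zhi <- net_charge(sequence, hi, pka, include_termini)
  if (zlo < 0 || zhi > 0)
    stop("isoelectric_point: net charge does not change sign on [0, 14]")
  while ((hi - lo) > 1e-8) {
    mid <- (lo + hi) / 2
    z <- net_charge(sequence, mid, pka, include_termini)
    if (z > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(net_charge(sequence, mid, pka, include_termini)) > tol)
    stop("isoelectric_point: bisection converged without reaching |charge| < ",
         tol)
  mid
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of one-letter sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("read_fasta_sequences: file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("read_fasta_sequences: no FASTA headers in ", path)
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[seq(starts[i], ends[i])], collapse = ""), character(1))
  names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  gsub("\\s", "", seqs)
}

# Bondi-style van der Waals radii (Angstrom) by element
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90, ZN = 1.39, FE = 1.40, MG = 1.73)

# deterministic quasi-uniform unit sphere points (golden-spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples a fixed quasi-uniform point set on each atom's solvent-expanded
#' sphere and counts points not buried inside any neighbouring sphere:
#' per-atom area = (exposed / n_points) * 4 pi (r_vdw + probe)^2. The point
#' set is fixed in the lab frame, so rigid-transform invariance holds at the
#' sampling level (about 1%), not exactly.
#'
#' @param structure an `xl_structure`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @param uniform_radius fallback van der Waals radius for atoms whose
#'   element is unknown, e.g. coarse Calpha-only bead models (default NA:
#'   unknown elements raise an error; the synthetic fixtures use 3.8).
#' @return List of class `sasa_result`: `area` (per atom, Angstrom^2),
#'   `total`, `probe`, `n_points`.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960L,
                               uniform_radius = NA) {
  stopifnot(is_xl_structure(structure))
  at <- structure$atoms
  elem <- toupper(trimws(at$element))
  r <- unname(vdw_radii[elem])
  if (anyNA(r)) {
    if (is.na(uniform_radius))
      stop("shrake_rupley_sasa: unknown element for atom(s) ",
           paste(utils::head(which(is.na(r)), 3), collapse = ", "),
           " (element '", elem[which(is.na(r))[1]],
           "'); supply uniform_radius for coarse models")
    r[is.na(r)] <- uniform_radius
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  sph <- fibonacci_sphere(n_points)
  R <- r + probe
  # neighbour lists under the maximal interaction distance
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    pts <- sweep(sph * R[i], 2L, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        dd <- sweep(pts, 2L, xyz[j, ])
        exposed <- exposed & (rowSums(dd^2) >= R[j]^2)
        if (!any(exposed)) break
      }
      frac <- sum(exposed) / n_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * R[i]^2
  }
  out <- list(area = area, total = sum(area), probe = probe,
              n_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$area), x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area between two placed partners
#'
#' `dASA = SASA(A) + SASA(B) - SASA(A+B)` for structures in a common frame;
#' symmetric in its arguments and non-negative up to sampling noise. An
#' optional linear free-energy estimate (`dG = -coefficient * dASA`) can be
#' requested; it is a rough literature-style proxy, off by default.
#'
#' @param A,B `xl_structure` partners, already placed in one frame.
#' @param probe,n_points,uniform_radius passed to [shrake_rupley_sasa()].
#' @param dg_coefficient optional cal/(mol Angstrom^2) coefficient for a
#'   linear buried-area free-energy estimate; NULL (default) reports none.
#' @return List of class `bsa_result`: `dasa` (total, Angstrom^2),
#'   `dasa_a`, `dasa_b` (per partner), `sasa_a`, `sasa_b`, `sasa_ab`, and
#'   `dg_estimate` (kcal/mol or NULL).
#' @export
buried_surface_area <- function(A, B, probe = 1.4, n_points = 960L,
                                uniform_radius = NA, dg_coefficient = NULL) {
  sa <- shrake_rupley_sasa(A, probe, n_points, uniform_radius)
  sb <- shrake_rupley_sasa(B, probe, n_points, uniform_radius)
  chains_a <- unique(A$atoms$chain); chains_b <- unique(B$atoms$chain)
  if (length(intersect(chains_a, chains_b))) {
    B2 <- B; B2$atoms$chain <- paste0(B2$atoms$chain, "*")
    ab <- combine_structures(list(A, B2), id = "AB")
  } else ab <- combine_structures(list(A, B), id = "AB")
  sab <- shrake_rupley_sasa(ab, probe, n_points, uniform_radius)
  na <- nrow(A$atoms)
  dasa_a <- sa$total - sum(sab$area[seq_len(na)])
  dasa_b <- sb$total - sum(sab$area[-seq_len(na)])
  dasa <- sa$total + sb$total - sab$total
  # interpenetrating partners produce meaningless buried areas; warn
  pa <- as.matrix(A$atoms[, c("x", "y", "z")])
  pb <- as.matrix(B$atoms[, c("x", "y", "z")])
  mind2 <- min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb))
  if (mind2 < 1) warning("buried_surface_area: partners interpenetrate (min distance < 1 A)")
  out <- list(dasa = dasa, dasa_a = dasa_a, dasa_b = dasa_b,
              sasa_a = sa$total, sasa_b = sb$total, sasa_ab = sab$total,
              dg_estimate = if (is.null(dg_coefficient)) NULL
                            else -dg_coefficient * dasa / 1000)
  class(out) <- "bsa_result"
  out
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("bsa_result: buried area %.1f A^2 (A: %.1f, B: %.1f)\n",
              x$dasa, x$dasa_a, x$dasa_b))
  if (!is.null(x$dg_estimate))
    cat(sprintf("  linear dG estimate: %.2f kcal/mol\n", x$dg_estimate))
  invisible(x)
}
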