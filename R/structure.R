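#' Molecular structure container
#'
#' A light container for rigid-body subunit structures: an id plus an atom
#' table in file (author) numbering. Chains are ordered as encountered;
#' coordinates are in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   residue number), `resid` (3-letter residue name), `elety` (atom name,
#'   e.g. "CA"), `element`, `x`, `y`, `z`, and optionally `o` (occupancy)
#'   and `b` (B-factor).
#' @param id text label.
#' @return An object of class `xl_structure`.
#' @export
xl_structure <- function(atoms, id = "structure") {
  req <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("xl_structure: missing atom columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("xl_structure: empty atom table")
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("xl_structure: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("xl_structure: duplicate (chain, resno, atom name) after altloc resolution: ",
         key[anyDuplicated(key)])
  structure(list(id = id, atoms = atoms[, c(req, "o", "b")]),
            class = "xl_structure")
}

is_xl_structure <- function(x) inherits(x, "xl_structure")

#' @export
print.xl_structure <- function(x, ...) {
  ca <- sum(x$atoms$elety == "CA")
  cat(sprintf("xl_structure '%s': %d atoms, %d chains (%s), %d residues, %d CA\n",
              x$id, nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ","),
              nrow(unique(x$atoms[, c("chain", "resno")])), ca))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure an `xl_structure`.
#' @return Integer residue count (distinct chain/residue-number pairs).
#' @export
n_residues <- function(structure) {
  nrow(unique(structure$atoms[, c("chain", "resno")]))
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into an [xl_structure()]. Alternate locations are
#' resolved to the highest-occupancy record (ties broken by file order),
#' waters are excluded by default, and residues carrying insertion codes are
#' dropped with a warning (author numbering without insertion codes is the
#' contract used by cross-link tables).
#'
#' @param path file path.
#' @param format "pdb", "cif" or "auto" (by file extension, default pdb).
#' @param drop_hydrogens drop H atoms (default TRUE).
#' @param keep_waters retain HOH/WAT residues (default FALSE).
#' @param id structure id; defaults to the file name.
#' @return An `xl_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           drop_hydrogens = TRUE, keep_waters = FALSE,
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("read_structure: cannot parse ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at))
    stop("read_structure: no atoms parsed from ", path)
  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (drop_hydrogens) at <- at[!(at$elesy %in% c("H", "D")), ]
  if (!nrow(at)) stop("read_structure: no atoms retained from ", path)
  # insertion codes unsupported: drop affected residues, warn
  ins <- !is.na(at$insert) & nzchar(at$insert)
  if (any(ins)) {
    bad <- unique(paste0(at$chain[ins], at$resno[ins], at$insert[ins]))
    warning("read_structure: dropping ", length(bad),
            " residue(s) with insertion codes: ",
            paste(utils::head(bad, 5), collapse = ", "))
    at <- at[!ins, ]
  }
  if (!nrow(at)) stop("read_structure: no atoms retained from ", path)
  # altloc resolution: highest occupancy, ties to first encountered
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, ][!duplicated(key[ord]), ]
  at <- at[order(match(at$chain, unique(pdb$atom$chain)), at$resno,
                 as.integer(rownames(at))), ]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | !nzchar(elem)))
    elem <- substr(trimws(at$elety), 1, 1)
  xl_structure(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, element = ifelse(is.na(elem), "", elem),
               x = at$x, y = at$y, z = at$z,
               o = ifelse(is.na(at$o), 1, at$o),
               b = ifelse(is.na(at$b), 0, at$b),
               stringsAsFactors = FALSE),
    id = if (is.null(id)) basename(path) else id)
}

#' Write a structure as PDB
#'
#' Fixed-column PDB serialisation with TER records between chains. Round
#' trips through [read_structure()] preserve chain ids, residue numbers,
#' atom names, and coordinates to 3 decimals.
#'
#' @param structure an `xl_structure`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(is_xl_structure(structure))
  at <- structure$atoms
  if (!nrow(at)) stop("write_structure: empty structure")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000 - 5e-4))
    stop("write_structure: coordinate exceeds PDB fixed-width field (|x| >= 10000)")
  name4 <- ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, ]
    rec <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   serial + seq_len(nrow(sub)),
                   name4[at$chain == ch], sub$resid, substr(ch, 1, 1),
                   sub$resno, sub$x, sub$y, sub$z, sub$o, sub$b,
                   sub$element)
    serial <- serial + nrow(sub)
    last <- sub[nrow(sub), ]
    ter <- sprintf("TER   %5d      %-3s %1s%4d", serial + 1L,
                   last$resid, substr(ch, 1, 1), last$resno)
    serial <- serial + 1L
    lines <- c(lines, rec, ter)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# parse "A" or "A:10-20" selections (inclusive, author numbering)
parse_selection <- function(selection) {
  if (is.null(selection)) return(NULL)
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(list(chain = parts[1], from = NA, to = NA))
  rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  if (length(rng) != 2L) stop("bad selection syntax: ", selection,
                              " (expected CHAIN or CHAIN:START-END)")
  list(chain = parts[1], from = as.integer(rng[1]), to = as.integer(rng[2]))
}

#' Extract C-alpha coordinates
#'
#' One coordinate per residue possessing a CA atom, in chain-then-residue
#' order, with a parallel (chain, resno) index. Residues lacking a CA are
#' skipped and reported in `gaps` so cross-links to them can be flagged
#' unmappable rather than erroring.
#'
#' @param structure an `xl_structure`.
#' @param selection optional `"CHAIN"` or `"CHAIN:START-END"` selection
#'   (inclusive, author numbering).
#' @return List with `xyz` (n x 3 matrix), `index` (data.frame chain/resno),
#'   and `gaps` (residues without a CA atom).
#' @export
ca_coords <- function(structure, selection = NULL) {
  stopifnot(is_xl_structure(structure))
  at <- structure$atoms
  sel <- parse_selection(selection)
  if (!is.null(sel)) {
    keep <- at$chain == sel$chain
    if (!is.na(sel$from)) keep <- keep & at$resno >= sel$from & at$resno <= sel$to
    at <- at[keep, ]
    if (!nrow(at)) stop("ca_coords: selection '", selection,
                        "' matches no residues in ", structure$id)
  }
  res <- unique(at[, c("chain", "resno")])
  ca <- at[at$elety == "CA", ]
  has_ca <- paste(res$chain, res$resno) %in% paste(ca$chain, ca$resno)
  list(xyz = as.matrix(ca[, c("x", "y", "z")]),
       index = data.frame(chain = ca$chain, resno = ca$resno,
                          stringsAsFactors = FALSE),
       gaps = res[!has_ca, , drop = FALSE])
}

#' Apply a rigid transform to a structure
#'
#' @param structure an `xl_structure`.
#' @param transform a [rigid_transform()].
#' @return A new transformed `xl_structure`; the input is untouched.
#' @export
apply_transform <- function(structure, transform) {
  stopifnot(is_xl_structure(structure))
  if (!is_rigid_transform(transform))
    stop("apply_transform: not a rigid_transform")
  xyz <- rt_apply(transform, as.matrix(structure$atoms[, c("x", "y", "z")]))
  out <- structure
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of `mobile`
#' onto `reference` by the Kabsch SVD algorithm; reflections are excluded.
#'
#' @param mobile,reference n x 3 coordinate matrices of equal length, n >= 3.
#' @return List with `transform` (maps mobile onto reference) and `rmsd`
#'   (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("superpose: coordinate sets differ in length")
  n <- nrow(mobile)
  if (n < 3L) stop("superpose: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  sv <- svd(crossprod(P, Q))
  if (sv$d[2] < 1e-12)
    stop("superpose: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t)
  res <- rt_apply(tr, mobile) - reference
  list(transform = tr, rmsd = sqrt(mean(rowSums(res^2))))
}

#' Subset a structure by selection
#'
#' @param structure an `xl_structure`.
#' @param selection `"CHAIN"` or `"CHAIN:START-END"` (inclusive, author
#'   numbering).
#' @param id id for the subset (defaults to the parent id).
#' @return An `xl_structure` containing the selected residues.
#' @export
subset_structure <- function(structure, selection, id = NULL) {
  stopifnot(is_xl_structure(structure))
  sel <- parse_selection(selection)
  at <- structure$atoms
  keep <- at$chain == sel$chain
  if (!is.na(sel$from)) keep <- keep & at$resno >= sel$from & at$resno <= sel$to
  if (!any(keep)) stop("subset_structure: selection '", selection,
                       "' matches nothing in ", structure$id)
  xl_structure(at[keep, , drop = FALSE],
               id = if (is.null(id)) structure$id else id)
}

#' Combine structures into one
#'
#' Concatenates atom tables; chain ids must be unique across the inputs.
#'
#' @param structures list of `xl_structure` objects.
#' @param id id for the combined structure.
#' @return An `xl_structure`.
#' @export
combine_structures <- function(structures, id = "complex") {
  stopifnot(length(structures) >= 1L)
  chains <- unlist(lapply(structures, function(s) unique(s$atoms$chain)))
  if (anyDuplicated(chains))
    stop("combine_structures: duplicate chain ids across subunits: ",
         paste(unique(chains[duplicated(chains)]), collapse = ", "))
  xl_structure(do.call(rbind, lapply(structures, `[[`, "atoms")), id = id)
}
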