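#' Load a cross-link residue-pair table
#'
#' Reads a CLMS residue-pair CSV (Xi-style export) with header columns
#' `Protein1,Residue1,Protein2,Residue2,Linker[,Score]`. Duplicate rows
#' (same unordered residue pair and linker) are collapsed and counted;
#' self-links (same protein, same residue) are dropped with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of class `xl_links` with columns `protein_a`,
#'   `residue_a`, `protein_b`, `residue_b`, `linker`, `confidence`, and an
#'   attribute `n_duplicates`.
#' @export
load_crosslinks <- function(path) {
  if (!file.exists(path)) stop("load_crosslinks: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("Protein1", "Residue1", "Protein2", "Residue2", "Linker")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("load_crosslinks: missing required column(s): ",
         paste(miss, collapse = ", "))
  r1 <- suppressWarnings(as.integer(raw$Residue1))
  r2 <- suppressWarnings(as.integer(raw$Residue2))
  bad <- which(is.na(r1) | is.na(r2) | r1 < 1 | r2 < 1)
  if (length(bad))
    stop("load_crosslinks: non-integer or non-positive residue number at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!nzchar(raw$Protein1) | !nzchar(raw$Protein2)))
    stop("load_crosslinks: empty protein name")
  links <- data.frame(
    protein_a = as.character(raw$Protein1), residue_a = r1,
    protein_b = as.character(raw$Protein2), residue_b = r2,
    linker = as.character(raw$Linker),
    confidence = if ("Score" %in% names(raw)) as.numeric(raw$Score) else NA_real_,
    stringsAsFactors = FALSE)
  self <- links$protein_a == links$protein_b & links$residue_a == links$residue_b
  if (any(self)) {
    warning("load_crosslinks: dropping ", sum(self), " self-link row(s)")
    links <- links[!self, ]
  }
  if (!nrow(links)) stop("load_crosslinks: no usable links in ", path)
  # unordered pair key for duplicate collapsing
  a <- paste0(links$protein_a, "|", links$residue_a)
  b <- paste0(links$protein_b, "|", links$residue_b)
  key <- paste(pmin(a, b), pmax(a, b), links$linker, sep = "::")
  ndup <- sum(duplicated(key))
  if (ndup) message("load_crosslinks: collapsed ", ndup, " duplicate row(s)")
  links <- links[!duplicated(key), ]
  rownames(links) <- NULL
  class(links) <- c("xl_links", "data.frame")
  attr(links, "n_duplicates") <- ndup
  links
}

#' Build a cross-link table in code
#'
#' @param protein_a,residue_a,protein_b,residue_b,linker,confidence vectors
#'   (recycled) describing one link per element.
#' @return An `xl_links` data.frame.
#' @export
crosslink_table <- function(protein_a, residue_a, protein_b, residue_b,
                            linker = "EDC", confidence = NA_real_) {
  links <- data.frame(protein_a = as.character(protein_a),
                      residue_a = as.integer(residue_a),
                      protein_b = as.character(protein_b),
                      residue_b = as.integer(residue_b),
                      linker = linker, confidence = confidence,
                      stringsAsFactors = FALSE)
  if (any(links$residue_a < 1 | links$residue_b < 1))
    stop("crosslink_table: residue numbers must be >= 1")
  if (any(links$protein_a == links$protein_b &
          links$residue_a == links$residue_b))
    stop("crosslink_table: self-link (same protein, same residue)")
  class(links) <- c("xl_links", "data.frame")
  links
}

#' Write a cross-link table as CSV
#' @param links an `xl_links` data.frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_crosslinks <- function(links, path) {
  utils::write.csv(
    data.frame(Protein1 = links$protein_a, Residue1 = links$residue_a,
               Protein2 = links$protein_b, Residue2 = links$residue_b,
               Linker = links$linker, Score = links$confidence),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protein-to-chain mapping from JSON
#'
#' The chain map associates each protein name with the chain id(s) of its
#' copies in a model, e.g. `{"Mis18a": ["A","C","D","F"]}`.
#'
#' @param path JSON file.
#' @return Named list of character vectors.
#' @export
read_chain_map <- function(path) {
  cm <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_chain_map(cm)
  lapply(cm, as.character)
}

validate_chain_map <- function(chain_map, structure = NULL) {
  if (!length(chain_map) || is.null(names(chain_map)) ||
      any(!nzchar(names(chain_map))))
    stop("chain map must be a named list: protein -> chain ids")
  if (any(!lengths(chain_map)))
    stop("chain map entries must be non-empty")
  if (!is.null(structure)) {
    have <- unique(structure$atoms$chain)
    missing <- setdiff(unlist(chain_map), have)
    if (length(missing))
      stop("chain map references chain(s) absent from the structure: ",
           paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# CA coordinate lookup table: chain|resno -> row of xyz
ca_lookup <- function(structure) {
  ca <- ca_coords(structure)
  idx <- paste(ca$index$chain, ca$index$resno, sep = "|")
  list(xyz = ca$xyz, key = idx)
}

# all CA coordinates of (protein, residue) over its copies; NULL if none
copy_coords <- function(lookup, chains, resno) {
  keys <- paste(chains, resno, sep = "|")
  hit <- match(keys, lookup$key)
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(NULL)
  list(xyz = lookup$xyz[hit, , drop = FALSE],
       chain = sub("\\|.*", "", lookup$key[hit]))
}

#' Minimum C-alpha distance realising a cross-link
#'
#' With multiple copies of a protein, the minimum Calpha-Calpha Euclidean
#' distance over all copy-pair combinations decides the link (standard CLMS
#' convention). When both residues are on the same protein, a chain is never
#' paired with itself at the same residue pair unless the residues differ;
#' `inter_copy_only` restricts homo-oligomer links to different copies.
#'
#' @param structure an `xl_structure` (the model to score against).
#' @param link one-row `xl_links` data.frame (or list with the same fields).
#' @param chain_map named list protein -> chain ids.
#' @param inter_copy_only for links within one protein, consider only pairs
#'   of different copies (interface analysis); default FALSE.
#' @return List with `distance` (Angstrom), `chain_a`, `chain_b`; or `NULL`
#'   when either residue lacks a CA atom in every copy (unmappable).
#' @export
link_distance <- function(structure, link, chain_map,
                          inter_copy_only = FALSE) {
  lookup <- ca_lookup(structure)
  link_distance_impl(lookup, link, chain_map, inter_copy_only)
}

link_distance_impl <- function(lookup, link, chain_map, inter_copy_only) {
  for (p in c(link$protein_a, link$protein_b))
    if (is.null(chain_map[[p]]))
      stop("link_distance: protein '", p, "' absent from chain map")
  ca <- copy_coords(lookup, chain_map[[link$protein_a]], link$residue_a)
  cb <- copy_coords(lookup, chain_map[[link$protein_b]], link$residue_b)
  if (is.null(ca) || is.null(cb)) return(NULL)
  # pairwise distances over all copy combinations
  d2 <- outer(rowSums(ca$xyz^2), rowSums(cb$xyz^2), "+") -
    2 * tcrossprod(ca$xyz, cb$xyz)
  d2[d2 < 0] <- 0
  same_prot <- link$protein_a == link$protein_b
  if (same_prot) {
    same_chain <- outer(ca$chain, cb$chain, "==")
    if (inter_copy_only) d2[same_chain] <- Inf
    else if (link$residue_a == link$residue_b) d2[same_chain] <- Inf
  }
  if (all(!is.finite(d2))) return(NULL)
  k <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[k]), chain_a = ca$chain[k[1]], chain_b = cb$chain[k[2]])
}

#' Score a model against a cross-link set
#'
#' A cross-link is satisfied when its minimum Calpha-Calpha distance is
#' strictly less than the threshold (default 22 Angstrom); the score is the
#' fraction of satisfied links over the mappable ones. Links whose residues
#' have no CA atom in any copy are reported unmappable and excluded from the
#' denominator.
#'
#' @param structure an `xl_structure`.
#' @param links an `xl_links` table.
#' @param chain_map named list protein -> chain ids.
#' @param threshold satisfaction cutoff in Angstrom (default 22).
#' @param inter_copy_only see [link_distance()].
#' @return An `xl_satisfaction` list: `n_links`, `n_mappable`, `n_satisfied`,
#'   `fraction_satisfied`, `threshold`, and a `per_link` data.frame with the
#'   minimum distance, satisfied flag and realising chain pair of each link.
#' @export
score_crosslinks <- function(structure, links, chain_map, threshold = 22,
                             inter_copy_only = FALSE) {
  stopifnot(is_xl_structure(structure), nrow(links) >= 1L, threshold > 0)
  validate_chain_map(chain_map, structure)
  lookup <- ca_lookup(structure)
  per <- lapply(seq_len(nrow(links)), function(i)
    link_distance_impl(lookup, links[i, ], chain_map, inter_copy_only))
  mappable <- !vapply(per, is.null, logical(1))
  if (!any(mappable))
    stop("score_crosslinks: no mappable links (cannot form a fraction)")
  dist <- vapply(per, function(x) if (is.null(x)) NA_real_ else x$distance,
                 numeric(1))
  sat <- !is.na(dist) & dist < threshold
  per_link <- data.frame(
    protein_a = links$protein_a, residue_a = links$residue_a,
    protein_b = links$protein_b, residue_b = links$residue_b,
    linker = links$linker,
    min_distance = dist, mappable = mappable, satisfied = sat,
    chain_a = vapply(per, function(x) if (is.null(x)) NA_character_ else x$chain_a,
                     character(1)),
    chain_b = vapply(per, function(x) if (is.null(x)) NA_character_ else x$chain_b,
                     character(1)),
    stringsAsFactors = FALSE)
  out <- list(
    n_links = nrow(links), n_mappable = sum(mappable),
    n_satisfied = sum(sat),
    fraction_satisfied = sum(sat) / sum(mappable),
    threshold = threshold, per_link = per_link)
  class(out) <- "xl_satisfaction"
  out
}

#' @export
print.xl_satisfaction <- function(x, ...) {
  cat(sprintf(
    "cross-link satisfaction: %d/%d satisfied (%.1f%%) of %d mappable (%d total), threshold %.1f A\n",
    x$n_satisfied, x$n_mappable, 100 * x$fraction_satisfied,
    x$n_mappable, x$n_links, x$threshold))
  invisible(x)
}

#' Compare satisfaction across models
#'
#' Tabulates percent satisfied / violated over mappable links for a set of
#' scored models, optionally writing a CSV and drawing a stacked bar chart.
#'
#' @param reports named list of `xl_satisfaction` objects.
#' @param csv optional output CSV path.
#' @param plot draw a stacked bar chart on the active device (default FALSE).
#' @return data.frame with columns `model`, `pct_satisfied`, `pct_violated`,
#'   `n_mappable`.
#' @export
satisfaction_comparison <- function(reports, csv = NULL, plot = FALSE) {
  stopifnot(length(reports) >= 1L)
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  tab <- data.frame(
    model = names(reports),
    pct_satisfied = vapply(reports, function(r) 100 * r$fraction_satisfied,
                           numeric(1)),
    pct_violated = vapply(reports, function(r) 100 * (1 - r$fraction_satisfied),
                          numeric(1)),
    n_mappable = vapply(reports, `[[`, integer(1), "n_mappable"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (isTRUE(plot)) {
    m <- t(as.matrix(tab[, c("pct_satisfied", "pct_violated")]))
    graphics::barplot(m, names.arg = tab$model, col = c("#2c7fb8", "#d95f0e"),
                      ylab = "% of mappable cross-links",
                      legend.text = c("satisfied", "violated"))
  }
  tab
}

#' Write a satisfaction report to disk
#'
#' @param report an `xl_satisfaction` object.
#' @param csv per-link CSV path (optional).
#' @param json summary JSON path (optional).
#' @return The report, invisibly.
#' @export
write_satisfaction <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$per_link, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report[c("n_links", "n_mappable", "n_satisfied",
                                  "fraction_satisfied", "threshold")],
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
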