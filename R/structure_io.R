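#' Construct a structure frame
#'
#' A \code{structure_frame} is one ensemble snapshot: a data frame of atoms
#' with coordinates (A), partial charges (e) and radii (A). It is the unit
#' consumed by the membrane-geometry estimator, the dielectric-map builder
#' and the Poisson-Boltzmann solver.
#'
#' @param atoms Data frame with columns \code{atom_name}, \code{element},
#'   \code{residue_name}, \code{residue_id}, \code{chain_id}, \code{x},
#'   \code{y}, \code{z}, \code{charge}, \code{radius}.
#' @param frame_label Text label for the frame (e.g. a time tag such as
#'   \code{"0ns"}).
#' @param box Optional 3-vector of box lengths in A.
#' @return An object of class \code{structure_frame}.
#' @export
structure_frame <- function(atoms, frame_label = "frame", box = NULL) {
  required <- c("atom_name", "element", "residue_name", "residue_id",
                "chain_id", "x", "y", "z", "charge", "radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) < 1L) stop("a structure_frame needs at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$radius < 0)) stop("negative atom radius")
  if (any(!nzchar(atoms$chain_id))) stop("empty chain_id")
  ids <- atom_ids(atoms)
  if (anyDuplicated(ids))
    stop("duplicate atom identifiers within frame: ",
         paste(ids[duplicated(ids)][1], collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, frame_label = frame_label, box = box),
            class = "structure_frame")
}

atom_ids <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_id, atoms$atom_name, sep = ":")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame '%s': %d atoms, %d residues, total charge %+.3f e\n",
              x$frame_label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))),
              sum(x$atoms$charge)))
  invisible(x)
}

#' Bundle frames into an ensemble
#'
#' @param frames List of \code{structure_frame} objects sharing the same
#'   atom topology (identical atom identifiers in identical order).
#' @param state_label One of \code{"closed"}, \code{"open"},
#'   \code{"desensitized"}.
#' @return An object of class \code{frame_ensemble}.
#' @export
frame_ensemble <- function(frames, state_label = c("closed", "open", "desensitized")) {
  state_label <- match.arg(state_label)
  if (!length(frames)) stop("empty ensemble")
  ref <- atom_ids(frames[[1]]$atoms)
  for (f in frames) {
    if (!identical(atom_ids(f$atoms), ref))
      stop("ensemble frames do not share atom topology")
  }
  structure(list(frames = frames, state_label = state_label),
            class = "frame_ensemble")
}

elem_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("NA", "CL", "MG", "ZN", "BR", "FE")
  ifelse(nm %in% two, nm, substr(gsub("^[0-9]+", "", nm), 1, 1))
}

#' Read a structure file
#'
#' Reads a single structural snapshot in PDB or whitespace-delimited PQR
#' format into a \code{\link{structure_frame}}. PQR supplies partial
#' charges and radii in its own columns; PDB records carry neither, so
#' charges and radii are assigned from a configurable parameter table
#' (see \code{\link{default_parameter_table}}).
#'
#' @param path Path to the file.
#' @param dialect \code{"pqr"} or \code{"pdb"}.
#' @param params Parameter table for the PDB dialect, as returned by
#'   \code{\link{default_parameter_table}} or
#'   \code{\link{read_parameter_table}}. Ignored for PQR.
#' @param frame_label Label stored on the frame; defaults to the file name.
#' @return A \code{\link{structure_frame}}.
#' @export
read_structure <- function(path, dialect = c("pqr", "pdb"), params = NULL,
                           frame_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pqr") read_pqr(path, frame_label)
  else read_pdb_frame(path, params, frame_label)
}

# Whitespace PQR dialect:
#   ATOM serial name resname [chain] resid x y z charge radius
# The chain column is optional (10 vs 11 fields); coordinates kept to the
# precision printed in the file.
read_pqr <- function(path, frame_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) == 10L) {
      f <- append(f, "A", after = 4L)   # no chain column: default chain A
    }
    if (length(f) != 11L)
      stop(sprintf("malformed PQR record at line %d of %s: expected 10 or 11 fields, got %d",
                   lineno[i], path, length(f)))
    num <- suppressWarnings(as.numeric(f[6:11]))
    if (any(is.na(num)))
      stop(sprintf("malformed PQR record at line %d of %s: non-numeric field",
                   lineno[i], path))
    rows[[i]] <- data.frame(
      atom_name = f[3], element = elem_from_name(f[3]),
      residue_name = f[4], residue_id = as.integer(num[1]),
      chain_id = f[5], x = num[2], y = num[3], z = num[4],
      charge = num[5], radius = num[6], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  structure_frame(atoms, frame_label = frame_label)
}

read_pdb_frame <- function(path, params = NULL, frame_label = basename(path)) {
  if (is.null(params)) params <- default_parameter_table()
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  elesy <- if ("elesy" %in% names(a)) trimws(a$elesy) else rep("", nrow(a))
  elesy[is.na(elesy)] <- ""
  elem <- ifelse(nzchar(elesy), toupper(elesy), elem_from_name(a$elety))
  atoms <- data.frame(
    atom_name = trimws(a$elety), element = elem,
    residue_name = trimws(a$resid), residue_id = as.integer(a$resno),
    chain_id = chain, x = a$x, y = a$y, z = a$z,
    charge = NA_real_, radius = NA_real_, stringsAsFactors = FALSE)
  atoms <- assign_parameters(atoms, params)
  structure_frame(atoms, frame_label = frame_label)
}

# Fill charge/radius from the parameter table: radius by element, charge by
# (residue, atom) entry when present, else the residue-independent atom
# default, else 0.
assign_parameters <- function(atoms, params) {
  rad <- params$radii[atoms$element]
  if (any(is.na(rad))) {
    bad <- atoms$element[is.na(rad)]
    stop("no radius parameter for element(s): ",
         paste(unique(bad), collapse = ", "),
         " (atoms ", paste(head(atoms$atom_name[is.na(rad)], 5), collapse = ", "), ")")
  }
  atoms$radius <- unname(rad)
  atoms$charge <- 0
  ch <- params$charges
  if (!is.null(ch)) {
    for (res in names(ch)) {
      sel <- atoms$residue_name == res
      if (!any(sel)) next
      for (an in names(ch[[res]])) {
        atoms$charge[sel & atoms$atom_name == an] <- ch[[res]][[an]]
      }
    }
  }
  atoms
}

#' Default charge/radius parameter table for PDB input
#'
#' PDB files carry neither partial charges nor radii; this table supplies
#' per-element radii and per-(residue, atom) partial charges for the
#' titratable functional groups in their default protonation forms. It is
#' deliberately data, not code: read a YAML file with
#' \code{\link{read_parameter_table}} to substitute any other charge model.
#'
#' @return A list with components \code{radii} (named numeric, per element)
#'   and \code{charges} (nested list: residue -> atom -> charge).
#' @export
default_parameter_table <- function() {
  path <- system.file("extdata", "parameter_table.yaml", package = "pbpka")
  read_parameter_table(path)
}

#' Read a charge/radius parameter table from YAML
#'
#' @param path YAML file with top-level keys \code{radii} (element: A) and
#'   \code{charges} (residue: atom: e).
#' @return A list as described in \code{\link{default_parameter_table}}.
#' @export
read_parameter_table <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$radii)) stop("parameter table lacks a 'radii' section")
  list(radii = unlist(y$radii), charges = y$charges)
}

#' Write a frame in whitespace PQR format
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pqr <- function(frame, path) {
  a <- frame$atoms
  lines <- sprintf("ATOM %6d %-4s %-4s %s %5d %11.3f %11.3f %11.3f %8.4f %7.4f",
                   seq_len(nrow(a)), a$atom_name, a$residue_name, a$chain_id,
                   a$residue_id, a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Identify titratable sites in a frame
#'
#' Finds every Asp, Glu, His and Lys residue (or the subset named in
#' \code{include}) and attaches its reference pKa in water and the two
#' functional-group charge sets (protonated and deprotonated, differing by
#' exactly +1 e). Residues missing the side-chain atoms required by the
#' charge sets are skipped with a warning.
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param include Character subset of \code{c("ASP","GLU","HIS","LYS")}.
#' @param site_params Charge-set/reference-pKa definitions, as returned by
#'   \code{\link{default_site_definitions}}.
#' @return A list of \code{titratable_site} objects, ordered by
#'   (chain, residue_id). Each has fields \code{residue_name},
#'   \code{residue_id}, \code{chain_id}, \code{site_id},
#'   \code{reference_pka}, \code{charge_sets} and \code{acidic} (TRUE for
#'   Asp/Glu/His-style loss of charge on deprotonation is handled via the
#'   charge sets themselves).
#' @export
identify_titratable_sites <- function(frame,
                                      include = c("ASP", "GLU", "HIS", "LYS"),
                                      site_params = default_site_definitions()) {
  if (length(include)) {
    bad <- setdiff(include, c("ASP", "GLU", "HIS", "LYS"))
    if (length(bad)) stop("non-titratable residue names in include: ",
                          paste(bad, collapse = ", "))
  }
  a <- frame$atoms
  key <- paste(a$chain_id, a$residue_id, sep = ":")
  res <- unique(data.frame(chain_id = a$chain_id, residue_id = a$residue_id,
                           residue_name = a$residue_name, key = key,
                           stringsAsFactors = FALSE))
  res <- res[res$residue_name %in% include, , drop = FALSE]
  res <- res[order(res$chain_id, res$residue_id), , drop = FALSE]
  sites <- list()
  for (i in seq_len(nrow(res))) {
    def <- site_params[[res$residue_name[i]]]
    here <- a$atom_name[key == res$key[i]]
    need <- names(def$charge_sets$protonated)
    if (!all(need %in% here)) {
      warning(sprintf("skipping %s %s%d: missing side-chain atoms %s",
                      res$residue_name[i], res$chain_id[i], res$residue_id[i],
                      paste(setdiff(need, here), collapse = ", ")))
      next
    }
    sites[[length(sites) + 1L]] <- structure(list(
      residue_name  = res$residue_name[i],
      residue_id    = res$residue_id[i],
      chain_id      = res$chain_id[i],
      site_id       = paste(res$chain_id[i], res$residue_id[i],
                            res$residue_name[i], sep = ":"),
      reference_pka = def$reference_pka,
      charge_sets   = def$charge_sets,
      is_base       = def$is_base
    ), class = "titratable_site")
  }
  sites
}

#' Built-in titratable-site definitions
#'
#' Reference pKas in water (Asp 3.90, Glu 4.07, His 6.04, Lys 10.54) and a
#' simplified localized charge model: the +1 proton charge difference is
#' carried entirely by the titratable functional-group atoms, so the
#' protonated and deprotonated sets differ by exactly +1 e. The set is
#' data (shipped as YAML), not code; pass any drop-in replacement with the
#' same shape to \code{\link{identify_titratable_sites}}.
#'
#' @return Named list (ASP/GLU/HIS/LYS) of definitions with
#'   \code{reference_pka}, \code{charge_sets} (protonated/deprotonated named
#'   vectors) and \code{is_base}.
#' @export
default_site_definitions <- function() {
  path <- system.file("extdata", "titratable_sites.yaml", package = "pbpka")
  y <- yaml::read_yaml(path)
  lapply(y, function(d) {
    cs <- lapply(d$charge_sets, function(v) unlist(v))
    dq <- sum(cs$protonated) - sum(cs$deprotonated)
    if (abs(dq - 1) > 1e-9)
      stop("charge sets must differ by exactly +1 e (protonated - deprotonated)")
    list(reference_pka = d$reference_pka, charge_sets = cs,
         is_base = isTRUE(d$is_base))
  })
}

backbone_atom_names <- c("N", "CA", "C", "O", "OXT")

#' Minimal side-chain heavy-atom distance between two residues
#'
#' Side-chain heavy atoms are all non-hydrogen atoms beyond the backbone
#' set (Cb inclusive). The distance is the minimum Euclidean distance over
#' all such atom pairs, as used to judge hydrogen-bonding proximity of
#' interacting residues.
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param residue_a,residue_b Residue identifiers \code{"chain:resid"}.
#' @return Distance in A.
#' @export
min_sidechain_distance <- function(frame, residue_a, residue_b) {
  sc <- function(id) {
    parts <- strsplit(id, ":")[[1]]
    if (length(parts) < 2L) stop("residue identifier must be 'chain:resid'")
    a <- frame$atoms
    sel <- a$chain_id == parts[1] & a$residue_id == as.integer(parts[2])
    if (!any(sel)) stop("residue not found: ", id)
    sel <- sel & !(a$atom_name %in% backbone_atom_names) & a$element != "H"
    if (!any(sel)) stop("no side-chain heavy atoms for residue ", id)
    as.matrix(a[sel, c("x", "y", "z")])
  }
  xa <- sc(residue_a); xb <- sc(residue_b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

#' Export a result table as CSV
#'
#' Writes any tabular result (pKa tables, protonation fractions, rankings)
#' as UTF-8 CSV with a header, '.' decimal separator and the data frame's
#' column order.
#'
#' @param records A non-empty data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
export_table <- function(records, path) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("refusing to export an empty table")
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
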