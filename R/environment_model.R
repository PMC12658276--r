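#' Estimate per-frame membrane geometry
#'
#' The bilayer midplane is the mean z-coordinate of the terminal methyl
#' carbons of the lipid tails; the total thickness is the difference
#' between the mean z of the phosphorus atoms of the upper and lower
#' leaflets (leaflets separated by the methyl midplane). The hydrophobic
#' core spans \code{|z - midplane| < core_half_thickness} with
#' \code{core_half_thickness = total_thickness/2 - headgroup_thickness};
#' each headgroup shell sits immediately outside the core and is
#' \code{headgroup_thickness} (default 2 A) thick. Geometry is estimated
#' per frame because membrane thickness and insertion fluctuate between
#' snapshots.
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param phosphorus_selector Predicate on the atom data frame, or a
#'   regular expression matched against atom names. Default: atoms named
#'   \code{"P"}.
#' @param terminal_methyl_selector Same forms; default matches the
#'   \code{C216}/\code{C316}-style terminal-methyl names.
#' @param headgroup_thickness Headgroup shell thickness in A (default 2).
#' @return A list of class \code{membrane_geometry} with
#'   \code{midplane_z}, \code{core_half_thickness},
#'   \code{headgroup_thickness}, \code{total_thickness}.
#' @export
estimate_membrane_geometry <- function(frame,
                                       phosphorus_selector = "^P$",
                                       terminal_methyl_selector = "^C[0-9]16$|^C316$|^C216$",
                                       headgroup_thickness = 2) {
  a <- frame$atoms
  sel <- function(s) {
    if (is.function(s)) which(s(a)) else grep(s, a$atom_name)
  }
  ip <- sel(phosphorus_selector)
  im <- sel(terminal_methyl_selector)
  if (!length(ip)) stop("membrane geometry: phosphorus selector matched no atoms")
  if (!length(im)) stop("membrane geometry: terminal-methyl selector matched no atoms")
  midplane <- mean(a$z[im])
  zp <- a$z[ip]
  upper <- zp > midplane
  if (all(upper) || all(!upper))
    stop("membrane geometry: all phosphorus atoms on one side of the methyl midplane")
  thickness <- mean(zp[upper]) - mean(zp[!upper])
  structure(list(
    midplane_z = midplane,
    core_half_thickness = thickness / 2 - headgroup_thickness,
    headgroup_thickness = headgroup_thickness,
    total_thickness = thickness
  ), class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf("membrane slab: midplane z = %.3f A, thickness %.3f A (core half %.3f, headgroups %.3f A)\n",
              x$midplane_z, x$total_thickness, x$core_half_thickness,
              x$headgroup_thickness))
  invisible(x)
}

# default mapping from ion residue/atom names to valence
default_ion_table <- function() {
  c(NA. = 1, SOD = 1, K = 1, POT = 1, CL = -1, CLA = -1,
    CA = 2, CAL = 2, MG = 2, ZN = 2)
}

ion_valence <- function(names_vec, table = default_ion_table()) {
  nm <- toupper(names_vec)
  nm[nm == "NA"] <- "NA."            # guard against R's NA coercion
  v <- table[nm]
  if (any(is.na(v)))
    stop("unknown ion species: ",
         paste(unique(names_vec[is.na(v)]), collapse = ", "))
  unname(v)
}

#' Select explicit ions near the protein
#'
#' A frame extracted from a simulation can carry ions bound at the protein
#' surface whose field an implicit-ion treatment misses; such ions must be
#' entered explicitly into the electrostatic calculation. An ion is
#' retained iff its minimum distance to any protein heavy atom is strictly
#' below the threshold for its valence class: 3 A for monovalent ions and
#' 6 A for divalent ions by default.
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param protein_rows Logical or integer index of the protein atoms within
#'   \code{frame$atoms}.
#' @param ion_rows Index of the candidate ion atoms.
#' @param thresholds Named numeric, A: \code{c(monovalent = 3, divalent = 6)}.
#' @param ion_table Named valence lookup by residue name.
#' @return A list of class \code{ion_selection}: data frame \code{ions}
#'   (species, valence, position, distance, retained flag) and the
#'   thresholds used.
#' @export
select_explicit_ions <- function(frame, protein_rows, ion_rows,
                                 thresholds = c(monovalent = 3, divalent = 6),
                                 ion_table = default_ion_table()) {
  a <- frame$atoms
  prot <- a[protein_rows, , drop = FALSE]
  prot <- prot[prot$element != "H", , drop = FALSE]
  if (!nrow(prot)) stop("no protein heavy atoms to measure distances against")
  ions <- a[ion_rows, , drop = FALSE]
  if (!nrow(ions)) {
    return(structure(list(ions = data.frame(), thresholds = thresholds),
                     class = "ion_selection"))
  }
  val <- ion_valence(ions$residue_name, ion_table)
  pm <- as.matrix(prot[, c("x", "y", "z")])
  im <- as.matrix(ions[, c("x", "y", "z")])
  d2 <- outer(rowSums(im^2), rowSums(pm^2), "+") - 2 * im %*% t(pm)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  thr <- ifelse(abs(val) >= 2, thresholds[["divalent"]], thresholds[["monovalent"]])
  out <- data.frame(species = ions$residue_name, valence = val,
                    x = ions$x, y = ions$y, z = ions$z,
                    distance = dmin, threshold = thr,
                    retained = dmin < thr, stringsAsFactors = FALSE)
  structure(list(ions = out, thresholds = thresholds), class = "ion_selection")
}
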