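#' Build an axis-aligned grid covering a frame
#'
#' The grid covers the atom bounding box expanded by \code{padding} on all
#' sides, with \code{ceil(extent/spacing) + 1} nodes per axis.
#'
#' @param frame A \code{\link{structure_frame}}, or a numeric matrix of
#'   points (columns x, y, z) to enclose.
#' @param spacing Grid spacing in A (> 0).
#' @param padding Padding in A added on every side (>= 0).
#' @return A list of class \code{grid_spec}: \code{origin}, \code{spacing},
#'   \code{dims}.
#' @export
build_grid <- function(frame, spacing, padding = 10) {
  stopifnot(spacing > 0, padding >= 0)
  pts <- if (inherits(frame, "structure_frame"))
    as.matrix(frame$atoms[, c("x", "y", "z")]) else as.matrix(frame)
  if (!nrow(pts)) stop("cannot build a grid around zero atoms")
  lo <- apply(pts, 2, min) - padding
  hi <- apply(pts, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  structure(list(origin = as.numeric(lo), spacing = spacing, dims = dims),
            class = "grid_spec")
}

grid_axes <- function(grid) {
  lapply(1:3, function(d) grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing)
}

#' Default region permittivities
#'
#' Relative dielectric constants of the reference environment, membrane
#' core, membrane headgroups, protein interior and solvent: 1, 4, 8, 8
#' and 80.
#' @return Named numeric vector.
#' @export
default_region_values <- function() {
  c(reference = 1, membrane_core = 4, headgroups = 8, protein = 8, solvent = 80)
}

# region codes used in the voxel map
REGION_SOLVENT <- 0L
REGION_CORE <- 1L
REGION_HEADGROUP <- 2L
REGION_PROTEIN <- 3L

#' Build the voxel dielectric map
#'
#' Voxels inside any atom sphere (at the atom's input radius) are protein
#' interior; otherwise voxels within the membrane core slab take the core
#' permittivity, voxels in the headgroup shells the headgroup value, and
#' everything else is solvent. With \code{membrane = NULL} the map is
#' protein + solvent only.
#'
#' @param frame A \code{\link{structure_frame}} supplying atom spheres;
#'   rows with zero radius contribute no protein voxels.
#' @param grid A \code{\link{build_grid}} result.
#' @param membrane A \code{membrane_geometry} or \code{NULL}.
#' @param region_values Named permittivities (see
#'   \code{\link{default_region_values}}).
#' @param protein_rows Optional index restricting which atoms carve the
#'   protein region (e.g. to exclude explicit ions kept as point charges).
#' @return A list of class \code{dielectric_map}: \code{grid},
#'   \code{epsilon} (3-D array), \code{region} (3-D integer array),
#'   \code{region_values}.
#' @export
build_dielectric_map <- function(frame, grid, membrane = NULL,
                                 region_values = default_region_values(),
                                 protein_rows = NULL) {
  needed <- c("membrane_core", "headgroups", "protein", "solvent")
  if (!all(needed %in% names(region_values)))
    stop("region_values must name: ", paste(needed, collapse = ", "))
  dims <- grid$dims
  region <- array(REGION_SOLVENT, dim = dims)
  if (!is.null(membrane)) {
    zax <- grid_axes(grid)[[3]]
    dz <- abs(zax - membrane$midplane_z)
    core <- dz < membrane$core_half_thickness
    head <- !core & dz < membrane$core_half_thickness + membrane$headgroup_thickness
    for (k in which(core)) region[, , k] <- REGION_CORE
    for (k in which(head)) region[, , k] <- REGION_HEADGROUP
  }
  a <- frame$atoms
  if (!is.null(protein_rows)) a <- a[protein_rows, , drop = FALSE]
  a <- a[a$radius > 0, , drop = FALSE]
  if (nrow(a)) {
    region <- array(.mark_protein_voxels(as.integer(region),
                                         as.matrix(a[, c("x", "y", "z")]),
                                         a$radius, grid$origin, grid$spacing,
                                         dims, REGION_PROTEIN),
                    dim = dims)
  }
  eps <- array(region_values[["solvent"]], dim = dims)
  eps[region == REGION_CORE] <- region_values[["membrane_core"]]
  eps[region == REGION_HEADGROUP] <- region_values[["headgroups"]]
  eps[region == REGION_PROTEIN] <- region_values[["protein"]]
  structure(list(grid = grid, epsilon = eps, region = region,
                 region_values = region_values),
            class = "dielectric_map")
}

#' Build the mobile-ion screening map
#'
#' The linearized screening coefficient (the
#' \eqn{\sum_i z_i^2 e^2 c_{\infty,i}/k_BT} factor, premultiplied by the
#' unit conversions of the solver) is applied in solvent voxels only; it is
#' zero inside the protein and the membrane, where mobile ions cannot go.
#'
#' @param dielectric A \code{\link{build_dielectric_map}} result.
#' @param constants A \code{\link{pb_constants}} bundle.
#' @return A list of class \code{screening_map}: \code{grid},
#'   \code{kappa_sq} (3-D array, A^-2 times permittivity units).
#' @export
build_screening_map <- function(dielectric, constants) {
  coef <- screening_coefficient(constants)
  ks <- array(0, dim = dielectric$grid$dims)
  ks[dielectric$region == REGION_SOLVENT] <- coef
  structure(list(grid = dielectric$grid, kappa_sq = ks),
            class = "screening_map")
}

# trilinear weights of points onto grid nodes; returns node charge array
spread_charges <- function(grid, charges) {
  dims <- grid$dims
  qarr <- array(0, dim = dims)
  if (!nrow(charges)) return(qarr)
  u <- (as.matrix(charges[, c("x", "y", "z")]) -
          matrix(grid$origin, nrow(charges), 3, byrow = TRUE)) / grid$spacing
  i0 <- floor(u)
  f <- u - i0
  if (any(i0 < 0) || any(i0[, 1] > dims[1] - 2) || any(i0[, 2] > dims[2] - 2) ||
      any(i0[, 3] > dims[3] - 2))
    stop("charge site outside grid")
  for (n in seq_len(nrow(charges))) {
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[n, 1] else 1 - f[n, 1]) *
        (if (dy) f[n, 2] else 1 - f[n, 2]) *
        (if (dz) f[n, 3] else 1 - f[n, 3])
      ii <- i0[n, 1] + dx + 1L; jj <- i0[n, 2] + dy + 1L; kk <- i0[n, 3] + dz + 1L
      qarr[ii, jj, kk] <- qarr[ii, jj, kk] + w * charges$charge[n]
    }
  }
  qarr
}

# trilinear interpolation of a grid field at arbitrary points
interp_grid <- function(arr, grid, pts) {
  pts <- as.matrix(pts)
  dims <- grid$dims
  u <- (pts - matrix(grid$origin, nrow(pts), 3, byrow = TRUE)) / grid$spacing
  i0 <- floor(u)
  f <- u - i0
  if (any(i0 < 0) || any(i0[, 1] > dims[1] - 2) || any(i0[, 2] > dims[2] - 2) ||
      any(i0[, 3] > dims[3] - 2))
    stop("interpolation point outside grid")
  out <- numeric(nrow(pts))
  for (n in seq_len(nrow(pts))) {
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[n, 1] else 1 - f[n, 1]) *
        (if (dy) f[n, 2] else 1 - f[n, 2]) *
        (if (dz) f[n, 3] else 1 - f[n, 3])
      acc <- acc + w * arr[i0[n, 1] + dx + 1L, i0[n, 2] + dy + 1L, i0[n, 3] + dz + 1L]
    }
    out[n] <- acc
  }
  out
}

# shift a grid so that `center` falls exactly on a lattice point; the
# origin moves down by less than one spacing and one node is added per
# axis, so coverage only grows. Anchoring both legs of a thermodynamic
# cycle to the same site center makes the charge-to-lattice alignment --
# and hence the grid self-energy -- identical, so it cancels exactly.
snap_grid_to <- function(grid, center) {
  h <- grid$spacing
  center <- unname(as.numeric(center))
  shift <- (center - grid$origin) %% h
  moved <- shift > 1e-12 & shift < h - 1e-12
  grid$origin <- unname(grid$origin - ifelse(moved, h - shift, 0))
  grid$dims <- unname(grid$dims + ifelse(moved, 1L, 0L))
  grid
}

# logical mask of boundary nodes, and their coordinates
boundary_nodes <- function(grid) {
  dims <- grid$dims
  mask <- array(FALSE, dim = dims)
  mask[c(1, dims[1]), , ] <- TRUE
  mask[, c(1, dims[2]), ] <- TRUE
  mask[, , c(1, dims[3])] <- TRUE
  idx <- which(mask, arr.ind = TRUE)
  coords <- cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing,
                  grid$origin[2] + (idx[, 2] - 1) * grid$spacing,
                  grid$origin[3] + (idx[, 3] - 1) * grid$spacing)
  list(mask = mask, index = idx, coords = coords)
}
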