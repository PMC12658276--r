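#' Specification for a toy membrane-embedded charge system
#'
#' Describes a fully synthetic system the pipeline can run on: titratable
#' side-chain fragments at chosen positions, optional fixed background
#' charges, an optional membrane slab realized by uncharged marker atoms
#' (phosphorus per leaflet, terminal methyls at the midplane), and
#' explicit ions. Frames generated from one spec and seed are
#' bit-reproducible.
#'
#' @param sites Data frame with columns \code{residue_name} (ASP, GLU,
#'   HIS or LYS), \code{chain_id}, \code{residue_id}, \code{x}, \code{y},
#'   \code{z} (position of the functional-group anchor atom).
#' @param background Optional data frame of fixed charges: \code{x},
#'   \code{y}, \code{z}, \code{charge}, \code{radius}.
#' @param membrane \code{NULL}, or a list with \code{thickness} (A),
#'   \code{midplane_z} (A, default 0) and \code{n_per_leaflet} (default
#'   8 phosphorus markers per leaflet).
#' @param ions Optional data frame: \code{species} (\code{"NA."},
#'   \code{"CL"}, \code{"CA"}, ...), \code{x}, \code{y}, \code{z}.
#' @param jitter_amplitude Per-coordinate Gaussian jitter (A) used by
#'   \code{\link{jitter_frames}}.
#' @param seed Integer seed.
#' @return A list of class \code{toy_system_spec}.
#' @export
toy_system_spec <- function(sites, background = NULL, membrane = NULL,
                            ions = NULL, jitter_amplitude = 0.1, seed = 1) {
  if (!nrow(sites)) stop("at least one titratable site is required")
  structure(list(sites = sites, background = background,
                 membrane = membrane, ions = ions,
                 jitter_amplitude = jitter_amplitude, seed = seed),
            class = "toy_system_spec")
}

# local side-chain fragment geometries; the first atom is the anchor
fragment_geometry <- list(
  GLU = data.frame(atom_name = c("CD", "OE1", "OE2"),
                   element = c("C", "O", "O"),
                   dx = c(0, 1.25, -0.60), dy = c(0, 0, 1.10),
                   dz = c(0, 0, 0), radius = c(1.7, 1.5, 1.5)),
  ASP = data.frame(atom_name = c("CG", "OD1", "OD2"),
                   element = c("C", "O", "O"),
                   dx = c(0, 1.25, -0.60), dy = c(0, 0, 1.10),
                   dz = c(0, 0, 0), radius = c(1.7, 1.5, 1.5)),
  HIS = data.frame(atom_name = c("CE1", "ND1", "NE2"),
                   element = c("C", "N", "N"),
                   dx = c(0, 1.30, -0.65), dy = c(0, 0, 1.15),
                   dz = c(0, 0, 0), radius = c(1.7, 1.55, 1.55)),
  LYS = data.frame(atom_name = c("NZ", "CE"),
                   element = c("N", "C"),
                   dx = c(0, 1.50), dy = c(0, 0), dz = c(0, 0),
                   radius = c(1.55, 1.7))
)

#' Build a toy membrane system frame
#'
#' Realizes a \code{\link{toy_system_spec}} as a
#' \code{\link{structure_frame}}: titratable fragments carry their
#' default-form charge sets, membrane markers are uncharged zero-radius
#' atoms (so the slab geometry is testable independently of the
#' electrostatics), background charges and ions enter as single atoms.
#'
#' @param spec A \code{\link{toy_system_spec}}.
#' @param site_params Site definitions (see
#'   \code{\link{default_site_definitions}}).
#' @return A \code{\link{structure_frame}}.
#' @export
make_toy_membrane_system <- function(spec,
                                     site_params = default_site_definitions()) {
  rows <- list()
  for (i in seq_len(nrow(spec$sites))) {
    s <- spec$sites[i, ]
    geom <- fragment_geometry[[s$residue_name]]
    if (is.null(geom)) stop("unsupported residue: ", s$residue_name)
    def <- site_params[[s$residue_name]]
    default_state <- if (s$residue_name == "LYS") "protonated" else "deprotonated"
    cs <- def$charge_sets[[default_state]]
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = geom$atom_name, element = geom$element,
      residue_name = s$residue_name, residue_id = s$residue_id,
      chain_id = s$chain_id,
      x = s$x + geom$dx, y = s$y + geom$dy, z = s$z + geom$dz,
      charge = unname(cs[geom$atom_name]), radius = geom$radius,
      stringsAsFactors = FALSE)
  }
  if (!is.null(spec$background) && nrow(spec$background)) {
    b <- spec$background
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = paste0("Q", seq_len(nrow(b))), element = "C",
      residue_name = "BCK", residue_id = 9000L + seq_len(nrow(b)),
      chain_id = "X", x = b$x, y = b$y, z = b$z,
      charge = b$charge, radius = b$radius, stringsAsFactors = FALSE)
  }
  if (!is.null(spec$membrane)) {
    m <- spec$membrane
    mid <- if (is.null(m$midplane_z)) 0 else m$midplane_z
    npl <- if (is.null(m$n_per_leaflet)) 8L else m$n_per_leaflet
    ang <- 2 * pi * (seq_len(npl) - 1) / npl
    ring_r <- 25
    pz <- c(rep(mid + m$thickness / 2, npl), rep(mid - m$thickness / 2, npl))
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "P", element = "P", residue_name = "LIP",
      residue_id = 8000L + seq_len(2 * npl), chain_id = "M",
      x = ring_r * cos(c(ang, ang)), y = ring_r * sin(c(ang, ang)), z = pz,
      charge = 0, radius = 0, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = rep(c("C216", "C316"), length.out = npl), element = "C",
      residue_name = "LIP", residue_id = 8500L + seq_len(npl),
      chain_id = "M", x = ring_r * cos(ang), y = ring_r * sin(ang),
      z = rep(mid, npl), charge = 0, radius = 0, stringsAsFactors = FALSE)
  }
  if (!is.null(spec$ions) && nrow(spec$ions)) {
    io <- spec$ions
    val <- ion_valence(io$species)
    nm <- toupper(sub("\\.$", "", io$species))
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = nm, element = nm, residue_name = nm,
      residue_id = 7000L + seq_len(nrow(io)), chain_id = "I",
      x = io$x, y = io$y, z = io$z, charge = val,
      radius = ifelse(abs(val) >= 2, 1.3, 1.6), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  solid <- atoms[atoms$radius > 0, , drop = FALSE]
  if (nrow(solid) > 1) {
    xyz <- as.matrix(solid[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 0.5)
      stop(sprintf("overlapping atoms in toy spec (min distance %.2f A < 0.5 A)",
                   min(d)))
  }
  structure_frame(atoms, frame_label = "0")
}

#' Jittered frame ensemble from one frame
#'
#' Emulates snapshots extracted along a short relaxation trajectory:
#' \code{n_frames} copies of the frame, each atom coordinate displaced by
#' zero-mean Gaussian noise of the given amplitude; the first frame is
#' unperturbed and labels follow the 0, 2, 4, ... ns convention.
#'
#' @param frame A \code{\link{structure_frame}}.
#' @param n_frames Number of frames (default 5).
#' @param amplitude Per-coordinate standard deviation in A.
#' @param seed Integer seed.
#' @param state_label Ensemble state label.
#' @return A \code{\link{frame_ensemble}}.
#' @export
jitter_frames <- function(frame, n_frames = 5, amplitude = 0.1, seed = 1,
                          state_label = "closed") {
  stopifnot(amplitude >= 0, n_frames >= 1)
  set.seed(seed)
  labels <- as.character(seq(0, by = 2, length.out = n_frames))
  frames <- vector("list", n_frames)
  frames[[1]] <- frame
  frames[[1]]$frame_label <- labels[1]
  na <- nrow(frame$atoms)
  for (i in seq_len(n_frames - 1) + 1) {
    f <- frame
    f$atoms$x <- f$atoms$x + stats::rnorm(na, 0, amplitude)
    f$atoms$y <- f$atoms$y + stats::rnorm(na, 0, amplitude)
    f$atoms$z <- f$atoms$z + stats::rnorm(na, 0, amplitude)
    f$frame_label <- labels[i]
    frames[[i]] <- f
  }
  frame_ensemble(frames, state_label)
}

#' Simulate a pH dose-response curve
#'
#' Hill-equation responses plus i.i.d. Gaussian noise, averaged over
#' replicates, with the SEM reported per point.
#'
#' @param ph50 Midpoint. @param n_h Hill coefficient. @param i_max
#'   Amplitude.
#' @param ph_grid pH values sampled.
#' @param noise_sd Per-measurement Gaussian noise SD.
#' @param n_replicates Replicates averaged per point.
#' @param seed Integer seed.
#' @param transition \code{"activation"} or \code{"ssd"}.
#' @return Data frame: \code{ph}, \code{response}, \code{sem}, \code{n}.
#' @export
simulate_dose_response <- function(ph50, n_h = 1, i_max = 1,
                                   ph_grid = seq(5, 8, by = 0.25),
                                   noise_sd = 0, n_replicates = 1, seed = 1,
                                   transition = c("activation", "ssd")) {
  transition <- match.arg(transition)
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  sgn <- if (transition == "activation") 1 else -1
  truth <- i_max / (1 + 10^(sgn * n_h * (ph_grid - ph50)))
  reps <- matrix(rep(truth, n_replicates), ncol = n_replicates)
  if (noise_sd > 0)
    reps <- reps + matrix(stats::rnorm(length(reps), 0, noise_sd),
                          ncol = n_replicates)
  data.frame(ph = ph_grid, response = rowMeans(reps),
             sem = if (n_replicates > 1) apply(reps, 1, stats::sd) / sqrt(n_replicates)
                   else NA_real_,
             n = n_replicates)
}

#' Simulate a substitution panel with a planted property dependence
#'
#' Generates per-substitution midpoints
#' \code{ph50 = intercept + slope * scale(substitution) + noise} for
#' power-testing the property regressions.
#'
#' @param position Residue position label (metadata only).
#' @param substitutions One-letter codes of the substituted residues
#'   (>= 4).
#' @param scale_values Named numeric property scale.
#' @param slope,intercept Planted linear dependence.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return Data frame: \code{position}, \code{substitution}, \code{ph50}.
#' @export
simulate_mutant_panel <- function(position, substitutions, scale_values,
                                  slope, intercept, noise_sd = 0, seed = 1) {
  if (length(substitutions) < 4L)
    stop("need at least 4 substitutions")
  missing <- setdiff(substitutions, names(scale_values))
  if (length(missing))
    stop("substitution absent from scale: ", paste(missing, collapse = ", "))
  set.seed(seed)
  x <- scale_values[substitutions]
  data.frame(position = position, substitution = substitutions,
             ph50 = intercept + slope * x +
               stats::rnorm(length(x), 0, noise_sd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exhaustive microstate titration oracle
#'
#' Brute-force reference for small coupled-site systems: enumerates all
#' protonation microstates (at most 3 sites, 8 microstates), assigns each
#' the free energy
#' \eqn{G = \sum_i x_i \ln 10\, k_BT (pH - pK_{a,ref,i}) + \sum_{i<j} C q_i q_j / (\varepsilon_r d_{ij})}
#' (with \eqn{q_i} the site charge in microstate x: \eqn{x_i} for bases,
#' \eqn{x_i - 1} for acids), Boltzmann-averages the per-site protonation
#' over pH, and reports each site's apparent half-protonation point. With
#' no interactions this reduces exactly to Henderson-Hasselbalch.
#'
#' @param reference_pkas Numeric vector (length <= 3).
#' @param is_base Logical vector: TRUE for His/Lys-type sites.
#' @param distances Symmetric matrix of inter-site distances (A); ignored
#'   for a single site.
#' @param eps_r Relative permittivity of the medium.
#' @param constants \code{\link{pb_constants}}.
#' @param ph_grid pH values scanned.
#' @return List: \code{ph}, \code{curves} (matrix, one column per site),
#'   \code{pka_half} (per-site apparent midpoint, linear interpolation).
#' @export
microstate_titration_oracle <- function(reference_pkas, is_base,
                                        distances = NULL, eps_r = 78,
                                        constants = pb_constants(kbt = 0.593),
                                        ph_grid = seq(0, 14, by = 0.02)) {
  ns <- length(reference_pkas)
  if (ns > 3) stop("oracle limited to 3 sites (8 microstates)")
  stopifnot(length(is_base) == ns)
  states <- as.matrix(expand.grid(rep(list(0:1), ns)))
  qmat <- sweep(states, 2, ifelse(is_base, 0, 1), `-`)
  inter <- numeric(nrow(states))
  if (ns > 1) {
    for (s in seq_len(nrow(states))) {
      acc <- 0
      for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
        if (qmat[s, i] != 0 && qmat[s, j] != 0)
          acc <- acc + coulomb_energy(qmat[s, i], qmat[s, j],
                                      distances[i, j], eps_r, constants)
      }
      inter[s] <- acc
    }
  }
  kbt <- constants$kbt
  curves <- matrix(NA_real_, length(ph_grid), ns)
  for (p in seq_along(ph_grid)) {
    g <- states %*% (log(10) * kbt * (ph_grid[p] - reference_pkas)) + inter
    w <- exp(-(g - min(g)) / kbt)
    w <- w / sum(w)
    curves[p, ] <- colSums(states * as.numeric(w))
  }
  pka_half <- vapply(seq_len(ns), function(i) {
    f <- curves[, i]
    k <- which(diff(sign(f - 0.5)) != 0)
    if (!length(k)) return(NA_real_)
    k <- k[1]
    ph_grid[k] + (0.5 - f[k]) * (ph_grid[k + 1] - ph_grid[k]) / (f[k + 1] - f[k])
  }, numeric(1))
  list(ph = ph_grid, curves = curves, pka_half = pka_half)
}
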