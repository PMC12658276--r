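#' Settings bundle for pKa calculations
#'
#' Collects every tunable of the electrostatic pKa machinery in one place,
#' with defaults matching the production protocol: two-pass grid focusing
#' at 1.5 then 0.5 A, region permittivities 1/4/8/8/80, 0.15 M implicit
#' ionic strength, relevant pH 7.4 for the closed and 5.5 for the open and
#' desensitized states, and at most 10 protonation-update rounds.
#'
#' @param constants \code{\link{pb_constants}}.
#' @param region_values Region permittivities.
#' @param coarse_spacing,fine_spacing Focusing spacings in A.
#' @param padding Coarse-grid padding in A.
#' @param fine_extent Fine-grid edge length in A.
#' @param tol,maxit Solver controls.
#' @param relevant_ph Named vector of per-state relevant pH values.
#' @param max_rounds Iteration cap for the protonation-update protocol.
#' @param switch_mode \code{"all"} (every qualifying site switches per
#'   round) or \code{"one"} (only the most extreme qualifying site).
#' @return A list of class \code{pka_settings}.
#' @export
pka_settings <- function(constants = pb_constants(),
                         region_values = default_region_values(),
                         coarse_spacing = 1.5, fine_spacing = 0.5,
                         padding = 10, fine_extent = 12,
                         tol = 1e-6, maxit = 10000,
                         relevant_ph = c(closed = 7.4, open = 5.5,
                                         desensitized = 5.5),
                         max_rounds = 10,
                         switch_mode = c("all", "one")) {
  structure(list(constants = constants, region_values = region_values,
                 coarse_spacing = coarse_spacing, fine_spacing = fine_spacing,
                 padding = padding, fine_extent = fine_extent,
                 tol = tol, maxit = maxit, relevant_ph = relevant_ph,
                 max_rounds = max_rounds,
                 switch_mode = match.arg(switch_mode)),
            class = "pka_settings")
}

#' Default protonation assignment
#'
#' Round-1 states of the iterative protocol: Asp, Glu and His start in
#' their default (deprotonated / neutral-tautomer) forms, Lys starts
#' protonated.
#'
#' @param sites List of titratable sites from
#'   \code{\link{identify_titratable_sites}}.
#' @return Named character vector site_id -> state.
#' @export
default_assignment <- function(sites) {
  st <- vapply(sites, function(s)
    if (s$residue_name == "LYS") "protonated" else "deprotonated",
    character(1))
  names(st) <- vapply(sites, `[[`, character(1), "site_id")
  st
}

# atom charges with every titratable site set per `assignment`;
# zero_site: site whose titrating-group charges are zeroed (environment
# charge set for that site's evaluation).
apply_assignment_charges <- function(frame, sites, assignment,
                                     zero_site = NULL) {
  atoms <- frame$atoms
  key <- paste(atoms$chain_id, atoms$residue_id, sep = ":")
  for (s in sites) {
    st <- assignment[[s$site_id]]
    if (is.null(st) || is.na(st))
      stop("site missing from assignment: ", s$site_id)
    cs <- s$charge_sets[[st]]
    sel_res <- key == paste(s$chain_id, s$residue_id, sep = ":")
    for (an in names(cs))
      atoms$charge[sel_res & atoms$atom_name == an] <- cs[[an]]
  }
  if (!is.null(zero_site)) {
    sel_res <- key == paste(zero_site$chain_id, zero_site$residue_id, sep = ":")
    for (an in names(zero_site$charge_sets$protonated))
      atoms$charge[sel_res & atoms$atom_name == an] <- 0
  }
  atoms
}

site_group_atoms <- function(frame, site, state) {
  a <- frame$atoms
  cs <- site$charge_sets[[state]]
  sel <- a$chain_id == site$chain_id & a$residue_id == site$residue_id &
    a$atom_name %in% names(cs)
  g <- a[sel, , drop = FALSE]
  g$charge <- unname(cs[g$atom_name])
  g
}

site_residue_rows <- function(frame, site) {
  which(frame$atoms$chain_id == site$chain_id &
          frame$atoms$residue_id == site$residue_id)
}

#' Transfer free energies of a protonation state through the cycle
#'
#' Computes the electrostatic free energy of the site's titrating-group
#' charges in two contexts on identically aligned grids: (i) the protein
#' leg, with the full frame carving the dielectric map, all other charges
#' (background plus other titratable sites at their current assignment)
#' generating an environment potential, and the membrane slab if present;
#' (ii) the water leg, where the excised residue keeps its own
#' low-dielectric cavity but sits in pure solvent with no environment
#' charges. Identical spacing, alignment and local dielectric make the
#' grid self-energies cancel in the protein-minus-water difference.
#'
#' @param frame \code{\link{structure_frame}}.
#' @param site A titratable site.
#' @param state \code{"protonated"} or \code{"deprotonated"}.
#' @param assignment Current protonation assignment (all sites).
#' @param sites All titratable sites of the frame.
#' @param membrane \code{membrane_geometry} or \code{NULL}.
#' @param settings \code{\link{pka_settings}}.
#' @param env_potential Optional precomputed environment potential (a
#'   \code{potential_grid}) to reuse across the two states.
#' @return List with \code{protein} and \code{water} energies (kcal/mol)
#'   and the \code{env_potential} used.
#' @export
transfer_free_energy <- function(frame, site, state, assignment, sites,
                                 membrane = NULL, settings = pka_settings(),
                                 env_potential = NULL) {
  state <- match.arg(state, c("protonated", "deprotonated"))
  group <- site_group_atoms(frame, site, state)
  center <- colMeans(group[, c("x", "y", "z")])
  cst <- settings$constants

  # environment potential: all charges except the titrating group itself
  if (is.null(env_potential)) {
    env_atoms <- apply_assignment_charges(frame, sites, assignment,
                                          zero_site = site)
    env_charges <- env_atoms[env_atoms$charge != 0, , drop = FALSE]
    env_potential <- if (nrow(env_charges)) {
      focused_solve(env_charges, frame, membrane, cst,
                    settings$coarse_spacing, settings$fine_spacing,
                    settings$padding, center, settings$fine_extent,
                    settings$region_values, tol = settings$tol,
                    maxit = settings$maxit)
    } else NULL
  }
  g_inter <- if (!is.null(env_potential)) {
    sum(group$charge * interp_grid(env_potential$phi, env_potential$grid,
                                   group[, c("x", "y", "z")]))
  } else 0

  # self (reaction-field) energies of the group charges
  pot_prot <- focused_solve(group, frame, membrane, cst,
                            settings$coarse_spacing, settings$fine_spacing,
                            settings$padding, center, settings$fine_extent,
                            settings$region_values, tol = settings$tol,
                            maxit = settings$maxit)
  g_self_prot <- electrostatic_free_energy(pot_prot, group)

  model <- structure_frame(frame$atoms[site_residue_rows(frame, site), ,
                                       drop = FALSE],
                           frame_label = paste0("model:", site$site_id))
  pot_model <- focused_solve(group, model, NULL, cst,
                             settings$coarse_spacing, settings$fine_spacing,
                             settings$padding, center, settings$fine_extent,
                             settings$region_values, tol = settings$tol,
                             maxit = settings$maxit)
  g_self_model <- electrostatic_free_energy(pot_model, group)

  list(protein = g_self_prot + g_inter, water = g_self_model,
       env_potential = env_potential)
}

#' Single-site pKa from the thermodynamic cycle
#'
#' \deqn{pK_a = pK_{a,ref} + \frac{(G_d - G_p)_{prot} - (G_d - G_p)_{water}}{\ln 10 \, k_B T}}
#' where \eqn{G_p}, \eqn{G_d} are the electrostatic free energies of the
#' protonated and deprotonated group in the protein and water legs. An
#' environment that stabilizes the protonated form raises the pKa.
#'
#' @inheritParams transfer_free_energy
#' @return pKa in pH units.
#' @export
site_pka <- function(frame, site, assignment, sites, membrane = NULL,
                     settings = pka_settings()) {
  tp <- transfer_free_energy(frame, site, "protonated", assignment, sites,
                             membrane, settings)
  td <- transfer_free_energy(frame, site, "deprotonated", assignment, sites,
                             membrane, settings,
                             env_potential = tp$env_potential)
  ddG <- (td$protein - tp$protein) - (td$water - tp$water)
  site$reference_pka + ddG / (log(10) * settings$constants$kbt)
}

#' Ensemble-averaged pKa of a site
#'
#' Averages the single-site pKa over every frame of the ensemble and every
#' equivalent subunit copy of the site (for a trimer sampled at five time
#' points, n = 5 x 3 = 15). Failed samples are recorded as missing with a
#' warning and reduce n.
#'
#' @param ensemble \code{\link{frame_ensemble}}.
#' @param site_ids Character vector of equivalent site identifiers (the
#'   same residue on each subunit).
#' @param assignment Protonation assignment covering all sites.
#' @param membrane \code{NULL}, a fixed \code{membrane_geometry}, or
#'   \code{"auto"} to estimate the slab per frame from the marker atoms.
#' @param settings \code{\link{pka_settings}}.
#' @return A list of class \code{pka_estimate}: \code{site} (first id),
#'   \code{equivalent_sites}, \code{mean_pka}, \code{sd}, \code{n},
#'   \code{samples} (per frame x subunit).
#' @export
ensemble_pka <- function(ensemble, site_ids, assignment, membrane = NULL,
                         settings = pka_settings()) {
  samples <- c()
  for (fr in ensemble$frames) {
    memb <- membrane
    if (identical(membrane, "auto"))
      memb <- tryCatch(estimate_membrane_geometry(fr), error = function(e) NULL)
    sites <- identify_titratable_sites(fr)
    by_id <- stats::setNames(sites, vapply(sites, `[[`, "", "site_id"))
    for (sid in site_ids) {
      s <- by_id[[sid]]
      if (is.null(s)) stop("site not present in frame: ", sid)
      val <- tryCatch(site_pka(fr, s, assignment, sites, memb, settings),
                      error = function(e) {
                        warning(sprintf("pKa sample failed for %s in %s: %s",
                                        sid, fr$frame_label,
                                        conditionMessage(e)))
                        NA_real_
                      })
      samples <- c(samples, stats::setNames(val, paste(fr$frame_label, sid,
                                                       sep = "/")))
    }
  }
  ok <- samples[!is.na(samples)]
  structure(list(site = site_ids[1], equivalent_sites = site_ids,
                 mean_pka = mean(ok), sd = stats::sd(ok), n = length(ok),
                 samples = samples),
            class = "pka_estimate")
}
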