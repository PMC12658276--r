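#' Update a protonation assignment against the relevant pH
#'
#' Applies the round-update rule: every currently-deprotonated Asp, Glu or
#' His whose ensemble mean pKa lies above the relevant pH becomes
#' protonated, and every currently-protonated Lys whose mean pKa lies
#' below the relevant pH becomes deprotonated; all other sites are left
#' unchanged. In \code{"one"} mode only the single qualifying site with
#' the largest |pKa - relevant pH| switches.
#'
#' @param pka_table Data frame with columns \code{site_id},
#'   \code{residue_name}, \code{mean_pka}.
#' @param relevant_ph The state's relevant pH (7.4 closed, 5.5 open and
#'   desensitized by default).
#' @param assignment Named character vector site_id -> state.
#' @param switch_mode \code{"all"} or \code{"one"}.
#' @return List with \code{assignment} (updated) and \code{changed_sites}.
#' @export
update_assignment <- function(pka_table, relevant_ph, assignment,
                              switch_mode = c("all", "one")) {
  switch_mode <- match.arg(switch_mode)
  missing <- setdiff(pka_table$site_id, names(assignment))
  if (length(missing))
    stop("sites in pKa table absent from assignment: ",
         paste(missing, collapse = ", "))
  acid_like <- pka_table$residue_name %in% c("ASP", "GLU", "HIS")
  to_prot <- acid_like & pka_table$mean_pka > relevant_ph &
    assignment[pka_table$site_id] == "deprotonated"
  to_deprot <- pka_table$residue_name == "LYS" &
    pka_table$mean_pka < relevant_ph &
    assignment[pka_table$site_id] == "protonated"
  qualifying <- which(to_prot | to_deprot)
  if (switch_mode == "one" && length(qualifying) > 1L) {
    dev <- abs(pka_table$mean_pka[qualifying] - relevant_ph)
    qualifying <- qualifying[which.max(dev)]
  }
  changed <- pka_table$site_id[qualifying]
  for (i in qualifying) {
    assignment[pka_table$site_id[i]] <-
      if (to_prot[i]) "protonated" else "deprotonated"
  }
  list(assignment = assignment, changed_sites = changed)
}

#' Run the iterative protonation-update protocol
#'
#' Round 1 computes ensemble pKas for every site under the all-default
#' assignment (Asp/Glu deprotonated, His neutral, Lys protonated). After
#' each round the assignment is updated against the state's relevant pH;
#' sites whose state was adjusted keep the pKa of the round immediately
#' preceding the adjustment and are not re-evaluated. Rounds continue
#' until no site changes or \code{max_rounds} is hit, in which case the
#' report carries \code{converged = FALSE} rather than an error.
#'
#' @param ensemble_provider Function taking a protonation assignment and
#'   returning a \code{\link{frame_ensemble}} (an MD engine stand-in, a
#'   loader of precomputed ensembles, or the synthetic jitter generator).
#' @param state Conformational state label; selects the relevant pH.
#' @param site_groups List of character vectors, each the equivalent
#'   subunit copies of one site (as from
#'   \code{\link{equivalent_site_groups}}).
#' @param membrane Membrane treatment passed to \code{\link{ensemble_pka}}.
#' @param settings \code{\link{pka_settings}}.
#' @return A list of class \code{convergence_report}: \code{rounds} (each
#'   with \code{round_index}, \code{pka_table}, \code{assignment_before},
#'   \code{assignment_after}, \code{changed_sites}), \code{converged},
#'   \code{final_pka_table}, \code{state}.
#' @export
run_iteration <- function(ensemble_provider, state = "closed", site_groups,
                          membrane = NULL, settings = pka_settings()) {
  relevant_ph <- settings$relevant_ph[[state]]
  ens0 <- ensemble_provider(NULL)
  sites0 <- identify_titratable_sites(ens0$frames[[1]])
  assignment <- default_assignment(sites0)
  frozen <- stats::setNames(rep(NA_real_, length(site_groups)),
                            vapply(site_groups, `[`, "", 1))
  frozen_sd <- frozen; frozen_n <- frozen; frozen_round <- frozen
  rounds <- list()
  converged <- FALSE
  for (r in seq_len(settings$max_rounds)) {
    ens <- ensemble_provider(assignment)
    active <- names(frozen)[is.na(frozen)]
    rows <- list()
    for (g in site_groups) {
      if (!(g[1] %in% active)) next
      est <- ensemble_pka(ens, g, assignment, membrane, settings)
      lead <- strsplit(g[1], ":")[[1]]
      rows[[g[1]]] <- data.frame(site_id = g[1], residue_name = lead[3],
                                 mean_pka = est$mean_pka, sd = est$sd,
                                 n = est$n, stringsAsFactors = FALSE)
    }
    if (!length(rows)) { converged <- TRUE; break }
    pka_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    before <- assignment
    upd <- update_assignment(pka_table, relevant_ph, assignment,
                             settings$switch_mode)
    # adjusted sites: freeze the value of this round (the last before the
    # adjustment) and mirror the switch onto the equivalent subunit copies
    for (sid in upd$changed_sites) {
      frozen[sid] <- pka_table$mean_pka[pka_table$site_id == sid]
      frozen_sd[sid] <- pka_table$sd[pka_table$site_id == sid]
      frozen_n[sid] <- pka_table$n[pka_table$site_id == sid]
      frozen_round[sid] <- r
      grp <- site_groups[[which(vapply(site_groups, `[`, "", 1) == sid)]]
      upd$assignment[grp] <- upd$assignment[sid]
    }
    assignment <- upd$assignment
    rounds[[r]] <- list(round_index = r, pka_table = pka_table,
                        assignment_before = before,
                        assignment_after = assignment,
                        changed_sites = upd$changed_sites)
    if (!length(upd$changed_sites)) { converged <- TRUE; break }
  }
  last_table <- rounds[[length(rounds)]]$pka_table
  final_rows <- list()
  for (g in site_groups) {
    sid <- g[1]
    if (!is.na(frozen[sid])) {
      final_rows[[sid]] <- data.frame(site_id = sid,
                                      residue_name = strsplit(sid, ":")[[1]][3],
                                      mean_pka = frozen[sid], sd = frozen_sd[sid],
                                      n = frozen_n[sid],
                                      from_round = frozen_round[sid],
                                      adjusted = TRUE, stringsAsFactors = FALSE)
    } else {
      row <- last_table[last_table$site_id == sid, , drop = FALSE]
      row$from_round <- length(rounds)
      row$adjusted <- FALSE
      final_rows[[sid]] <- row
    }
  }
  final <- do.call(rbind, c(final_rows, list(make.row.names = FALSE)))
  structure(list(rounds = rounds, converged = converged,
                 final_pka_table = final, state = state,
                 final_assignment = assignment),
            class = "convergence_report")
}

#' Group equivalent subunit copies of each titratable site
#'
#' Sites with the same residue name and residue id on different chains are
#' symmetry-equivalent copies in a homomultimer and are averaged together
#' in the ensemble pKa.
#'
#' @param sites List from \code{\link{identify_titratable_sites}}.
#' @return List of character vectors of site ids.
#' @export
equivalent_site_groups <- function(sites) {
  key <- vapply(sites, function(s)
    paste(s$residue_name, s$residue_id, sep = ":"), character(1))
  ids <- vapply(sites, `[[`, character(1), "site_id")
  unname(lapply(split(ids, key), unname))
}
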