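#' Henderson-Hasselbalch protonation fraction
#'
#' \eqn{f(\mathrm{prot}) = 1/(1 + 10^{pH - pK_a})}: the probability that a
#' titratable site carries its proton at the given pH.
#'
#' @param pka pKa in pH units.
#' @param ph pH.
#' @return Fraction in [0, 1].
#' @examples
#' round(protonation_fraction(6.24, 6.0), 2)  # 0.63
#' round(protonation_fraction(7.81, 6.8), 2)  # 0.91
#' @export
protonation_fraction <- function(pka, ph) {
  stopifnot(is.finite(pka), is.finite(ph))
  1 / (1 + 10^(ph - pka))
}

#' Protonation-fraction table across the gating transitions
#'
#' For every site, the protonated fraction at the five (structure, pH)
#' conditions spanning activation and steady-state desensitization (SSD):
#' closed structure at pH 7.4 (rest), closed structure at the activation
#' pH (start of activation), open structure at the activation pH (end of
#' activation), closed structure at the SSD pH (start of SSD), and
#' desensitized structure at the SSD pH (end of SSD).
#'
#' @param pka_closed,pka_open,pka_desensitized Data frames with columns
#'   \code{site_id} and \code{mean_pka} (one row per site; all three must
#'   share the site list).
#' @param ph_conditions Named numeric: \code{rest} (default 7.4),
#'   \code{activation} (6.0), \code{ssd} (6.8).
#' @return Data frame of class \code{fprot_table} with columns
#'   \code{site_id}, \code{f_closed}, \code{f_start_activation},
#'   \code{f_end_activation}, \code{f_start_ssd}, \code{f_end_ssd}, plus
#'   \code{complete} flagging rows with all three pKas available.
#' @export
fprot_table <- function(pka_closed, pka_open, pka_desensitized,
                        ph_conditions = c(rest = 7.4, activation = 6.0,
                                          ssd = 6.8)) {
  ids <- pka_closed$site_id
  m <- function(tab) tab$mean_pka[match(ids, tab$site_id)]
  pc <- m(pka_closed); po <- m(pka_open); pd <- m(pka_desensitized)
  out <- data.frame(
    site_id = ids,
    f_closed = protonation_fraction_vec(pc, ph_conditions[["rest"]]),
    f_start_activation = protonation_fraction_vec(pc, ph_conditions[["activation"]]),
    f_end_activation = protonation_fraction_vec(po, ph_conditions[["activation"]]),
    f_start_ssd = protonation_fraction_vec(pc, ph_conditions[["ssd"]]),
    f_end_ssd = protonation_fraction_vec(pd, ph_conditions[["ssd"]]),
    stringsAsFactors = FALSE
  )
  out$complete <- !is.na(po) & !is.na(pd) & !is.na(pc)
  if (any(!out$complete))
    warning("incomplete rows (site missing in a state): ",
            paste(ids[!out$complete], collapse = ", "))
  class(out) <- c("fprot_table", class(out))
  out
}

protonation_fraction_vec <- function(pka, ph) {
  ifelse(is.na(pka), NA_real_, 1 / (1 + 10^(ph - pka)))
}

#' Rank candidate pH sensors from two state pKa tables
#'
#' Two criteria: (1) the pKas from the closed and target states are both
#' within [5, 8], or straddle it (one below 5 and the other above 8) --
#' the range in which a protonation change during the transition is
#' plausible; (2) the amplitude of the pKa change between the states,
#' min-max scaled across the analyzed residues. The score is a weighted
#' sum of the two; ties break by |delta pKa|, then input site order.
#'
#' @param pka_closed,pka_target Data frames with \code{site_id},
#'   \code{mean_pka}.
#' @param weights Named numeric \code{c(range = 1, delta = 1)}.
#' @param range_bounds The relevant pKa window, default \code{c(5, 8)}.
#' @return Data frame with \code{site_id}, \code{pka_closed},
#'   \code{pka_target}, \code{in_range}, \code{delta_pka},
#'   \code{scaled_delta}, \code{score}, \code{rank}, sorted by descending
#'   score.
#' @export
rank_sensors <- function(pka_closed, pka_target,
                         weights = c(range = 1, delta = 1),
                         range_bounds = c(5, 8)) {
  if (!nrow(pka_closed)) stop("empty pKa table")
  ids <- sort(pka_closed$site_id)
  pc <- pka_closed$mean_pka[match(ids, pka_closed$site_id)]
  pt <- pka_target$mean_pka[match(ids, pka_target$site_id)]
  if (any(is.na(pt))) stop("tables do not share the site list")
  lo <- range_bounds[1]; hi <- range_bounds[2]
  both_in <- pc >= lo & pc <= hi & pt >= lo & pt <= hi
  straddle <- (pc < lo & pt > hi) | (pt < lo & pc > hi)
  in_range <- both_in | straddle
  delta <- pt - pc
  spread <- diff(range(abs(delta)))
  scaled <- if (spread > 0) (abs(delta) - min(abs(delta))) / spread
            else rep(0, length(delta))
  score <- weights[["range"]] * as.numeric(in_range) +
    weights[["delta"]] * scaled
  out <- data.frame(site_id = ids, pka_closed = pc, pka_target = pt,
                    in_range = in_range, delta_pka = delta,
                    scaled_delta = scaled, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -abs(out$delta_pka), seq_len(nrow(out))), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify drivers and stabilizers of a transition
#'
#' A residue whose protonation fraction changes at the moment of
#' acidification (closed structure, rest pH versus transition pH) may
#' drive the transition; one whose fraction changes only once the new
#' conformation is reached (rest condition versus end-of-transition
#' condition) may stabilize it. Both use the absolute change with a
#' default threshold of 0.15, and a residue can be both.
#'
#' @param fprot A \code{\link{fprot_table}}.
#' @param transition \code{"activation"} or \code{"ssd"}.
#' @param threshold |delta f| threshold (default 0.15).
#' @return Data frame with \code{site_id}, \code{transition},
#'   \code{delta_f_start}, \code{delta_f_end}, \code{driver},
#'   \code{stabilizer}.
#' @export
classify_driver_stabilizer <- function(fprot,
                                       transition = c("activation", "ssd"),
                                       threshold = 0.15) {
  transition <- match.arg(transition)
  cols <- if (transition == "activation")
    c("f_start_activation", "f_end_activation")
  else c("f_start_ssd", "f_end_ssd")
  keep <- if ("complete" %in% names(fprot)) fprot$complete else TRUE
  skipped <- fprot$site_id[!keep]
  if (length(skipped))
    warning("skipping incomplete rows: ", paste(skipped, collapse = ", "))
  f <- fprot[keep, , drop = FALSE]
  dstart <- f[[cols[1]]] - f$f_closed
  dend <- f[[cols[2]]] - f$f_closed
  data.frame(site_id = f$site_id, transition = transition,
             delta_f_start = dstart, delta_f_end = dend,
             driver = abs(dstart) >= threshold,
             stabilizer = abs(dend) >= threshold,
             stringsAsFactors = FALSE)
}
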