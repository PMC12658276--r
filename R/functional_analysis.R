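#' Fit a pH dose-response curve to the Hill equation
#'
#' Activation curves are fitted to
#' \deqn{I = I_{max} / [1 + (10^{-pH_{50}} / 10^{-pH})^{n_H}]}
#' i.e. current rising as the pH falls. Steady-state desensitization (SSD)
#' curves use the analogous form with the response falling as the
#' conditioning pH falls (an availability curve), and the fitted midpoint
#' is reported as pHD50. Fitting is nonlinear least squares
#' (Levenberg-Marquardt) started from the linearly interpolated half-max
#' crossing, \eqn{n_H = 1} and \eqn{I_{max} = \max} response.
#'
#' @param ph Numeric vector of pH values (>= 5 points).
#' @param response Normalized current at each pH.
#' @param transition \code{"activation"} or \code{"ssd"}.
#' @param weights Optional fitting weights (e.g. 1/sem^2).
#' @return A list of class \code{hill_fit}: \code{ph50} (named
#'   \code{phd50} semantics for SSD), \code{n_h}, \code{i_max}, their
#'   standard errors (\code{se}), \code{transition}, \code{converged},
#'   \code{fitted}, \code{residual_sd}.
#' @export
fit_hill <- function(ph, response, transition = c("activation", "ssd"),
                     weights = NULL) {
  transition <- match.arg(transition)
  stopifnot(length(ph) == length(response))
  if (length(ph) < 5L)
    stop("need at least 5 pH points for a Hill fit")
  if (diff(range(response)) < 1e-12)
    stop("degenerate flat curve: response carries no pH dependence")
  half <- max(response) / 2
  ord <- order(ph)
  ph_o <- ph[ord]; r_o <- response[ord]
  cross <- which(diff(sign(r_o - half)) != 0)
  ph50_0 <- if (length(cross)) {
    i <- cross[1]
    ph_o[i] + (half - r_o[i]) * (ph_o[i + 1] - ph_o[i]) / (r_o[i + 1] - r_o[i])
  } else stats::median(ph)
  if (!any(r_o < half) || !any(r_o > half))
    warning("data do not span both sides of the midpoint; fit may be poorly constrained")
  sgn <- if (transition == "activation") 1 else -1
  dat <- data.frame(ph = ph, response = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ imax / (1 + 10^(sgn * nh * (ph - ph50))),
      data = dat,
      start = list(imax = max(response), ph50 = ph50_0, nh = 1),
      lower = c(imax = 1e-6, ph50 = min(ph) - 2, nh = 0.05),
      upper = c(imax = 10, ph50 = max(ph) + 2, nh = 10),
      weights = if (is.null(weights)) rep(1, length(ph)) else weights,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ph50 = NA_real_, n_h = NA_real_, i_max = NA_real_,
                          se = c(i_max = NA, ph50 = NA, n_h = NA),
                          transition = transition, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  cf <- summary(fit)$coefficients
  structure(list(
    ph50 = unname(cf["ph50", "Estimate"]),
    n_h = unname(cf["nh", "Estimate"]),
    i_max = unname(cf["imax", "Estimate"]),
    se = c(i_max = cf["imax", "Std. Error"], ph50 = cf["ph50", "Std. Error"],
           n_h = cf["nh", "Std. Error"]),
    transition = transition,
    converged = TRUE,
    fitted = stats::fitted(fit),
    residual_sd = summary(fit)$sigma
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$transition == "ssd") "pHD50" else "pH50"
  if (!x$converged) { cat("Hill fit: not converged\n"); return(invisible(x)) }
  cat(sprintf("Hill fit (%s): %s = %.3f +/- %.3f, nH = %.2f +/- %.2f, Imax = %.3f\n",
              x$transition, lab, x$ph50, x$se[["ph50"]], x$n_h,
              x$se[["n_h"]], x$i_max))
  invisible(x)
}

#' Midpoint shift of a mutant relative to wild type
#'
#' \eqn{\Delta pH_{50} = pH_{50}(\mathrm{mutant}) - pH_{50}(\mathrm{WT})},
#' with the standard error propagated in quadrature.
#'
#' @param mutant_fit,wt_fit Converged \code{\link{fit_hill}} results for
#'   the same transition.
#' @return List with \code{delta}, \code{se}, \code{transition}.
#' @export
delta_ph50 <- function(mutant_fit, wt_fit) {
  if (!isTRUE(mutant_fit$converged) || !isTRUE(wt_fit$converged))
    stop("both Hill fits must have converged")
  if (!identical(mutant_fit$transition, wt_fit$transition))
    stop("fits are for different transitions")
  list(delta = mutant_fit$ph50 - wt_fit$ph50,
       se = sqrt(mutant_fit$se[["ph50"]]^2 + wt_fit$se[["ph50"]]^2),
       transition = mutant_fit$transition)
}

#' Classify the size of a midpoint shift
#'
#' Bins |delta pH50| as weak [0.08, 0.2), moderate [0.2, 0.3) or strong
#' (>= 0.3); below 0.08 the effect is "none". A mutation is functionally
#' important when |delta pH50| >= 0.2 or |delta pHD50| >= 0.15.
#'
#' @param delta_ph50 Activation midpoint shift (pH units), or NA.
#' @param delta_phd50 SSD midpoint shift, or NA.
#' @return List with \code{bin} (from the activation shift) and
#'   \code{functionally_important}.
#' @export
classify_effect <- function(delta_ph50 = NA, delta_phd50 = NA) {
  if (is.na(delta_ph50) && is.na(delta_phd50))
    stop("provide at least one midpoint shift")
  bin <- if (is.na(delta_ph50)) NA_character_ else {
    a <- abs(delta_ph50)
    if (a >= 0.3) "strong" else if (a >= 0.2) "moderate"
    else if (a >= 0.08) "weak" else "none"
  }
  fi <- (!is.na(delta_ph50) && abs(delta_ph50) >= 0.2) ||
    (!is.na(delta_phd50) && abs(delta_phd50) >= 0.15)
  list(bin = bin, functionally_important = fi)
}

#' Double-mutant-cycle coupling
#'
#' Two residues interact when the effect of the double mutation differs
#' from the sum of the two single-mutation effects:
#' \eqn{\mathrm{coupling} = \Delta(AB) - [\Delta(A) + \Delta(B)]}, with SE
#' propagated in quadrature. The verdict is "non-additive" when
#' |coupling| exceeds z times its SE (z = 1.96 by default).
#'
#' @param single_a,single_b,double_ab Lists with \code{delta} and
#'   \code{se} (as from \code{\link{delta_ph50}}).
#' @param z Normal quantile for the additivity test.
#' @return List with \code{coupling}, \code{se}, \code{non_additive}.
#' @export
mutant_cycle_coupling <- function(single_a, single_b, double_ab, z = 1.96) {
  for (r in list(single_a, single_b, double_ab))
    if (is.null(r$delta) || is.na(r$delta)) stop("missing mutant record")
  coupling <- double_ab$delta - (single_a$delta + single_b$delta)
  se <- sqrt(sum(c(single_a$se, single_b$se, double_ab$se)^2, na.rm = TRUE))
  list(coupling = coupling, se = se,
       non_additive = is.finite(se) && se > 0 && abs(coupling) > z * se)
}

#' Load the side-chain property scales
#'
#' Twelve per-amino-acid scales (bulkiness, flexibility, H-bond
#' donor/acceptor counts, hydropathy, polarity, helix/sheet/turn/coil
#' propensities, size, surface area) transcribed from the published
#' scales named in the data file header. Replace the CSV to use other
#' conventions.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Data frame with \code{amino_acid} (one-letter code) plus one
#'   column per scale.
#' @export
load_property_scales <- function(path = system.file("extdata",
                                                    "property_scales.csv",
                                                    package = "pbpka")) {
  sc <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(sc) != 20L) stop("property scale table must have 20 amino acids")
  sc
}

#' Regress midpoints against a side-chain property scale
#'
#' Ordinary least squares of the measured pH50 (or pHD50) of a
#' substitution panel at one position on a side-chain property of the
#' substituted residue, with the two-sided p-value for a nonzero slope.
#' At least 4 distinct substitutions with finite responses are required.
#'
#' @param panel Data frame with columns \code{substitution} (one-letter
#'   amino-acid code) and the response column.
#' @param scale_values Named numeric: property value per one-letter code
#'   (one column of \code{\link{load_property_scales}} named by
#'   \code{amino_acid}).
#' @param response Column of \code{panel} to regress (default
#'   \code{"ph50"}).
#' @param min_variants Minimum panel size (default 4).
#' @return List of class \code{property_regression}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{n}.
#' @export
property_regression <- function(panel, scale_values, response = "ph50",
                                min_variants = 4) {
  y <- panel[[response]]
  keep <- is.finite(y)
  panel <- panel[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(panel) < min_variants)
    stop(sprintf("property regression needs at least %d variants with finite %s; got %d",
                 min_variants, response, nrow(panel)))
  xv <- scale_values[panel$substitution]
  if (any(is.na(xv)))
    stop("substitution absent from scale: ",
         paste(panel$substitution[is.na(xv)], collapse = ", "))
  if (stats::var(xv) < 1e-12)
    stop("degenerate predictor: zero variance in scale values")
  fit <- stats::lm(y ~ xv)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(y)),
            class = "property_regression")
}

#' Batch regression over all property scales
#'
#' Runs \code{\link{property_regression}} independently for each scale
#' column of the property table, optionally with Holm correction across
#' the scales (the default reports raw p-values).
#'
#' @inheritParams property_regression
#' @param scales Property table from \code{\link{load_property_scales}}.
#' @param holm Apply Holm correction across scales (default FALSE).
#' @return Data frame with one row per scale: \code{scale}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{n}.
#' @export
property_regression_batch <- function(panel, scales = load_property_scales(),
                                      response = "ph50", min_variants = 4,
                                      holm = FALSE) {
  cols <- setdiff(names(scales), "amino_acid")
  rows <- lapply(cols, function(cn) {
    sv <- stats::setNames(scales[[cn]], scales$amino_acid)
    r <- property_regression(panel, sv, response, min_variants)
    data.frame(scale = cn, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_adjusted <- stats::p.adjust(out$p_value, "holm")
  rownames(out) <- NULL
  out
}
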