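hill_curve <- function(ph, ph50, nh, imax, transition = "activation") {
  sgn <- if (transition == "activation") 1 else -1
  imax / (1 + 10^(sgn * nh * (ph - ph50)))
}

test_that("noiseless Hill curves are inverted exactly", {
  ph <- seq(5, 7.4, 0.3)
  fit <- fit_hill(ph, hill_curve(ph, 6.2, 1.5, 1))
  expect_true(fit$converged)
  expect_equal(fit$ph50, 6.2, tolerance = 1e-6)
  expect_equal(fit$n_h, 1.5, tolerance = 1e-6)
  expect_equal(fit$i_max, 1, tolerance = 1e-6)
  # midpoint identity: the model at pH50 is half the amplitude
  expect_equal(hill_curve(6.2, 6.2, 1.5, 1), 0.5)
  # SSD availability curve: response falls as the conditioning pH falls
  resp <- hill_curve(ph, 7.0, 2, 1, "ssd")
  expect_true(all(diff(resp[order(ph)]) > 0))
  fs <- fit_hill(ph, resp, transition = "ssd")
  expect_equal(fs$ph50, 7.0, tolerance = 1e-6)
  expect_equal(fs$n_h, 2, tolerance = 1e-5)
})

test_that("Hill fit recovers the midpoint from noisy data", {
  ph <- seq(5, 7.6, 0.2)
  errs <- vapply(1:100, function(s) {
    dr <- simulate_dose_response(6.2, 1.5, 1, ph, noise_sd = 0.02,
                                 n_replicates = 1, seed = s)
    fit <- fit_hill(dr$ph, dr$response)
    if (!fit$converged) return(Inf)
    abs(fit$ph50 - 6.2)
  }, numeric(1))
  expect_gte(mean(errs < 0.05), 0.95)
})

test_that("Hill fit is invariant to uniform response rescaling", {
  ph <- seq(5, 7.4, 0.25)
  set.seed(5)
  resp <- hill_curve(ph, 6.3, 1.2, 1) + rnorm(length(ph), 0, 0.01)
  f1 <- fit_hill(ph, resp)
  f2 <- fit_hill(ph, 0.5 * resp)
  expect_equal(f2$ph50, f1$ph50, tolerance = 1e-6)
  expect_equal(f2$n_h, f1$n_h, tolerance = 1e-6)
  expect_equal(f2$i_max, 0.5 * f1$i_max, tolerance = 1e-6)
})

test_that("degenerate and undersampled curves are refused", {
  expect_error(fit_hill(c(5, 6, 7), c(1, 0.5, 0)), "5")
  ph <- seq(5, 7, 0.25)
  expect_error(fit_hill(ph, rep(0.7, length(ph))), "flat")
})

test_that("midpoint shifts subtract with quadrature errors", {
  mk <- function(ph50, se) structure(list(ph50 = ph50, n_h = 1, i_max = 1,
    se = c(i_max = 0.01, ph50 = se, n_h = 0.05), transition = "activation",
    converged = TRUE), class = "hill_fit")
  d <- delta_ph50(mk(6.0, 0.02), mk(6.3, 0.02))
  expect_equal(d$delta, -0.3)
  expect_equal(d$se, sqrt(2) * 0.02, tolerance = 1e-9)
  expect_equal(delta_ph50(mk(6.1, 0.02), mk(6.1, 0.02))$delta, 0)
  bad <- mk(6, 0.02); bad$converged <- FALSE
  expect_error(delta_ph50(bad, mk(6.3, 0.02)), "converged")
})

test_that("effect classes use the printed closed/open bin edges", {
  expect_equal(classify_effect(-0.55)$bin, "strong")
  expect_equal(classify_effect(-0.10)$bin, "weak")
  expect_false(classify_effect(-0.10)$functionally_important)
  # boundary values land in the higher-|shift| bin
  expect_equal(classify_effect(0.08)$bin, "weak")
  expect_equal(classify_effect(0.2)$bin, "moderate")
  expect_equal(classify_effect(0.3)$bin, "strong")
  expect_equal(classify_effect(0.0799)$bin, "none")
  expect_true(classify_effect(0.2)$functionally_important)
  expect_false(classify_effect(0.19, -0.14)$functionally_important)
  expect_true(classify_effect(delta_phd50 = -0.16)$functionally_important)
  expect_error(classify_effect(), "at least one")
})

test_that("mutant-cycle coupling measures non-additivity symmetrically", {
  r <- function(d, se = 0.03) list(delta = d, se = se)
  add <- mutant_cycle_coupling(r(-0.2), r(-0.3), r(-0.5))
  expect_equal(add$coupling, 0)
  expect_false(add$non_additive)
  cp <- mutant_cycle_coupling(r(-0.2), r(-0.3), r(-0.25))
  expect_equal(cp$coupling, 0.25)
  expect_equal(cp$se, sqrt(3) * 0.03, tolerance = 1e-9)
  expect_true(cp$non_additive)
  sw <- mutant_cycle_coupling(r(-0.3), r(-0.2), r(-0.25))
  expect_equal(sw$coupling, cp$coupling)
  expect_error(mutant_cycle_coupling(r(NA), r(-0.2), r(-0.25)), "missing")
})

test_that("the property table carries 12 complete scales", {
  sc <- load_property_scales()
  expect_equal(nrow(sc), 20)
  expect_setequal(setdiff(names(sc), "amino_acid"),
                  c("bulkiness", "flexibility", "hydrogen_acceptor",
                    "hydrogen_donor", "hydropathy", "polarity",
                    "alpha_propensity", "beta_propensity", "turn_propensity",
                    "coil_propensity", "size", "surface"))
  expect_false(anyNA(sc))
})

test_that("property regression recovers planted dependence and guards inputs", {
  sc <- load_property_scales()
  sv <- stats::setNames(sc$hydropathy, sc$amino_acid)
  panel <- simulate_mutant_panel("K374", c("A", "Q", "M", "E", "R", "C", "I"),
                                 sv, slope = 0.05, intercept = 6, noise_sd = 0,
                                 seed = 1)
  r <- suppressWarnings(property_regression(panel, sv))  # exact fit flags lm
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope, 0.05, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$n, 7)
  expect_error(property_regression(panel[1:3, ], sv), "4")
  expect_error(property_regression(panel, stats::setNames(rep(1, 20),
                                                          sc$amino_acid)),
               "degenerate")
  expect_error(property_regression(transform(panel, substitution = "Z"), sv),
               "absent")
})

test_that("batch regression covers all 12 scales with one n", {
  sc <- load_property_scales()
  sv <- stats::setNames(sc$size, sc$amino_acid)
  panel <- simulate_mutant_panel("K374", c("A", "Q", "M", "E", "R", "C"),
                                 sv, slope = 0.002, intercept = 6,
                                 noise_sd = 0.05, seed = 9)
  res <- property_regression_batch(panel)
  expect_equal(nrow(res), 12)
  expect_equal(unique(res$n), 6)
  holm <- property_regression_batch(panel, holm = TRUE)
  expect_true(all(holm$p_adjusted >= holm$p_value))
})

test_that("regression p-values are uniform under the null", {
  sc <- load_property_scales()
  sv <- stats::setNames(sc$polarity, sc$amino_acid)
  subs <- c("A", "Q", "M", "E", "R", "C", "I", "S")
  pvals <- vapply(1:500, function(s) {
    panel <- simulate_mutant_panel("X", subs, sv, slope = 0, intercept = 6,
                                   noise_sd = 0.1, seed = s)
    property_regression(panel, sv)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
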