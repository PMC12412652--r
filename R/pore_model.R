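## pore_model: dose-response analytics (release percent, 4PL IC50) and an
## equilibrium reading of the concentration-threshold activation/inhibition
## mechanism, including the alpha-9 intramolecular competition of
## full-length BAX.

#' Release percent from raw fluorescence
#'
#' Normalizes a fluorescence reading between the buffer-plus-liposomes
#' control (Fmin, 0 percent) and the detergent control (Fmax, 100 percent).
#' Values outside `[0, 100]` are flagged; a clamped copy is provided
#' alongside the raw value.
#'
#' @param F Fluorescence reading(s).
#' @param Fmin,Fmax Controls; `Fmax > Fmin`.
#' @return data.frame with `raw`, `clamped`, `out_of_range`.
#' @export
release_percent <- function(F, Fmin, Fmax) {
  if (Fmax <= Fmin) stop("Fmax must exceed Fmin")
  raw <- 100 * (F - Fmin) / (Fmax - Fmin)
  data.frame(raw = raw, clamped = pmin(100, pmax(0, raw)),
             out_of_range = raw < 0 | raw > 100)
}

#' Four-parameter logistic dose-response fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + (ic50/x)^hill)` with the IC50
#' log-parameterized. Orientation (activation vs inhibition) is
#' auto-detected from the dose-response trend; by construction the fitted
#' curve passes through `(top + bottom)/2` at the IC50.
#'
#' @param dose Doses (molar, > 0).
#' @param response Responses (percent).
#' @return A `dose_response_fit`: bottom, top, ic50, hill, direction,
#'   approximate CIs, residual norm.
#' @export
fit_4pl <- function(dose, response) {
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 4) stop("need at least 4 distinct doses")
  if (stats::sd(response) < 1e-9) stop("flat response; 4PL undefined")
  lo <- min(response); hi <- max(response)
  ## trend across dose: positive slope = response rises with dose
  trend <- stats::coef(stats::lm(response ~ log(dose)))[2]
  direction <- if (trend < 0) "inhibition" else "activation"
  resid_fun <- function(par) {
    bottom <- par[1]; top <- par[2]; lic50 <- par[3]; hill <- par[4]
    y <- bottom + (top - bottom) / (1 + (exp(lic50) / dose)^hill)
    response - y
  }
  hill0 <- if (direction == "inhibition") -1 else 1
  starts <- list(
    c(lo, hi, log(stats::median(dose)), hill0),
    c(lo, hi, log(stats::median(dose)), hill0 * 2),
    c(lo, hi, log(exp(mean(log(range(dose))))), hill0 * 0.5)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_fun,
                                       control = minpack.lm::nls.lm.control(maxiter = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sum(fit$fvec^2)
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("4PL fit failed to converge")
  par <- best$fit$par
  bottom <- par[1]; top <- par[2]; ic50 <- exp(par[3]); hill <- par[4]
  ## orient so top >= bottom (flip hill sign accordingly)
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
                 direction = direction,
                 ci_ic50 = if (is.finite(se[3])) exp(par[3] + c(-1.96, 1.96) * se[3])
                 else c(NA_real_, NA_real_),
                 residual_norm = sqrt(best$rn)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit (%s): bottom %.2f, top %.2f, IC50 %.3g M, hill %.2f\n",
              x$direction, x$bottom, x$top, x$ic50, x$hill))
  invisible(x)
}

#' Predict from a 4PL fit
#' @param object A `dose_response_fit`.
#' @param dose Doses (molar).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.dose_response_fit <- function(object, dose, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ic50 / dose)^object$hill)
}

#' Mechanism parameters for the concentration-threshold model
#'
#' Equilibrium reading of the binder-activation/inhibition mechanism:
#' binder engages the target groove (1:1, apparent
#' `Kd_app = Kd_bind * (1 + K9)` where K9 is the intramolecular alpha-9
#' groove-occupancy constant -- 0 for BAK and C-terminally truncated BAX,
#' large for full-length BAX). Engagement activates: the activated
#' fraction is `min(1, c_B * theta_B + c_A * theta_A)` with theta the
#' binder/activator occupancies and c an engagement-turnover multiplier
#' (transient engagements activate more targets than are occupied at any
#' instant). Binder-bound targets cannot dimerize; free activated
#' monomers dimerize with association constant `K_dim`, and release
#' saturates as `100 * D / (D + K_rel)`.
#'
#' @param T_total Target concentration (molar; default 38e-9).
#' @param Kd_bind Binder-target dissociation constant (molar).
#' @param K9 Unitless alpha-9 pre-equilibrium constant (0 = no competition).
#' @param K_dim Dimerization association constant (1/M).
#' @param K_rel Release saturation constant (molar dimer at half-maximal
#'   release).
#' @param engagement_multiplier Turnover multiplier c_B (>= 1).
#' @param activation Binder engagement activates the target (TRUE for the
#'   designed binders; FALSE for a purely blocking ligand).
#' @param activator_conc External activator (cBID) concentration (molar;
#'   0 = absent).
#' @param activator_Kd Activator engagement constant (molar).
#' @param activator_multiplier Turnover multiplier c_A for the activator.
#' @param baseline Baseline release percent with no activation.
#' @return A `mechanism_params` list with `Kd_app` populated.
#' @export
mechanism_params <- function(T_total = 38e-9, Kd_bind = 0.4e-9, K9 = 0,
                             K_dim = 1e9, K_rel = 0.5e-9,
                             engagement_multiplier = 10,
                             activation = TRUE,
                             activator_conc = 0, activator_Kd = 15e-9,
                             activator_multiplier = 20,
                             baseline = 0) {
  stopifnot(T_total > 0, Kd_bind >= 0, K9 >= 0, K_dim >= 0, K_rel > 0,
            engagement_multiplier >= 1, activator_conc >= 0)
  p <- as.list(environment())
  p$Kd_app <- Kd_bind * (1 + K9)
  structure(p, class = "mechanism_params")
}

## 1:1 occupancy of target by ligand at totals Tt, Lt with dissociation Kd,
## solved by monotone bisection on free ligand to 1e-10 relative tolerance.
occupancy_1to1 <- function(Tt, Lt, Kd) {
  if (Lt <= 0) return(0)
  if (Kd <= 0) return(min(1, Lt / Tt))
  f <- function(Lf) Lf + Tt * Lf / (Lf + Kd) - Lt
  lo <- 0; hi <- Lt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-10 * max(hi, .Machine$double.xmin)) break
  }
  Lf <- (lo + hi) / 2
  Lf / (Lf + Kd)
}

## Monomer-dimer partition: M_tot = m + 2*Kdim*m^2; returns dimer conc.
dimer_conc <- function(M_tot, K_dim) {
  if (M_tot <= 0) return(0)
  if (K_dim <= 0) return(0)
  m <- (-1 + sqrt(1 + 8 * K_dim * M_tot)) / (4 * K_dim)
  (M_tot - m) / 2
}

#' Simulate the equilibrium dose-response of the threshold mechanism
#'
#' For each binder dose, solves the coupled binding equilibria (bisection,
#' relative tolerance 1e-10), forms the activated pool, removes the
#' binder-occupied fraction, dimerizes the free activated monomers and
#' maps dimers to release percent. With activation on and no external
#' activator the curve is biphasic: activation at sub-stoichiometric
#' binder, inhibition once the binder saturates the target pool.
#'
#' @param params A [mechanism_params()].
#' @param doses Binder doses (molar).
#' @return Numeric vector of release percentages.
#' @export
simulate_dose_response <- function(params, doses) {
  stopifnot(inherits(params, "mechanism_params"))
  p <- params
  vapply(doses, function(B) {
    thetaB <- occupancy_1to1(p$T_total, B, p$Kd_app)
    thetaA <- if (p$activator_conc > 0)
      occupancy_1to1(p$T_total, p$activator_conc, p$activator_Kd) else 0
    act_frac <- if (p$activation)
      min(1, p$engagement_multiplier * thetaB + p$activator_multiplier * thetaA)
    else min(1, p$activator_multiplier * thetaA)
    activated <- p$T_total * act_frac
    bound <- p$T_total * thetaB
    A_free <- max(0, activated - bound)
    D <- dimer_conc(A_free, p$K_dim)
    p$baseline + (100 - p$baseline) * D / (D + p$K_rel)
  }, 0)
}

#' Activation/inhibition threshold summary
#'
#' Characterizes the biphasic dose-response on a log-spaced dose grid:
#' the dose of peak activation (absent for monotone curves), the 4PL IC50
#' of the descending branch, and the fold excess of that IC50 over the
#' target concentration -- the stoichiometric-threshold diagnostic (near 1
#' for tight binders of alpha-9-free targets, large for weak binders or
#' strong alpha-9 competition).
#'
#' @param params A [mechanism_params()].
#' @param dose_range Range (molar) of the log grid.
#' @param n_doses Grid size.
#' @return List: `activation_peak_dose` (NA if monotone), `inhibition_ic50`,
#'   `fold_excess`, plus the grid and responses.
#' @export
threshold_summary <- function(params, dose_range = c(1e-11, 1e-4),
                              n_doses = 60) {
  doses <- 10^seq(log10(dose_range[1]), log10(dose_range[2]),
                  length.out = n_doses)
  rel <- simulate_dose_response(params, doses)
  imax <- which.max(rel)
  interior <- imax > 1 && imax < n_doses &&
    rel[imax] > rel[1] + 1 && rel[imax] > rel[n_doses] + 1
  peak <- if (interior) doses[imax] else NA_real_
  ## descending branch: from the peak (or start) to the end
  i0 <- if (interior) imax else which.max(rel)
  idx <- i0:n_doses
  ic50 <- NA_real_
  if (length(idx) >= 4 && (max(rel[idx]) - min(rel[idx])) > 1) {
    fit <- tryCatch(fit_4pl(doses[idx], rel[idx]), error = function(e) NULL)
    if (!is.null(fit)) ic50 <- fit$ic50
  }
  list(activation_peak_dose = peak, inhibition_ic50 = ic50,
       fold_excess = ic50 / params$T_total,
       doses = doses, release = rel)
}
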