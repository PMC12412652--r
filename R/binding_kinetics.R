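## binding_kinetics: 1:1 biosensor model -- simulation, global fitting,
## and the on-rate/off-rate plane with iso-Kd diagonals.

#' A biolayer-interferometry trace
#'
#' @param time Seconds (monotone increasing).
#' @param signal Response units.
#' @param conc Analyte concentration (molar, > 0).
#' @param t_assoc,t_dissoc Association and dissociation phase start times;
#'   `t_assoc < t_dissoc <= max(time)`.
#' @return A `bli_trace` list.
#' @export
bli_trace <- function(time, signal, conc, t_assoc = 0, t_dissoc = max(time)) {
  stopifnot(length(time) == length(signal), all(diff(time) > 0), conc > 0,
            t_assoc < t_dissoc, t_dissoc <= max(time))
  structure(list(time = time, signal = signal, conc = conc,
                 t_assoc = t_assoc, t_dissoc = t_dissoc), class = "bli_trace")
}

## Closed-form 1:1 response for one trace's time grid.
model_1to1 <- function(time, conc, kon, koff, Rmax, t_assoc, t_dissoc,
                       offset = 0) {
  Kd <- koff / kon
  Req <- Rmax * conc / (conc + Kd)
  kobs <- kon * conc + koff
  r <- numeric(length(time))
  ta <- pmax(time - t_assoc, 0)
  assoc <- Req * (1 - exp(-kobs * ta))
  r1 <- Req * (1 - exp(-kobs * (t_dissoc - t_assoc)))
  diss <- r1 * exp(-koff * pmax(time - t_dissoc, 0))
  ifelse(time < t_dissoc, assoc, diss) * (time >= t_assoc) + offset
}

#' Simulate a 1:1 binding titration
#'
#' Association follows `R(t) = Req (1 - e^{-(kon C + koff) t})` with
#' `Req = Rmax C / (C + Kd)`; dissociation decays from the association
#' endpoint at `koff`. Additive Gaussian noise.
#'
#' @param kon Association rate (1/M/s).
#' @param koff Dissociation rate (1/s).
#' @param Rmax Saturating response.
#' @param concentrations Analyte concentrations (molar).
#' @param times Time grid (s); association starts at 0.
#' @param t_dissoc Dissociation start (s).
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed.
#' @return List of [bli_trace()]s.
#' @export
simulate_1to1 <- function(kon, koff, Rmax, concentrations,
                          times = seq(0, 900, by = 2), t_dissoc = 600,
                          noise_sd = 0, seed = 1) {
  stopifnot(kon > 0, koff > 0, Rmax > 0, all(concentrations > 0))
  with_seed(seed, {
    lapply(concentrations, function(C) {
      r <- model_1to1(times, C, kon, koff, Rmax, 0, t_dissoc)
      bli_trace(times, r + stats::rnorm(length(times), 0, noise_sd), C,
                t_assoc = 0, t_dissoc = t_dissoc)
    })
  })
}

#' Global 1:1 kinetic fit across a titration
#'
#' Nonlinear least squares sharing kon, koff and Rmax across all traces
#' (per-trace free baseline offsets), log-parameterized for positivity,
#' with a small deterministic multistart to avoid local minima. `Kd` is
#' `koff/kon` exactly.
#'
#' @param traces List of [bli_trace()]s (>= 2 distinct concentrations
#'   recommended; single-concentration fits are flagged low-confidence).
#' @param starts Number of multistart perturbations.
#' @return A `kinetic_fit`: kon, koff, Rmax, Kd, per-parameter approximate
#'   95 percent confidence intervals, residual norm, convergence info.
#' @export
fit_1to1 <- function(traces, starts = 5) {
  if (inherits(traces, "bli_trace")) traces <- list(traces)
  nconc <- length(unique(vapply(traces, `[[`, 0, "conc")))
  low_confidence <- nconc < 2
  nt <- length(traces)
  resid_fun <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); Rmax <- exp(par[3])
    offs <- if (length(par) > 3) par[4:(3 + nt)] else rep(0, nt)
    unlist(lapply(seq_len(nt), function(i) {
      tr <- traces[[i]]
      tr$signal - model_1to1(tr$time, tr$conc, kon, koff, Rmax,
                             tr$t_assoc, tr$t_dissoc, offs[i])
    }))
  }
  ## data-driven initial guesses: koff from the dissociation decay of the
  ## strongest trace; Kd from the concentration dependence of the
  ## association plateaus (coarse grid); kon = koff/Kd
  plateaus <- vapply(traces, function(t) {
    a <- t$signal[t$time >= t$t_assoc & t$time < t$t_dissoc]
    stats::quantile(a, 0.98, names = FALSE)
  }, 0)
  concs <- vapply(traces, `[[`, 0, "conc")
  hi <- which.max(plateaus)
  trh <- traces[[hi]]
  dphase <- trh$time >= trh$t_dissoc
  koff0 <- 1e-3
  if (sum(dphase) >= 4) {
    td <- trh$time[dphase] - trh$t_dissoc
    rd <- trh$signal[dphase]
    i1 <- seq_len(max(2, floor(sum(dphase) / 4)))
    i2 <- seq(sum(dphase) - length(i1) + 1, sum(dphase))
    r1 <- mean(rd[i1]); r2 <- mean(rd[i2])
    if (r1 > 0 && r2 > 0 && r1 > r2) {
      koff0 <- log(r1 / r2) / (mean(td[i2]) - mean(td[i1]))
    } else koff0 <- 0.1 / (max(td) + 1)
    koff0 <- min(max(koff0, 1e-7), 10)
  }
  kd_grid <- 10^seq(-13, -5, length.out = 60)
  sse <- vapply(kd_grid, function(kd) {
    f <- concs / (concs + kd)
    rm <- sum(plateaus * f) / sum(f^2)
    sum((plateaus - rm * f)^2)
  }, 0)
  kd0 <- kd_grid[which.min(sse)]
  f0 <- concs / (concs + kd0)
  Rmax0 <- max(sum(plateaus * f0) / sum(f0^2), max(plateaus), 1e-6)
  init <- c(log(koff0 / kd0), log(koff0), log(Rmax0), rep(0, nt))
  best <- NULL
  for (s in seq_len(starts)) {
    p0 <- init
    if (s > 1) {
      pert <- with_seed(1000 + s, stats::rnorm(3, 0, 0.7))
      p0[1:3] <- init[1:3] + pert
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sum(fit$fvec^2)
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("1:1 fit failed to converge from all starts")
  fit <- best$fit
  par <- fit$par
  kon <- exp(par[1]); koff <- exp(par[2]); Rmax <- exp(par[3])
  ## approximate CIs from the log-scale standard errors
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par)))
  ci_of <- function(k) {
    if (!is.finite(se[k])) return(c(NA_real_, NA_real_))
    exp(par[k] + c(-1.96, 1.96) * se[k])
  }
  structure(list(kon = kon, koff = koff, Rmax = Rmax, Kd = koff / kon,
                 offsets = if (length(par) > 3) par[4:(3 + nt)] else rep(0, nt),
                 ci = list(kon = ci_of(1), koff = ci_of(2), Rmax = ci_of(3)),
                 residual_norm = sqrt(best$rn),
                 n_traces = nt, n_concentrations = nconc,
                 low_confidence = low_confidence,
                 converged = fit$info %in% 1:4),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: kon %.3g /M/s, koff %.3g /s, Kd %.3g M (Rmax %.3g)\n",
              x$kon, x$koff, x$Kd, x$Rmax))
  if (x$low_confidence) cat("  (single concentration: low confidence)\n")
  invisible(x)
}

#' Rate-plane table with iso-Kd diagonals
#'
#' Places fits in on-rate/off-rate space: `log10 kon` against `log10 koff`,
#' where a fixed Kd is the diagonal `log10 kon = log10 koff - log10 Kd`.
#'
#' @param fits List of `kinetic_fit`s (or one).
#' @param iso_kd Kd values (molar) to label diagonals with.
#' @return List: `points` data.frame (kon, koff, Kd, log10s) and
#'   `diagonals` data.frame (Kd, intercept).
#' @export
rate_plane <- function(fits, iso_kd = 10^seq(-12, -6, by = 1)) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  pts <- do.call(rbind, lapply(fits, function(f)
    data.frame(kon = f$kon, koff = f$koff, Kd = f$Kd,
               log10_kon = log10(f$kon), log10_koff = log10(f$koff))))
  list(points = pts,
       diagonals = data.frame(Kd = iso_kd, intercept = -log10(iso_kd)))
}
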