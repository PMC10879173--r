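# Self-scission kinetics.
#
# Band intensities from cleavage gels are converted to cleaved fractions
# (cytosine-corrected), time courses are fit to inverted mono- or
# biexponential decays, and the resulting apparent rate constants k_obs
# are fit against Mg2+ concentration (Hill model) or pH (two-pKa model):
#
#   f_tRNA(t) = 1 - (A exp(-k1 t) + C)                          [mono]
#   f_tRNA(t) = 1 - (A exp(-k1 t) + B exp(-k2 t) + C)           [bi]
#   k_obs([Mg]) = k_max / (1 + (K_d / [Mg])^n)                  [Hill]
#   k_obs(pH) = k_max / (1 + 10^(pH-pKa1) + 10^(pKa2-pH)
#                          + 10^(pKa2-pKa1))                    [two-pKa]
#
# The reported k_obs is k1 for mono fits and the faster rate for bi fits.
# All fits are unweighted nonlinear least squares over pooled replicates
# (bounded L-BFGS-B with analytic-free numerical Hessian for standard
# errors).

#' Cytosine-corrected cleaved fraction from band intensities
#'
#' Band intensities of body-labeled RNA scale with the number of cytosine
#' residues, so each band is divided by its cytosine count before the
#' fraction is formed.
#'
#' @param I_trna,I_substrate Band intensities (>= 0, not both zero).
#' @param nC_trna,nC_substrate Cytosine counts (>= 1).
#' @return `f = (I_t/nC_t) / (I_t/nC_t + I_s/nC_s)`, in `[0, 1]`.
#' @export
fraction_cleaved <- function(I_trna, I_substrate, nC_trna = 1L,
                             nC_substrate = 1L) {
  stopifnot(all(I_trna >= 0), all(I_substrate >= 0),
            all(nC_trna >= 1), all(nC_substrate >= 1))
  if (any(I_trna + I_substrate == 0))
    stop("fraction_cleaved: both band intensities are zero", call. = FALSE)
  a <- I_trna / nC_trna
  b <- I_substrate / nC_substrate
  a / (a + b)
}

# Bounded least squares with a small deterministic multi-start and
# standard errors from the numerical Hessian of the SSR surface
# (cov = 2 sigma^2 H^-1). Never consumes the RNG.
#' @keywords internal
.ls_fit <- function(par0, lower, upper, predict, x, y,
                    scale_starts = list(1)) {
  ssr <- function(p) {
    r <- y - predict(p, x)
    if (any(!is.finite(r))) return(1e30)
    sum(r * r)
  }
  best <- NULL
  for (sc in scale_starts) {
    p0 <- pmin(pmax(par0 * sc, lower), upper)
    fit <- tryCatch(
      stats::nlminb(p0, ssr, lower = lower, upper = upper,
                    control = list(eval.max = 5000, iter.max = 2000,
                                   rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop(sprintf("fit did not converge; initial guesses: %s",
                 paste(signif(par0, 4), collapse = ", ")), call. = FALSE)
  best$par <- stats::setNames(best$par, names(par0))
  best$value <- best$objective
  best$convergence <- as.integer(best$convergence != 0)
  H <- tryCatch(stats::optimHess(best$par, ssr), error = function(e) NULL)
  n <- length(y); p <- length(par0)
  sigma2 <- best$value / max(n - p, 1L)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  list(par = best$par, se = stats::setNames(se, names(par0)),
       ssr = best$value, converged = best$convergence == 0, n = n)
}

.pred_mono <- function(p, t) 1 - (p[["A"]] * exp(-p[["k1"]] * t) + p[["C"]])
.pred_bi <- function(p, t) 1 - (p[["A"]] * exp(-p[["k1"]] * t) +
                                  p[["B"]] * exp(-p[["k2"]] * t) + p[["C"]])

#' Fit a self-scission time course
#'
#' Fits the inverted mono- and/or biexponential decay to pooled cleaved
#' fractions. With `model = "auto"` the biexponential is accepted only
#' when it improves the fit by an extra-sum-of-squares F-test at
#' `alpha = 0.01` *and* the two rates differ at least 3-fold; otherwise
#' the monoexponential is reported (guards against overfitting
#' triplicate gel data).
#'
#' @param times Time points in minutes (pooled replicates allowed).
#' @param f Cleaved fractions in `[0, 1]`.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @param alpha F-test level for model selection.
#' @return An `exp_fit` list: `model`, `coef` (A, B, C, k1, k2), `se`,
#'   `k_obs` (k1 for mono, the faster rate for bi), `ssr`, `n_obs`,
#'   `converged`.
#' @export
fit_exponential <- function(times, f, model = c("auto", "mono", "bi"),
                            alpha = 0.01) {
  model <- match.arg(model)
  stopifnot(length(times) == length(f), all(times >= 0))
  nt <- length(unique(times))
  if (nt < 4L) stop("need >= 4 distinct timepoints", call. = FALSE)
  if (model == "bi" && nt < 6L)
    stop("need >= 6 distinct timepoints for a biexponential fit",
         call. = FALSE)
  o <- order(times); t <- times[o]; y <- f[o]

  # initialization: plateau from the last observations, k from a
  # log-linear regression on the rising phase
  C0 <- max(0, min(1, 1 - max(y)))
  A0 <- max(1e-3, max(y) - min(y))
  resid0 <- 1 - y - C0
  use <- resid0 > 0.01 & t > 0
  k0 <- if (sum(use) >= 2) {
    sl <- stats::coef(stats::lm(log(resid0[use]) ~ t[use]))[2]
    max(1e-5, -as.numeric(sl))
  } else 1 / max(stats::median(t[t > 0]), 1e-6)

  fit_mono <- function() {
    p0 <- c(A = A0, k1 = k0, C = C0)
    r <- .ls_fit(p0, lower = c(A = 0, k1 = 1e-6, C = 0),
                 upper = c(A = 1.5, k1 = 1e3, C = 1),
                 .pred_mono, t, y,
                 scale_starts = list(1, c(1, 0.2, 1), c(1, 5, 1)))
    r$coef <- c(A = r$par[["A"]], B = 0, C = r$par[["C"]],
                k1 = r$par[["k1"]], k2 = NA_real_)
    r$model <- "mono"; r$k_obs <- r$par[["k1"]]
    r
  }
  fit_bi <- function() {
    p0 <- c(A = A0 / 2, k1 = k0 * 5, B = A0 / 2, k2 = k0 / 5, C = C0)
    r <- .ls_fit(p0,
                 lower = c(A = 0, k1 = 1e-6, B = 0, k2 = 1e-6, C = 0),
                 upper = c(A = 1.5, k1 = 1e3, B = 1.5, k2 = 1e3, C = 1),
                 .pred_bi, t, y,
                 scale_starts = list(1, c(1, 0.2, 1, 0.2, 1),
                                     c(1, 5, 1, 5, 1)))
    r$coef <- c(A = r$par[["A"]], B = r$par[["B"]], C = r$par[["C"]],
                k1 = r$par[["k1"]], k2 = r$par[["k2"]])
    r$model <- "bi"; r$k_obs <- max(r$par[["k1"]], r$par[["k2"]])
    r
  }

  res <- switch(model,
    mono = fit_mono(),
    bi = fit_bi(),
    auto = {
      m <- fit_mono()
      if (nt < 6L) m else {
        b <- fit_bi()
        n <- length(y)
        Fstat <- ((m$ssr - b$ssr) / 2) / (b$ssr / max(n - 5, 1))
        pval <- if (is.finite(Fstat) && Fstat > 0)
          stats::pf(Fstat, 2, max(n - 5, 1), lower.tail = FALSE) else 1
        ks <- sort(c(b$coef[["k1"]], b$coef[["k2"]]))
        if (pval < alpha && ks[2] / ks[1] >= 3 && b$ssr < m$ssr) b else m
      }
    })
  structure(list(model = res$model, coef = res$coef, se = res$se,
                 k_obs = res$k_obs, ssr = res$ssr, n_obs = res$n,
                 converged = res$converged),
            class = "exp_fit")
}

#' Fit the Hill-type Mg2+ dependence of k_obs
#'
#' `k_obs = k_max / (1 + (K_d/[Mg])^n)`; by construction the fitted curve
#' passes through `k_max/2` at `[Mg] = K_d`.
#'
#' @param mg Mg2+ concentrations (mM, > 0), at least 4 values.
#' @param kobs Observed rate constants (min^-1).
#' @return A `hill_fit` list: `k_max`, `K_d`, `n`, `se`, `ssr`,
#'   `converged`, `n_obs`.
#' @export
fit_hill <- function(mg, kobs) {
  stopifnot(length(mg) == length(kobs), all(mg > 0))
  if (length(unique(mg)) < 4L)
    stop("need >= 4 Mg2+ concentrations", call. = FALSE)
  if (diff(range(kobs)) <= 0)
    stop("degenerate fit: all k_obs equal", call. = FALSE)
  kmax0 <- max(kobs)
  half <- kmax0 / 2
  Kd0 <- unname(mg[which.min(abs(kobs - half))])
  pred <- function(p, x) p[["k_max"]] / (1 + (p[["K_d"]] / x)^p[["n"]])
  r <- .ls_fit(c(k_max = kmax0, K_d = Kd0, n = 1),
               lower = c(k_max = 1e-9, K_d = 1e-9, n = 0.05),
               upper = c(k_max = 1e4, K_d = 1e6, n = 20),
               pred, mg, kobs,
               scale_starts = list(1, c(1, 0.3, 1), c(1, 3, 2)))
  structure(list(k_max = r$par[["k_max"]], K_d = r$par[["K_d"]],
                 n = r$par[["n"]], se = r$se, ssr = r$ssr,
                 converged = r$converged, n_obs = r$n),
            class = "hill_fit")
}

#' Fit the two-pKa pH-rate profile
#'
#' `k_obs = k_max / (1 + 10^(pH-pKa1) + 10^(pKa2-pH) + 10^(pKa2-pKa1))`
#' with the constraint `pKa1 > pKa2` (basic limb above the acidic limb);
#' the fitted bell peaks at `(pKa1 + pKa2)/2`. The two groups are
#' conventionally interpreted as a hydrated Mg2+ ion (pKa1) and the
#' catalytic cytosine (pKa2).
#'
#' @param ph pH values spanning both limbs, at least 6 points.
#' @param kobs Observed rate constants (min^-1).
#' @return A `ph_fit` list: `k_max`, `pKa1`, `pKa2`, `se`, `ssr`,
#'   `converged`, `n_obs`. One-limbed (monotone) profiles give a warning.
#' @export
fit_ph <- function(ph, kobs) {
  stopifnot(length(ph) == length(kobs))
  if (length(unique(ph)) < 6L) stop("need >= 6 pH points", call. = FALSE)
  imax <- which.max(kobs)
  if (imax == which.min(ph) || imax == which.max(ph))
    warning("pH profile appears monotone (one limb only); ",
            "pKa estimates will be poorly constrained")
  peak <- unname(ph[imax])
  # parametrized as (k_max, pKa2, dpKa >= 0) so pKa1 = pKa2 + dpKa > pKa2
  pred <- function(p, x) {
    pka2 <- p[["pKa2"]]; pka1 <- pka2 + p[["dpKa"]]
    p[["k_max"]] / (1 + 10^(x - pka1) + 10^(pka2 - x) + 10^(pka2 - pka1))
  }
  p0 <- c(k_max = max(kobs), pKa2 = peak - 1.5, dpKa = 3)
  r <- .ls_fit(p0, lower = c(k_max = 1e-9, pKa2 = 0, dpKa = 1e-3),
               upper = c(k_max = 1e4, pKa2 = 14, dpKa = 14),
               pred, ph, kobs,
               scale_starts = list(1, c(1, 0.8, 1.5), c(1, 1.2, 0.5)))
  se <- r$se
  # pKa1 = pKa2 + dpKa: propagate assuming independence (diagnostic only)
  se_pka1 <- sqrt(sum(c(se[["pKa2"]], se[["dpKa"]])^2))
  structure(list(k_max = r$par[["k_max"]],
                 pKa1 = r$par[["pKa2"]] + r$par[["dpKa"]],
                 pKa2 = r$par[["pKa2"]],
                 se = c(k_max = se[["k_max"]], pKa1 = se_pka1,
                        pKa2 = se[["pKa2"]]),
                 ssr = r$ssr, converged = r$converged, n_obs = r$n),
            class = "ph_fit")
}

#' Simulate kinetic traces or rate profiles
#'
#' Closed-form values from the mono/biexponential, Hill, or two-pKa model
#' plus i.i.d. Gaussian noise. Fraction traces are clipped to `[0, 1]`.
#' Deterministic for a fixed `seed`.
#'
#' @param model `"mono"`, `"bi"`, `"hill"`, or `"ph"`.
#' @param params Named list/vector of model parameters (`A`, `k1`, `C`;
#'   plus `B`, `k2` for `"bi"`; `k_max`, `K_d`, `n` for `"hill"`;
#'   `k_max`, `pKa1`, `pKa2` for `"ph"`).
#' @param x Time points (minutes), Mg2+ concentrations (mM), or pH values.
#' @param noise_sd Gaussian noise SD. For `"hill"`/`"ph"` profiles the
#'   noise is relative (`value * (1 + rnorm)`), matching how rate errors
#'   scale; for fraction traces it is absolute.
#' @param replicates Number of replicate traces.
#' @param seed Optional RNG seed.
#' @return Data frame with `x` (named `time`, `mg` or `ph`), `replicate`,
#'   and the response (`f` or `k_obs`).
#' @export
simulate_trace <- function(model = c("mono", "bi", "hill", "ph"), params,
                           x, noise_sd = 0, replicates = 1L, seed = NULL) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0, replicates >= 1L)
  p <- as.list(params)
  if (!is.null(seed)) set.seed(seed)
  clean <- switch(model,
    mono = 1 - (p$A * exp(-p$k1 * x) + p$C),
    bi = 1 - (p$A * exp(-p$k1 * x) + p$B * exp(-p$k2 * x) + p$C),
    hill = p$k_max / (1 + (p$K_d / x)^p$n),
    ph = p$k_max / (1 + 10^(x - p$pKa1) + 10^(p$pKa2 - x) +
                      10^(p$pKa2 - p$pKa1)))
  xname <- switch(model, mono = "time", bi = "time", hill = "mg", ph = "ph")
  yname <- if (model %in% c("mono", "bi")) "f" else "k_obs"
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    y <- if (noise_sd == 0) clean
    else if (yname == "f")
      pmin(1, pmax(0, clean + stats::rnorm(length(x), 0, noise_sd)))
    else clean * (1 + stats::rnorm(length(x), 0, noise_sd))
    d <- data.frame(x = x, replicate = r, y = y)
    names(d) <- c(xname, "replicate", yname)
    d
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %sexponential, k_obs = %.4g min^-1 (SSR %.3g, n %d)\n",
              x$model, x$k_obs, x$ssr, x$n_obs))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> k_max %.4g min^-1, K_d %.4g mM, n %.3g (SSR %.3g)\n",
              x$k_max, x$K_d, x$n, x$ssr))
  invisible(x)
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("<ph_fit> k_max %.4g min^-1, pKa1 %.3f, pKa2 %.3f (SSR %.3g)\n",
              x$k_max, x$pKa1, x$pKa2, x$ssr))
  invisible(x)
}
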