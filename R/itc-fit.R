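#' Constraint specification for the sequential fit
#'
#' Encodes the constraint set used when fitting the three-event sequential
#' model: equality groups (parameters shared during optimization) and ordered
#' inequality pairs (enforced by smooth reparametrization).  The default is
#' the bridged-hexamer constraint set `k1 = k2`, `h1 = h2`, `k1 > k3`,
#' `h1 < h3`: two identical intratrimer events and one weaker, less
#' exothermic bridging event.
#'
#' @param equalities List of character vectors naming parameters constrained
#'   equal.
#' @param inequalities List of ordered character pairs `c(a, b)` meaning
#'   `a > b` for affinities and `a < b` for enthalpies (the declared
#'   direction is stored verbatim as `a OP b`).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(
    equalities = list(c("k1", "k2"), c("h1", "h2")),
    inequalities = list(c("k1", ">", "k3"), c("h1", "<", "h3"))) {
  all_eq <- unlist(equalities)
  if (anyDuplicated(all_eq))
    stop("a parameter may appear in at most one equality group")
  known <- c("k1", "k2", "k3", "h1", "h2", "h3")
  refs <- c(all_eq, unlist(lapply(inequalities, function(p) p[c(1, 3)])))
  if (!all(refs %in% known))
    stop("constraints reference undeclared parameters: ",
         paste(setdiff(refs, known), collapse = ", "))
  structure(list(equalities = equalities, inequalities = inequalities),
            class = "constraint_spec")
}

# The only constraint topology the sequential fit currently supports.
is_bridged_hexamer_constraints <- function(cs) {
  eq <- lapply(cs$equalities, sort)
  setequal(vapply(eq, paste, character(1), collapse = ","),
           c("k1,k2", "h1,h2")) &&
    length(cs$inequalities) == 2
}

fit_result <- function(params, std_errors, events, residual_rms, converged,
                       n_iterations, model_type, diagnostics = list()) {
  structure(list(params = params, std_errors = std_errors, events = events,
                 residual_rms = residual_rms, converged = converged,
                 n_iterations = n_iterations, model_type = model_type,
                 diagnostics = diagnostics),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("ITC fit (%s model): %s, %d iterations, residual RMS %.3g kcal/mol\n",
              x$model_type,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations, x$residual_rms))
  if (isTRUE(x$diagnostics$ill_conditioned))
    cat("  WARNING: ill-conditioned (flat isotherm or unidentifiable event)\n")
  ev <- x$events
  for (i in seq_len(nrow(ev))) {
    cat(sprintf("  event %s: Kd = %.4g +/- %.2g uM, dH = %.4g +/- %.2g kcal/mol",
                ev$event[i], ev$kd[i] * 1e6, ev$kd_se[i] * 1e6,
                ev$dh[i], ev$dh_se[i]))
    if (!is.null(ev$dg)) cat(sprintf(", dG = %.3g, -TdS = %.3g kcal/mol",
                                     ev$dg[i], ev$neg_t_ds[i]))
    cat("\n")
  }
  if ("n" %in% names(x$params))
    cat(sprintf("  N = %.4g +/- %.2g\n", x$params[["n"]],
                x$std_errors[["n"]]))
  invisible(x)
}

# Standard errors from an nls.lm fit via its summary (Jacobian-based).
.lm_std_errors <- function(fit, n_par) {
  se <- rep(NA_real_, n_par)
  ok <- try({
    s <- summary(fit)
    se <- s$coefficients[, "Std. Error"]
  }, silent = TRUE)
  if (inherits(ok, "try-error")) se <- rep(NA_real_, n_par)
  se
}

#' Fit the one-set-of-sites model to an isotherm
#'
#' Levenberg-Marquardt least squares on the normalized heats, with Ka
#' parametrized as `exp(theta)` (it spans decades) and N on a log scale for
#' positivity.  Initialization uses standard ITC heuristics: dH from the
#' first-injection plateau, N from the molar-ratio position of the steepest
#' heat change, and a small grid of Wiseman c-values for Ka, with the best
#' start refined.
#'
#' @param isotherm An `itc_isotherm` with at least 5 injections.
#' @param init Optional [thermo_params()] starting point.
#' @param fit_offset Also fit a constant heat-of-dilution offset
#'   (default FALSE).
#' @param exclude_first Drop the first injection from the residuals
#'   (default FALSE).
#' @return An `itc_fit` with fields `params` (n, ka, kd, dh, and offset if
#'   requested), `std_errors`, an `events` table carrying (kd, dh) with
#'   standard errors and derived dG and -TdS, `residual_rms`, and
#'   convergence diagnostics.
#' @export
fit_oss <- function(isotherm, init = NULL, fit_offset = FALSE,
                    exclude_first = FALSE) {
  stopifnot(inherits(isotherm, "itc_isotherm"))
  sch <- isotherm$schedule
  if (length(sch$injection_volumes) < 5)
    stop("at least 5 injections are required to fit the OSS model")
  conc <- dilute_concentrations(sch)
  y <- isotherm$normalized_heats
  keep <- if (exclude_first) -1L else seq_along(y)
  scale_y <- max(abs(y))
  if (!is.finite(scale_y) || scale_y < 1e-12) {
    return(fit_result(
      params = c(n = NA_real_, ka = NA_real_, kd = NA_real_, dh = 0),
      std_errors = c(n = NA_real_, kd = NA_real_, dh = NA_real_),
      events = data.frame(event = "binding", kd = NA_real_, kd_se = NA_real_,
                          dh = 0, dh_se = NA_real_),
      residual_rms = 0, converged = FALSE, n_iterations = 0L,
      model_type = "oss",
      diagnostics = list(ill_conditioned = TRUE,
                         reason = "flat isotherm: all heats ~ 0")))
  }

  model_norm <- function(n, ka, dh, offset = 0) {
    p <- thermo_params(n, 1 / ka, dh, sch$temperature)
    iso <- oss_isotherm(p, sch,
                        displacement_correction = isotherm$displacement_correction,
                        dilution_offset = offset)
    iso$normalized_heats
  }
  resid_fn <- function(par) {
    off <- if (fit_offset) par[["offset"]] else 0
    (model_norm(exp(par[["log_n"]]), exp(par[["log_ka"]]), par[["dh"]], off) - y)[keep]
  }

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- c(log_n = log(init$n_sites), log_ka = log(init$ka),
                     dh = init$dh)
  } else {
    dh0 <- y[1]
    dy <- abs(diff(y))
    n0 <- conc$molar_ratio[which.max(dy)]
    n0 <- min(max(n0, 0.2), 6)
    for (c_val in c(1, 10, 100, 1000)) {
      starts[[length(starts) + 1]] <-
        c(log_n = log(n0), log_ka = log(c_val / (n0 * sch$cell_conc0)),
          dh = dh0)
    }
  }
  if (fit_offset) starts <- lapply(starts, function(s) c(s, offset = 0))

  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  best <- NULL
  for (s in starts) {
    f <- try(minpack.lm::nls.lm(par = s, fn = resid_fn, control = ctrl),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    stop("OSS fit failed from every start; isotherm may be degenerate")

  p <- best$par
  n_hat <- exp(p[["log_n"]]); ka_hat <- exp(p[["log_ka"]])
  dh_hat <- p[["dh"]]; kd_hat <- 1 / ka_hat
  se_raw <- .lm_std_errors(best, length(p))
  names(se_raw) <- names(p)
  se_n <- n_hat * se_raw[["log_n"]]
  se_kd <- kd_hat * se_raw[["log_ka"]]  # |d kd / d log_ka| = kd
  se_dh <- se_raw[["dh"]]
  rms <- sqrt(best$deviance / length(best$fvec))
  converged <- best$info %in% 1:4
  ill <- any(!is.finite(c(se_n, se_kd, se_dh)))

  params <- c(n = n_hat, ka = ka_hat, kd = kd_hat, dh = dh_hat)
  ses <- c(n = se_n, kd = se_kd, dh = se_dh)
  if (fit_offset) {
    params <- c(params, offset = p[["offset"]])
    ses <- c(ses, offset = se_raw[["offset"]])
  }
  events <- data.frame(event = "binding", kd = kd_hat, kd_se = se_kd,
                       dh = dh_hat, dh_se = se_dh,
                       stringsAsFactors = FALSE)
  out <- fit_result(params, ses, events, rms, converged, best$niter, "oss",
                    diagnostics = list(ill_conditioned = ill,
                                       info = best$info,
                                       message = best$message))
  derive_thermo(out, sch$temperature)
}

#' Fit the constrained three-event sequential model
#'
#' Fits `(k1 = k2, k3, h1 = h2, h3)` to an isotherm by Levenberg-Marquardt
#' least squares on the normalized heats.  Equalities are enforced by
#' parameter sharing; the inequalities `k1 > k3` and `h1 < h3` by the smooth
#' reparametrization `k3 = k1 exp(-delta^2)`, `h3 = h1 + eps^2` with `delta`
#' and `eps` free, so any returned point is feasible by construction.
#' Five jittered starts (fixed sub-seeds) guard against local minima.
#'
#' @param isotherm An `itc_isotherm`; the schedule's cell concentration must
#'   be on the hexamer basis (trimer concentration / 2).
#' @param constraints A [constraint_spec()]; only the bridged-hexamer set is
#'   supported.
#' @param init Optional [sequential_model()] starting point; an infeasible
#'   start is projected into the feasible region.
#' @param n_starts Number of jittered multi-starts (default 5).
#' @param seed Seed for the start jitter (default 1; fixed so fits are
#'   deterministic).
#' @inheritParams fit_oss
#' @return An `itc_fit` with per-event rows `intratrimer` (k1 = k2) and
#'   `bridging` (k3) in `events`, plus `params` (k1, k2, k3, kd1, kd3,
#'   h1, h2, h3).
#' @export
fit_sequential_constrained <- function(isotherm,
                                       constraints = constraint_spec(),
                                       init = NULL, fit_offset = FALSE,
                                       exclude_first = FALSE, n_starts = 5,
                                       seed = 1) {
  stopifnot(inherits(isotherm, "itc_isotherm"),
            inherits(constraints, "constraint_spec"))
  if (!is_bridged_hexamer_constraints(constraints))
    stop("only the bridged-hexamer constraint set (k1=k2, h1=h2, k1>k3, h1<h3) is supported")
  sch <- isotherm$schedule
  if (length(sch$injection_volumes) < 5)
    stop("at least 5 injections are required")
  y <- isotherm$normalized_heats
  keep <- if (exclude_first) -1L else seq_along(y)

  unpack <- function(par) {
    k1 <- exp(par[["log_k1"]])
    k3 <- k1 * exp(-par[["delta"]]^2)
    h1 <- par[["h1"]]
    h3 <- h1 + par[["eps"]]^2
    list(k1 = k1, k3 = k3, h1 = h1, h3 = h3)
  }
  model_norm <- function(par) {
    u <- unpack(par)
    m <- sequential_model(c(u$k1, u$k1, u$k3), c(u$h1, u$h1, u$h3))
    off <- if (fit_offset) par[["offset"]] else 0
    sequential_isotherm(m, sch,
                        displacement_correction = isotherm$displacement_correction,
                        dilution_offset = off)$normalized_heats
  }
  resid_fn <- function(par) (model_norm(par) - y)[keep]

  # Base start: OSS heuristics on the same data, projected into feasibility.
  if (!is.null(init)) {
    k1_0 <- init$ka[1]
    k3_0 <- min(init$ka[3], 0.9 * k1_0)   # project infeasible starts
    if (k3_0 <= 0) k3_0 <- 0.1 * k1_0
    h1_0 <- min(init$dh[1], init$dh[3] - 1e-3)
    h3_0 <- max(init$dh[3], h1_0 + 1e-3)
  } else {
    oss0 <- try(fit_oss(isotherm, exclude_first = exclude_first),
                silent = TRUE)
    if (!inherits(oss0, "try-error") && is.finite(oss0$params[["ka"]])) {
      k1_0 <- oss0$params[["ka"]]
      h1_0 <- oss0$params[["dh"]]
    } else {
      k1_0 <- 1e6
      h1_0 <- y[1]
    }
    k3_0 <- k1_0 / 3
    h3_0 <- h1_0 + abs(h1_0) / 2
  }
  base <- c(log_k1 = log(k1_0), delta = sqrt(max(log(k1_0 / k3_0), 1e-4)),
            h1 = h1_0, eps = sqrt(max(h3_0 - h1_0, 1e-4)))
  if (fit_offset) base <- c(base, offset = 0)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  jitters <- lapply(seq_len(max(n_starts - 1, 0)), function(i) {
    j <- base
    j[["log_k1"]] <- j[["log_k1"]] + stats::rnorm(1, 0, 0.7)
    j[["delta"]] <- abs(j[["delta"]] + stats::rnorm(1, 0, 0.5))
    j[["h1"]] <- j[["h1"]] * stats::runif(1, 0.7, 1.3)
    j[["eps"]] <- abs(j[["eps"]] + stats::rnorm(1, 0, 0.5))
    j
  })
  starts <- c(list(base), jitters)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  best <- NULL
  for (s in starts) {
    f <- try(minpack.lm::nls.lm(par = s, fn = resid_fn, control = ctrl),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("sequential fit failed from every start")

  p <- best$par
  u <- unpack(p)
  se_raw <- .lm_std_errors(best, length(p))
  names(se_raw) <- names(p)
  # First-order propagation through the reparametrization.
  se_k1 <- u$k1 * se_raw[["log_k1"]]
  se_log_k3 <- sqrt(se_raw[["log_k1"]]^2 +
                      (2 * p[["delta"]] * se_raw[["delta"]])^2)
  se_k3 <- u$k3 * se_log_k3
  se_h1 <- se_raw[["h1"]]
  se_h3 <- sqrt(se_raw[["h1"]]^2 + (2 * p[["eps"]] * se_raw[["eps"]])^2)
  kd1 <- 1 / u$k1; kd3 <- 1 / u$k3
  rms <- sqrt(best$deviance / length(best$fvec))
  ill <- any(!is.finite(c(se_k1, se_k3, se_h1, se_h3))) ||
    (is.finite(se_h3) && abs(u$h3) > 0 && se_h3 > 10 * abs(u$h3 - u$h1 + 1e-9))

  params <- c(k1 = u$k1, k2 = u$k1, k3 = u$k3,
              kd1 = kd1, kd3 = kd3, h1 = u$h1, h2 = u$h1, h3 = u$h3)
  ses <- c(kd1 = kd1 * se_raw[["log_k1"]], kd3 = kd3 * se_log_k3,
           h1 = se_h1, h3 = se_h3)
  events <- data.frame(event = c("intratrimer", "bridging"),
                       kd = c(kd1, kd3),
                       kd_se = c(kd1 * se_raw[["log_k1"]], kd3 * se_log_k3),
                       dh = c(u$h1, u$h3), dh_se = c(se_h1, se_h3),
                       stringsAsFactors = FALSE)
  out <- fit_result(params, ses, events, rms, best$info %in% 1:4, best$niter,
                    "sequential",
                    diagnostics = list(ill_conditioned = ill,
                                       info = best$info,
                                       message = best$message,
                                       constraints = constraints))
  derive_thermo(out, sch$temperature)
}

#' Attach derived thermodynamics to a fit
#'
#' For every event in the fit: `dG = R T ln(Kd)` and `-T dS = dG - dH`, with
#' first-order error propagation (`se(dG) = R T se(Kd)/Kd`;
#' `se(-TdS) = sqrt(se(dG)^2 + se(dH)^2)`).
#'
#' @param fit An `itc_fit`.
#' @param temperature Kelvin.
#' @return The fit with columns `dg`, `dg_se`, `neg_t_ds`, `ntds_se` added to
#'   its `events` table.
#' @export
derive_thermo <- function(fit, temperature = 298.15) {
  stopifnot(inherits(fit, "itc_fit"))
  ev <- fit$events
  if (!nrow(ev) || !all(c("kd", "dh") %in% names(ev)))
    stop("fit carries no (kd, dh) events to derive from")
  ok <- is.finite(ev$kd) & ev$kd > 0
  ev$dg <- ifelse(ok, delta_g_from_kd(pmax(ev$kd, .Machine$double.xmin),
                                      temperature), NA_real_)
  ev$neg_t_ds <- ev$dg - ev$dh
  ev$dg_se <- ifelse(ok & is.finite(ev$kd_se),
                     .R_KCAL * temperature * ev$kd_se / ev$kd, NA_real_)
  ev$ntds_se <- sqrt(ev$dg_se^2 + ev$dh_se^2)
  fit$events <- ev
  fit$temperature <- temperature
  fit
}

#' Inverse-variance aggregation of replicate measurements
#'
#' Aggregates replicate estimates `y_i` with errors `sigma_i` by
#' inverse-variance weighting:
#' `y_hat = sum(y_i / sigma_i^2) / sum(1 / sigma_i^2)` and, as published,
#' `sigma_hat = 1 / sum(1 / sigma_i^2)` — a variance-scale quantity.
#' `conventional = TRUE` returns the usual standard error
#' `sqrt(1 / sum(1 / sigma_i^2))` instead.
#'
#' @param values Numeric vector of replicate measurements.
#' @param sigmas Numeric vector of their errors (> 0), same length.
#' @param conventional Return the square-root (standard-error) form of the
#'   aggregate error (default FALSE: the verbatim reciprocal-sum form).
#' @return Named list `list(aggregate, aggregate_error)`.
#' @examples
#' aggregate_inverse_variance(c(1, 2), c(1, 2))  # aggregate 1.2, error 0.8
#' @export
aggregate_inverse_variance <- function(values, sigmas, conventional = FALSE) {
  if (length(values) != length(sigmas))
    stop("values and sigmas must have the same length")
  if (!length(values)) stop("empty input")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("all sigmas must be finite and > 0")
  w <- 1 / sigmas^2
  y_hat <- sum(values * w) / sum(w)
  err <- 1 / sum(w)
  if (conventional) err <- sqrt(err)
  list(aggregate = y_hat, aggregate_error = err)
}
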