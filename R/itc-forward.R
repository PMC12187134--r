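#' Injection schedule for an ITC titration
#'
#' Describes a perfusion-cell titration: the active cell volume, the starting
#' macromolecule concentration in the cell, the titrant concentration in the
#' syringe, and the ordered injection volumes.
#'
#' @param cell_volume Active cell volume V0 in liters.
#' @param cell_conc0 Initial macromolecule concentration in the cell, molar.
#' @param syringe_conc Titrant concentration in the syringe, molar.
#' @param injection_volumes Ordered vector of injection volumes in liters
#'   (at least 2 injections).
#' @param temperature Kelvin; defaults to 298.15.
#' @return An object of class `injection_schedule`.
#' @examples
#' injection_schedule(1.4e-3, 20e-6, 300e-6, rep(10e-6, 28))
#' @export
injection_schedule <- function(cell_volume, cell_conc0, syringe_conc,
                               injection_volumes, temperature = 298.15) {
  stopifnot(is.numeric(injection_volumes))
  if (cell_volume <= 0 || cell_conc0 <= 0 || syringe_conc <= 0)
    stop("cell_volume, cell_conc0 and syringe_conc must be strictly positive")
  if (length(injection_volumes) < 2)
    stop("at least 2 injections are required")
  if (any(injection_volumes <= 0))
    stop("all injection volumes must be strictly positive")
  if (temperature <= 0) stop("temperature must be > 0 (kelvin)")
  if (sum(injection_volumes) >= 2 * cell_volume)
    stop("cumulative injected volume must stay below 2 * cell_volume")
  structure(list(cell_volume = cell_volume, cell_conc0 = cell_conc0,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf(
    "ITC schedule: %d injections (%.3g uL total) of %.0f uM titrant into %.0f uM at V0 = %.2f mL, T = %.2f K\n",
    length(x$injection_volumes), sum(x$injection_volumes) * 1e6,
    x$syringe_conc * 1e6, x$cell_conc0 * 1e6, x$cell_volume * 1e3,
    x$temperature))
  invisible(x)
}

#' Per-injection total concentrations with displacement correction
#'
#' Standard perfusion-cell accounting: after cumulative injected volume v the
#' cell contents have been partially displaced, and total concentrations in
#' the active volume are
#' `Mt = M0 (1 - v/(2 V0)) / (1 + v/(2 V0))` for the cell species and
#' `Xt = X0 (v/V0) / (1 + v/(2 V0))` for the titrant.
#'
#' @param schedule An [injection_schedule()].
#' @return A data frame with one row per injection: `injection`, `dv`
#'   (liters), `v_cum` (cumulative liters), `m_total` and `x_total` (molar),
#'   and `molar_ratio` = x_total / m_total.
#' @export
dilute_concentrations <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  v <- cumsum(schedule$injection_volumes)
  V0 <- schedule$cell_volume
  if (any(v >= 2 * V0)) stop("cumulative injected volume exceeds 2 * V0")
  f <- v / (2 * V0)
  m <- schedule$cell_conc0 * (1 - f) / (1 + f)
  x <- schedule$syringe_conc * (v / V0) / (1 + f)
  data.frame(injection = seq_along(v), dv = schedule$injection_volumes,
             v_cum = v, m_total = m, x_total = x, molar_ratio = x / m)
}

#' Total heat content for the one-set-of-sites model
#'
#' Closed-form (Wiseman) cumulative heat content of the cell for a
#' single-class binding model with stoichiometry n, association constant
#' Ka = 1/Kd and enthalpy dH:
#' `Q = (n Mt dH V0 / 2) * (z - sqrt(z^2 - 4 Xt/(n Mt)))` with
#' `z = 1 + Xt/(n Mt) + 1/(n Ka Mt)`.
#'
#' @param params A [thermo_params()].
#' @param m_total Total macromolecule concentration in the cell, molar.
#' @param x_total Total titrant concentration in the cell, molar.
#' @param cell_volume Active cell volume V0, liters.
#' @return Heat content in kcal (vectorized over `m_total`/`x_total`).
#' @export
oss_total_heat <- function(params, m_total, x_total, cell_volume) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(m_total < 0) || any(x_total < 0))
    stop("concentrations must be non-negative")
  n <- params$n_sites
  ka <- params$ka
  q <- numeric(length(m_total))
  pos <- m_total > 0
  nm <- n * m_total[pos]
  z <- 1 + x_total[pos] / nm + 1 / (ka * nm)
  disc <- z^2 - 4 * x_total[pos] / nm
  if (any(disc < -1e-12))
    stop("internal error: negative discriminant in Wiseman closed form; z = ",
         paste(signif(z[disc < -1e-12], 6), collapse = ", "))
  disc[disc < 0] <- 0
  q[pos] <- (nm * params$dh * cell_volume / 2) * (z - sqrt(disc))
  q
}

#' Simulate a one-set-of-sites isotherm
#'
#' Forward-models per-injection heats for the OSS model.  Per-injection heat
#' uses the displacement correction
#' `dQ(i) = Q(i) - Q(i-1) + (dV_i / V0) * (Q(i) + Q(i-1)) / 2`,
#' accounting for heat carried out of the active volume by the displaced
#' liquid; normalized heat is `dQ(i) / (dV_i * syringe_conc)` in kcal per
#' mole of injectant.
#'
#' @param params A [thermo_params()].
#' @param schedule An [injection_schedule()].
#' @param displacement_correction Apply the average-Q displacement term
#'   (default TRUE); turning it off gives the idealized telescoping heats.
#' @param dilution_offset Constant heat-of-dilution offset added to every
#'   normalized heat, kcal/mol of injectant (default 0).
#' @return An object of class `itc_isotherm`: the schedule plus per-injection
#'   `raw_heats` (ucal), `normalized_heats` (kcal/mol of injectant) and
#'   `molar_ratios`.
#' @export
oss_isotherm <- function(params, schedule, displacement_correction = TRUE,
                         dilution_offset = 0) {
  conc <- dilute_concentrations(schedule)
  q <- oss_total_heat(params, conc$m_total, conc$x_total, schedule$cell_volume)
  new_isotherm(schedule, q, conc,
               displacement_correction = displacement_correction,
               dilution_offset = dilution_offset,
               model = list(type = "oss", params = params))
}

# Shared: difference cumulative heats into an isotherm object.
new_isotherm <- function(schedule, q_total, conc,
                         displacement_correction = TRUE, dilution_offset = 0,
                         model = NULL) {
  V0 <- schedule$cell_volume
  q_prev <- c(0, q_total[-length(q_total)])
  dq <- q_total - q_prev
  if (displacement_correction)
    dq <- dq + (conc$dv / V0) * (q_total + q_prev) / 2
  norm <- dq / (conc$dv * schedule$syringe_conc) + dilution_offset
  raw <- dq * 1e9  # kcal -> ucal
  structure(list(schedule = schedule,
                 raw_heats = raw,
                 normalized_heats = norm,
                 molar_ratios = conc$molar_ratio,
                 total_heats = q_total,
                 displacement_correction = displacement_correction,
                 dilution_offset = dilution_offset,
                 model = model),
            class = "itc_isotherm")
}

#' @export
print.itc_isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections, molar ratio %.3g to %.3g\n",
              length(x$raw_heats), min(x$molar_ratios), max(x$molar_ratios)))
  cat(sprintf("  normalized heats %.3g to %.3g kcal/mol of injectant\n",
              min(x$normalized_heats), max(x$normalized_heats)))
  if (!is.null(x$model)) cat("  forward model:", x$model$type, "\n")
  invisible(x)
}

#' @export
as.data.frame.itc_isotherm <- function(x, ...) {
  data.frame(injection_index = seq_along(x$raw_heats),
             injection_volume_uL = x$schedule$injection_volumes * 1e6,
             heat_ucal = x$raw_heats,
             normalized_heat_kcal_per_mol = x$normalized_heats,
             molar_ratio = x$molar_ratios)
}

#' Three-event sequential binding model of the bridged hexamer
#'
#' The macromolecule is the 53BP1 hexamer (dimer-of-trimers equivalent, i.e.
#' the cell trimer concentration divided by two), which binds three LC8
#' dimers sequentially with association constants k1..k3 (1/M) and event
#' enthalpies h1..h3 (kcal/mol).  Two events are intratrimer and one is the
#' bridging event; the constraints `k1 = k2`, `h1 = h2`, `k1 > k3`,
#' `h1 < h3` are imposed at fitting time, not here.
#'
#' @param ka Ordered association constants `c(k1, k2, k3)` in 1/M; k1 must be
#'   positive, later events may be 0 to switch the event off.
#' @param dh Ordered event enthalpies `c(h1, h2, h3)`, kcal/mol.
#' @param macromolecule_basis Which unit the cell concentration counts;
#'   `"hexamer"` (the default and the only basis the fitting supports).
#' @return An object of class `sequential_model`.
#' @export
sequential_model <- function(ka, dh, macromolecule_basis = "hexamer") {
  stopifnot(length(ka) == 3, length(dh) == 3)
  if (ka[1] <= 0 || any(ka < 0)) stop("k1 must be > 0 and all ka >= 0")
  macromolecule_basis <- match.arg(macromolecule_basis, "hexamer")
  structure(list(ka = as.numeric(ka), dh = as.numeric(dh),
                 macromolecule_basis = macromolecule_basis),
            class = "sequential_model")
}

#' @export
print.sequential_model <- function(x, ...) {
  cat(sprintf(
    "Sequential (3-event, %s basis): Kd = %s uM; dH = %s kcal/mol\n",
    x$macromolecule_basis,
    paste(signif(1e6 / x$ka, 3), collapse = ", "),
    paste(signif(x$dh, 3), collapse = ", ")))
  invisible(x)
}

# Binding-polynomial occupancy fractions F_j at free ligand L.
# beta_j = prod(k_1..k_j); F_j = beta_j L^j / (1 + sum beta_j L^j).
sequential_fractions <- function(model, free_ligand) {
  beta <- cumprod(model$ka)
  lp <- outer(free_ligand, 1:3, function(l, j) l^j)
  num <- sweep(lp, 2, beta, `*`)
  denom <- 1 + rowSums(num)
  sweep(num, 1, denom, `/`)
}

#' Free ligand concentration for the sequential model
#'
#' Solves the mass balance `x_total = L + m_total * sum_j j F_j(L)` for the
#' free titrant concentration L, where F_j are the binding-polynomial
#' occupancy fractions.  The residual is monotone in L, so a bracketed
#' search on [0, x_total] is guaranteed to converge.
#'
#' @param model A [sequential_model()].
#' @param m_total Total macromolecule (hexamer-basis) concentration, molar.
#' @param x_total Total titrant concentration, molar.
#' @return Free ligand concentration in molar (vectorized over the totals).
#' @export
sequential_free_ligand <- function(model, m_total, x_total) {
  stopifnot(inherits(model, "sequential_model"))
  if (any(m_total < 0) || any(x_total < 0)) stop("totals must be non-negative")
  n <- max(length(m_total), length(x_total))
  m_total <- rep_len(m_total, n); x_total <- rep_len(x_total, n)
  beta <- cumprod(model$ka)
  vapply(seq_len(n), function(i) {
    x <- x_total[i]; m <- m_total[i]
    if (x == 0) return(0)
    resid <- function(l) {
      bl <- beta * l^(1:3)
      l + m * sum((1:3) * bl) / (1 + sum(bl)) - x
    }
    if (all(beta == 0)) return(x)
    r <- stats::uniroot(resid, lower = 0, upper = x,
                        tol = .Machine$double.eps * max(x, 1e-30),
                        maxiter = 2000)
    l <- r$root
    # Newton polish for a residual below 1e-12 * x_total
    for (k in 1:4) {
      fr <- resid(l)
      if (abs(fr) < 1e-13 * x) break
      eps <- max(l, x) * 1e-8
      dfr <- (resid(l + eps) - fr) / eps
      step <- fr / dfr
      if (!is.finite(step)) break
      l2 <- l - step
      if (l2 < 0 || l2 > x) break
      l <- l2
    }
    if (abs(resid(l)) > 1e-12 * x)
      stop(sprintf("free-ligand solver did not reach tolerance: residual %g at L = %g",
                   resid(l), l))
    l
  }, numeric(1))
}

# Cumulative heat content (kcal) of the cell under the sequential model:
# Q = m_total * V0 * sum_j F_j(L) * (h1 + ... + hj).
sequential_total_heat <- function(model, m_total, x_total, cell_volume) {
  l <- sequential_free_ligand(model, m_total, x_total)
  fr <- sequential_fractions(model, l)
  h_cum <- cumsum(model$dh)
  m_total * cell_volume * as.numeric(fr %*% h_cum)
}

#' Simulate a sequential-binding-sites isotherm
#'
#' Forward-models per-injection heats for the three-event sequential model.
#' Differencing and normalization follow [oss_isotherm()].  With
#' `reverse = TRUE` the roles are swapped: the macromolecule (hexamer basis)
#' is in the syringe and LC8 in the cell, emulating a reversed titration;
#' heats are still normalized per mole of injectant.
#'
#' @param model A [sequential_model()].
#' @param schedule An [injection_schedule()].  For the forward direction the
#'   cell concentration is the hexamer-basis macromolecule; for
#'   `reverse = TRUE` the cell holds the ligand and the syringe the
#'   macromolecule.
#' @param reverse Reversed titration direction (default FALSE).
#' @inheritParams oss_isotherm
#' @return An `itc_isotherm`.
#' @export
sequential_isotherm <- function(model, schedule,
                                displacement_correction = TRUE,
                                dilution_offset = 0, reverse = FALSE) {
  stopifnot(inherits(model, "sequential_model"))
  conc <- dilute_concentrations(schedule)
  if (reverse) {
    q <- sequential_total_heat(model, conc$x_total, conc$m_total,
                               schedule$cell_volume)
  } else {
    q <- sequential_total_heat(model, conc$m_total, conc$x_total,
                               schedule$cell_volume)
  }
  new_isotherm(schedule, q, conc,
               displacement_correction = displacement_correction,
               dilution_offset = dilution_offset,
               model = list(type = "sequential", params = model,
                            reverse = reverse))
}

#' Count phases of an isotherm from its curvature
#'
#' Counts strict sign changes of the second difference of the normalized-heat
#' curve.  A single-phase sigmoidal isotherm has one curvature sign change
#' (its single inflection); a two-phase isotherm with a visible intermediate
#' shows additional curvature reversals.
#'
#' @param isotherm An `itc_isotherm` (or a numeric vector of normalized
#'   heats).
#' @param tol Curvature magnitudes below `tol` times the largest are treated
#'   as zero (default 1e-6).
#' @return Integer count of curvature sign changes.
#' @export
curvature_sign_changes <- function(isotherm, tol = 1e-6) {
  y <- if (inherits(isotherm, "itc_isotherm")) isotherm$normalized_heats
       else as.numeric(isotherm)
  d2 <- diff(diff(y))
  if (!length(d2)) return(0L)
  d2[abs(d2) < tol * max(abs(d2))] <- 0
  s <- sign(d2)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}
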