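#' Two-affinity ladder model of LC8-bridged 53BP1 assembly
#'
#' Mass-action model with two affinity classes: intratrimer LC8 binding
#' (one LC8 dimer joins two chains of the same trimer at a QT register) and
#' bridging binding (one LC8 dimer joins the leftover chains of two trimers
#' at a register, forming the dimer-of-trimers).  Species free energies are
#' additive over bound LC8: each intratrimer event contributes `kd_intra`,
#' each bridging event `kd_bridge`.
#'
#' @param q Intact QT sites per chain (1, 2 or 3).
#' @param kd_intra Intratrimer dissociation constant, molar.
#' @param kd_bridge Bridging dissociation constant, molar; `Inf` switches
#'   bridging off.
#' @param degeneracy Include combinatorial statistical factors (3 chain-pair
#'   choices per intratrimer LC8 at an unbridged register); default TRUE.
#'   Disable when the dissociation constants already absorb degeneracy, as
#'   fitted constants do.
#' @param m_min Minimal total LC8 occupancy of a bridged species; defaults to
#'   `q`, the trimer-complex load, so the q = 3 ladder spans occupancies 3-9.
#'   Every bridged species additionally carries at least one bridging LC8.
#' @return An object of class `ladder_model`.
#' @examples
#' ladder_model(q = 3, kd_intra = 0.3e-6, kd_bridge = 1.1e-6)
#' @export
ladder_model <- function(q, kd_intra, kd_bridge, degeneracy = TRUE,
                         m_min = q) {
  if (!q %in% 1:3) stop("q must be 1, 2 or 3")
  if (kd_intra <= 0) stop("kd_intra must be > 0 (molar)")
  if (kd_bridge <= 0) stop("kd_bridge must be > 0 (molar); use Inf to disable bridging")
  if (m_min < 1 || m_min > 3 * q) stop("m_min must lie in [1, 3q]")
  structure(list(q = q, kd_intra = kd_intra, kd_bridge = kd_bridge,
                 degeneracy = isTRUE(degeneracy), m_min = m_min),
            class = "ladder_model")
}

#' @export
print.ladder_model <- function(x, ...) {
  cat(sprintf(
    "Bridging ladder: q = %d, Kd(intratrimer) = %.3g uM, Kd(bridging) = %.3g uM, degeneracy %s\n",
    x$q, x$kd_intra * 1e6, x$kd_bridge * 1e6,
    if (x$degeneracy) "on" else "off"))
  invisible(x)
}

# Statistical weight of a trimer carrying j intratrimer LC8:
# choose j of q registers; 3 chain-pair choices per occupied register if
# degeneracy is on.
.trimer_weights <- function(q, degeneracy) {
  j <- 0:q
  w <- choose(q, j)
  if (degeneracy) w <- w * 3^j
  w
}

# Micro-configurations of the bridged dimer-of-trimers: nb bridging LC8
# (1..q registers) and ni intratrimer LC8 over the 2q trimer-register slots.
# With degeneracy on, an intratrimer LC8 at an unbridged register has 3
# chain-pair choices; at a bridged register the bridge pins the third chain,
# leaving 1.  Weight of (ni, nb) is C(q, nb) * [x^ni] (1+3x)^(2(q-nb)) (1+x)^(2 nb)
# (all-ones factors when degeneracy is off).
.bridged_configs <- function(q, degeneracy, m_min) {
  rows <- list()
  for (nb in 1:q) {
    # polynomial coefficients in x for the intratrimer placements
    free_slots <- 2 * (q - nb)
    pinned_slots <- 2 * nb
    f <- if (degeneracy) 3 else 1
    pa <- choose(free_slots, 0:free_slots) * f^(0:free_slots)
    pb <- choose(pinned_slots, 0:pinned_slots)
    coef <- numeric(free_slots + pinned_slots + 1)
    for (i in seq_along(pa))
      coef[i:(i + pinned_slots)] <- coef[i:(i + pinned_slots)] + pa[i] * pb
    for (ni in 0:(2 * q)) {
      m <- ni + nb
      if (m < m_min) next
      w <- choose(q, nb) * coef[ni + 1]
      if (w <= 0) next
      rows[[length(rows) + 1]] <- c(ni = ni, nb = nb, m = m, w = w)
    }
  }
  as.data.frame(do.call(rbind, rows))
}

#' Enumerate the species of the bridging ladder
#'
#' Lists the compositions the model can populate: the free trimer, trimer
#' complexes with 1..q LC8 dimers, and bridged dimer-of-trimers species with
#' total occupancy `m_min`..3q.  For q = 3 the bridged ladder spans 3 to 9
#' LC8 dimers.
#'
#' @inheritParams ladder_model
#' @param masses Optional [mass_table()]; when given, an `expected_mass_kDa`
#'   column is added.
#' @return A data frame with columns `n_trimers`, `n_lc8_dimers`, `species`.
#' @export
enumerate_species <- function(q, m_min = q, masses = NULL) {
  if (!q %in% 1:3) stop("q must be 1, 2 or 3")
  if (m_min < 1 || m_min > 3 * q) stop("m_min must lie in [1, 3q]")
  df <- rbind(
    data.frame(n_trimers = 1, n_lc8_dimers = 0),
    data.frame(n_trimers = 1, n_lc8_dimers = 1:q),
    data.frame(n_trimers = 2, n_lc8_dimers = m_min:(3 * q)))
  df$species <- ifelse(df$n_trimers == 1 & df$n_lc8_dimers == 0, "free trimer",
                ifelse(df$n_trimers == 1,
                       sprintf("trimer:%dLC8", df$n_lc8_dimers),
                       sprintf("bridged:%dLC8", df$n_lc8_dimers)))
  # every row must satisfy the composition invariants
  for (i in seq_len(nrow(df)))
    species_composition(df$n_trimers[i], df$n_lc8_dimers[i], q)
  if (!is.null(masses))
    df$expected_mass_kDa <- df$n_trimers * 3 * masses$lbd_od_monomer +
      df$n_lc8_dimers * masses$lc8_dimer
  df
}

#' Equilibrium speciation of 53BP1 trimers and LC8
#'
#' Solves the two coupled mass balances (total trimer, total LC8 dimer) for
#' the free concentrations, then populates every ladder species by mass
#' action.  For fixed free LC8 the trimer balance is quadratic in the free
#' trimer and solved in closed form; the outer free-LC8 root is bracketed in
#' `[0, total_lc8_dimer]` and refined until both conservation residuals are
#' below `1e-12` of the totals.
#'
#' @param total_trimer Total 53BP1 trimer concentration, molar.
#' @param total_lc8_dimer Total LC8 dimer concentration, molar.
#' @param model A [ladder_model()].
#' @return An object of class `speciation_state`: `species` (data frame with
#'   `n_trimers`, `n_lc8_dimers`, `conc` in molar for every bound complex),
#'   `free_trimer`, `free_lc8`, the model and the totals.
#' @examples
#' speciate(10e-6, 20e-6, ladder_model(1, 0.3e-6, 1.1e-6))
#' @export
speciate <- function(total_trimer, total_lc8_dimer, model) {
  stopifnot(inherits(model, "ladder_model"))
  if (total_trimer < 0 || total_lc8_dimer < 0)
    stop("totals must be non-negative")
  q <- model$q
  ki <- 1 / model$kd_intra
  kb <- if (is.finite(model$kd_bridge)) 1 / model$kd_bridge else 0
  w1 <- .trimer_weights(q, model$degeneracy)      # j = 0..q
  cfg <- .bridged_configs(q, model$degeneracy, model$m_min)

  eval_at <- function(L) {
    a <- ki * L; b <- kb * L
    t1 <- w1 * a^(0:q)                      # per-trimer ladder terms
    # Dimer-of-trimers: each bound LC8 contributes one association factor,
    # and the trimer-trimer junction contributes one more (the first
    # bridging LC8 engages both grooves; ring closure by further bridges is
    # absorbed into kd_bridge), so terms carry kb^(nb+1).
    t2 <- cfg$w * a^cfg$ni * b^cfg$nb * kb  # dimer-of-trimers terms
    P1 <- sum(t1); S1 <- sum((0:q) * t1)
    P2 <- sum(t2); S2 <- sum(cfg$m * t2)
    Tt <- if (P2 > 0) {
      (-P1 + sqrt(P1^2 + 8 * P2 * total_trimer)) / (4 * P2)
    } else total_trimer / P1
    list(T = Tt, t1 = t1, t2 = t2, S1 = S1, S2 = S2)
  }
  lc8_bound <- function(L) {
    e <- eval_at(L)
    e$T * e$S1 + e$T^2 * e$S2
  }

  if (total_lc8_dimer == 0 || (ki == 0 && kb == 0)) {
    L <- total_lc8_dimer
  } else {
    resid <- function(L) L + lc8_bound(L) - total_lc8_dimer
    r <- stats::uniroot(resid, lower = 0, upper = total_lc8_dimer,
                        tol = .Machine$double.eps * total_lc8_dimer,
                        maxiter = 3000)
    L <- r$root
    for (k in 1:6) {          # damped-Newton polish on the outer balance
      fr <- resid(L)
      if (abs(fr) < 1e-13 * total_lc8_dimer) break
      eps <- max(L, total_lc8_dimer) * 1e-8
      dfr <- (resid(L + eps) - fr) / eps
      step <- fr / dfr
      if (!is.finite(step)) break
      L2 <- L - step
      if (L2 < 0 || L2 > total_lc8_dimer) step <- step / 2
      L2 <- L - step
      if (L2 >= 0 && L2 <= total_lc8_dimer) L <- L2
    }
    if (abs(resid(L)) > 1e-9 * max(total_lc8_dimer, 1e-30))
      stop(sprintf("speciation solver: LC8 balance residual %g at free LC8 = %g",
                   resid(L), L))
  }

  e <- eval_at(L)
  Tt <- e$T
  sp1 <- data.frame(n_trimers = 1, n_lc8_dimers = 1:q,
                    conc = Tt * e$t1[-1])
  sp2 <- if (nrow(cfg)) {
    agg <- tapply(Tt^2 * e$t2, cfg$m, sum)
    data.frame(n_trimers = 2, n_lc8_dimers = as.integer(names(agg)),
               conc = as.numeric(agg))
  } else NULL
  species <- rbind(sp1, sp2)
  species$species <- ifelse(species$n_trimers == 1,
                            sprintf("trimer:%dLC8", species$n_lc8_dimers),
                            sprintf("bridged:%dLC8", species$n_lc8_dimers))
  state <- structure(list(species = species, free_trimer = Tt, free_lc8 = L,
                          model = model,
                          totals = c(trimer = total_trimer,
                                     lc8_dimer = total_lc8_dimer),
                          micro = cbind(cfg, conc = Tt^2 * e$t2)),
                     class = "speciation_state")
  .check_conservation(state)
  state
}

.check_conservation <- function(state) {
  sp <- state$species
  tt <- sum(sp$n_trimers * sp$conc) + state$free_trimer
  tl <- sum(sp$n_lc8_dimers * sp$conc) + state$free_lc8
  tol_t <- 1e-9 * max(state$totals["trimer"], 1e-30)
  tol_l <- 1e-9 * max(state$totals["lc8_dimer"], 1e-30)
  if (abs(tt - state$totals["trimer"]) > tol_t ||
      abs(tl - state$totals["lc8_dimer"]) > tol_l)
    stop(sprintf("conservation violated: trimer residual %g, LC8 residual %g",
                 tt - state$totals["trimer"], tl - state$totals["lc8_dimer"]))
  invisible(state)
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf(
    "Speciation (q = %d): free trimer %.3g uM, free LC8 %.3g uM\n",
    x$model$q, x$free_trimer * 1e6, x$free_lc8 * 1e6))
  pop <- x$species[x$species$conc > 1e-3 * max(x$species$conc), ]
  for (i in seq_len(nrow(pop)))
    cat(sprintf("  %-14s %.4g uM\n", pop$species[i], pop$conc[i] * 1e6))
  invisible(x)
}

#' Fraction of trimers in bridged (two-trimer) species
#'
#' @param state A `speciation_state`.
#' @return Fraction of total trimer residing in dimer-of-trimers species.
#' @export
bridged_fraction <- function(state) {
  stopifnot(inherits(state, "speciation_state"))
  if (state$totals["trimer"] == 0) return(0)
  sp <- state$species
  sum(sp$conc[sp$n_trimers == 2] * 2) / state$totals[["trimer"]]
}

#' Mass-weighted profile of a speciation state
#'
#' Converts species concentrations to the quantities a SEC-MALS experiment
#' reports: weight fractions (proportional to concentration times mass) and
#' the weight-average molar mass `sum(c m^2) / sum(c m)`.
#'
#' @param state A `speciation_state`.
#' @param masses A [mass_table()].
#' @param include_free Include the free trimer and free LC8 dimer as species
#'   (default TRUE).
#' @return List with `profile` (data frame: species, conc, mass_kDa,
#'   weight_fraction) and `weight_average_mass` (kDa).
#' @export
mass_profile <- function(state, masses = mass_table(), include_free = TRUE) {
  stopifnot(inherits(state, "speciation_state"), inherits(masses, "mass_table"))
  sp <- state$species
  m <- sp$n_trimers * 3 * masses$lbd_od_monomer +
    sp$n_lc8_dimers * masses$lc8_dimer
  df <- data.frame(species = sp$species, conc = sp$conc, mass_kDa = m)
  if (include_free) {
    df <- rbind(data.frame(species = c("free trimer", "free LC8 dimer"),
                           conc = c(state$free_trimer, state$free_lc8),
                           mass_kDa = c(3 * masses$lbd_od_monomer,
                                        masses$lc8_dimer)),
                df)
  }
  cm <- df$conc * df$mass_kDa
  if (sum(cm) <= 0) stop("empty state: no populated species")
  df$weight_fraction <- cm / sum(cm)
  mw <- sum(df$conc * df$mass_kDa^2) / sum(cm)
  list(profile = df, weight_average_mass = mw)
}

#' Speciation along an LC8 titration
#'
#' Runs [speciate()] at each LC8:trimer molar equivalent and summarizes the
#' population shift from free trimer through the trimer complex to the
#' bridged dimer-of-trimers.
#'
#' @param equivalents Non-decreasing vector of LC8-dimer : trimer molar
#'   ratios (>= 0).
#' @param total_trimer Total trimer concentration, molar.
#' @param model A [ladder_model()].
#' @return List with `states` (one `speciation_state` per equivalent) and
#'   `summary` (data frame: equivalents, free/trimer-complex/bridged trimer
#'   fractions, bound LC8).
#' @export
titration_profile <- function(equivalents, total_trimer, model) {
  if (any(equivalents < 0)) stop("equivalents must be non-negative")
  if (is.unsorted(equivalents)) stop("equivalents must be non-decreasing")
  states <- lapply(equivalents, function(e)
    speciate(total_trimer, e * total_trimer, model))
  summ <- do.call(rbind, lapply(seq_along(states), function(i) {
    st <- states[[i]]
    sp <- st$species
    tot <- max(st$totals[["trimer"]], .Machine$double.xmin)
    data.frame(equivalents = equivalents[i],
               free_trimer_fraction = st$free_trimer / tot,
               trimer_complex_fraction =
                 sum(sp$conc[sp$n_trimers == 1]) / tot,
               bridged_fraction = bridged_fraction(st),
               bound_lc8 = sum(sp$n_lc8_dimers * sp$conc))
  }))
  list(states = states, summary = summ)
}

#' Assign the nearest enumerated composition to a measured mass
#'
#' Compares a measured molar mass (e.g. from SEC-MALS) against the expected
#' masses of every enumerated species and returns the closest, with ties
#' broken toward fewer LC8 dimers.  The distance is reported rather than an
#' identity asserted: intermediate observed masses may correspond to
#' partially occupied bridged species or to unmodeled oligomeric states.
#'
#' @param measured_mass Measured mass, kDa (> 0).
#' @param q Intact QT sites per chain.
#' @param masses A [mass_table()].
#' @param m_min Minimal bridged occupancy to consider (default `q`).
#' @return A [species_composition()] with attributes `expected_mass_kDa` and
#'   `mass_error_kDa`.
#' @examples
#' assign_composition(296, q = 3)  # 2 trimers : 9 LC8 dimers (292.8 kDa)
#' @export
assign_composition <- function(measured_mass, q, masses = mass_table(),
                               m_min = q) {
  if (measured_mass <= 0) stop("measured_mass must be > 0 (kDa)")
  sp <- enumerate_species(q, m_min = m_min, masses = masses)
  err <- abs(sp$expected_mass_kDa - measured_mass)
  ord <- order(err, sp$n_lc8_dimers)
  best <- sp[ord[1], ]
  out <- species_composition(best$n_trimers, best$n_lc8_dimers, q)
  attr(out, "expected_mass_kDa") <- best$expected_mass_kDa
  attr(out, "mass_error_kDa") <- err[ord[1]]
  out
}
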