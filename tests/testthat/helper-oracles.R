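# Independent numerical oracles used to validate the closed-form and
# polynomial-root implementations.  They share only the model definitions
# (mass balance, species law), never the package's solution path.

# One-set-of-sites: solve the free-ligand mass balance by plain bisection
# and return the cumulative heat content in kcal.  Independent of the
# Wiseman closed form used by oss_total_heat().
oracle_oss_total_heat <- function(n, ka, dh, m_total, x_total, cell_volume) {
  vapply(seq_along(m_total), function(i) {
    m <- m_total[i]; x <- x_total[i]
    if (x == 0 || m == 0) return(0)
    # bound ligand B solves x = F + n m Ka F / (1 + Ka F), B = x - F
    f_res <- function(f) f + n * m * ka * f / (1 + ka * f) - x
    lo <- 0; hi <- x
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (f_res(mid) > 0) hi <- mid else lo <- mid
    }
    f <- (lo + hi) / 2
    dh * (x - f) * cell_volume
  }, numeric(1))
}

# Difference cumulative heats exactly as the package documents, without
# calling package internals.
oracle_normalized_heats <- function(q_total, schedule) {
  V0 <- schedule$cell_volume
  dv <- schedule$injection_volumes
  q_prev <- c(0, q_total[-length(q_total)])
  dq <- q_total - q_prev + (dv / V0) * (q_total + q_prev) / 2
  dq / (dv * schedule$syringe_conc)
}

# Sequential model: free ligand by refining grid search on the mass-balance
# residual (no root bracketing shared with the package solver).
oracle_sequential_free_ligand <- function(ka, m, x, grid_n = 400,
                                          passes = 8) {
  if (x == 0) return(0)
  beta <- cumprod(ka)
  resid <- function(l) {
    bl <- beta * l^(1:3)
    abs(l + m * sum((1:3) * bl) / (1 + sum(bl)) - x)
  }
  lo <- 0; hi <- x
  for (p in seq_len(passes)) {
    g <- seq(lo, hi, length.out = grid_n)
    r <- vapply(g, resid, numeric(1))
    i <- which.min(r)
    lo <- g[max(i - 1, 1)]; hi <- g[min(i + 1, grid_n)]
  }
  (lo + hi) / 2
}

# Speciation: species concentrations from free (T, L) under the same
# mass-action law (weights recomputed here from first principles), and a
# refining 2-D grid search minimizing the joint conservation residual.
oracle_species_conc <- function(Tt, L, q, kd_intra, kd_bridge, degeneracy,
                                m_min = q) {
  ki <- 1 / kd_intra
  kb <- if (is.finite(kd_bridge)) 1 / kd_bridge else 0
  a <- ki * L; b <- kb * L
  s <- if (degeneracy) 3 else 1
  out <- list()
  for (j in 0:q)
    out[[length(out) + 1]] <- c(nt = 1, m = j,
                                conc = choose(q, j) * s^j * a^j * Tt)
  for (nb in 1:q) for (ni in 0:(2 * q)) {
    if (ni + nb < m_min) next
    # intra placements: 2(q-nb) slots with factor s, 2nb pinned slots
    w <- 0
    for (nf in 0:min(ni, 2 * (q - nb))) {
      npin <- ni - nf
      if (npin > 2 * nb) next
      w <- w + choose(2 * (q - nb), nf) * s^nf * choose(2 * nb, npin)
    }
    w <- w * choose(q, nb)
    out[[length(out) + 1]] <- c(nt = 2, m = ni + nb,
                                conc = w * a^ni * b^nb * kb * Tt^2)
  }
  df <- as.data.frame(do.call(rbind, out))
  stats::aggregate(conc ~ nt + m, df, sum)
}

oracle_speciate <- function(total_trimer, total_lc8, q, kd_intra, kd_bridge,
                            degeneracy = TRUE, m_min = q,
                            grid_n = 60, passes = 10) {
  # joint residual over both conservation balances; the free trimer is the
  # (nt = 1, m = 0) species row, free LC8 enters the L balance directly
  joint <- function(Tt, L) {
    sp <- oracle_species_conc(Tt, L, q, kd_intra, kd_bridge, degeneracy,
                              m_min)
    tt <- sum(sp$nt * sp$conc)
    ll <- L + sum(sp$m * sp$conc)
    abs(tt - total_trimer) / max(total_trimer, 1e-30) +
      abs(ll - total_lc8) / max(total_lc8, 1e-30)
  }
  t_lo <- 0; t_hi <- total_trimer; l_lo <- 0; l_hi <- total_lc8
  for (p in seq_len(passes)) {
    tg <- seq(t_lo, t_hi, length.out = grid_n)
    lg <- seq(l_lo, l_hi, length.out = grid_n)
    r <- outer(tg, lg, Vectorize(joint))
    i <- which(r == min(r), arr.ind = TRUE)[1, ]
    t_lo <- tg[max(i[1] - 1, 1)]; t_hi <- tg[min(i[1] + 1, grid_n)]
    l_lo <- lg[max(i[2] - 1, 1)]; l_hi <- lg[min(i[2] + 1, grid_n)]
  }
  Tt <- (t_lo + t_hi) / 2; L <- (l_lo + l_hi) / 2
  list(free_trimer = Tt, free_lc8 = L,
       species = oracle_species_conc(Tt, L, q, kd_intra, kd_bridge,
                                     degeneracy, m_min))
}
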