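test_that("species enumeration spans the documented occupancy ladders", {
  e3 <- enumerate_species(3)
  bridged <- e3$n_lc8_dimers[e3$n_trimers == 2]
  expect_equal(bridged, 3:9)   # two-trimer intermediates hold 3..9 LC8
  e1 <- enumerate_species(1)
  expect_equal(max(e1$n_lc8_dimers[e1$n_trimers == 2]), 3)
  expect_equal(max(e1$n_lc8_dimers[e1$n_trimers == 1]), 1)
  e2 <- enumerate_species(2)
  expect_equal(range(e2$n_lc8_dimers[e2$n_trimers == 2]), c(2, 6))
  # constructive guarantee: every row satisfies the composition invariants
  for (q in 1:3) {
    e <- enumerate_species(q)
    for (i in seq_len(nrow(e)))
      expect_s3_class(species_composition(e$n_trimers[i], e$n_lc8_dimers[i], q),
                      "species_composition")
  }
})

test_that("speciation limits: no ligand, no bridging", {
  m <- ladder_model(1, 0.3e-6, 1.1e-6)
  st0 <- speciate(10e-6, 0, m)
  expect_equal(st0$free_trimer, 10e-6)
  expect_equal(sum(st0$species$conc), 0)
  st_nb <- speciate(10e-6, 20e-6, ladder_model(1, 0.3e-6, Inf))
  expect_equal(sum(st_nb$species$conc[st_nb$species$n_trimers == 2]), 0)
  expect_gt(sum(st_nb$species$conc[st_nb$species$n_trimers == 1]), 0)
})

test_that("speciate matches the brute-force grid oracle", {
  m <- ladder_model(1, 0.3e-6, 1.1e-6)
  st <- speciate(10e-6, 20e-6, m)
  or <- oracle_speciate(10e-6, 20e-6, 1, 0.3e-6, 1.1e-6)
  expect_equal(st$free_trimer, or$free_trimer,
               tolerance = 1e-4)
  expect_equal(st$free_lc8, or$free_lc8, tolerance = 1e-4)
  for (i in seq_len(nrow(st$species))) {
    row <- st$species[i, ]
    oc <- or$species$conc[or$species$nt == row$n_trimers &
                            or$species$m == row$n_lc8_dimers]
    if (row$conc > 1e-12)
      expect_equal(row$conc, oc, tolerance = 1e-3)
  }
})

test_that("both totals are conserved across random scenarios", {
  set.seed(13)
  for (i in 1:250) {
    q <- sample(1:3, 1)
    m <- ladder_model(q, 10^runif(1, -8, -5), 10^runif(1, -8, -4),
                      degeneracy = sample(c(TRUE, FALSE), 1))
    tt <- runif(1, 1e-7, 5e-5)
    tl <- runif(1, 0, 2e-4)
    st <- speciate(tt, tl, m)   # speciate() itself errors if conservation fails
    sp <- st$species
    expect_equal(sum(sp$n_trimers * sp$conc) + st$free_trimer, tt,
                 tolerance = 1e-9)
    expect_equal(sum(sp$n_lc8_dimers * sp$conc) + st$free_lc8, tl,
                 tolerance = 1e-9)
  }
})

test_that("bridged fraction is monotone non-increasing in kd_bridge", {
  kds <- 10^seq(-7.5, -4, length.out = 12)
  bf <- vapply(kds, function(kb)
    bridged_fraction(speciate(10e-6, 30e-6, ladder_model(3, 0.3e-6, kb))),
    numeric(1))
  expect_true(all(diff(bf) <= 1e-12))
})

test_that("equilibrium concentrations reproduce the input constants", {
  m <- ladder_model(2, 0.5e-6, 2e-6)
  st <- speciate(8e-6, 25e-6, m)
  L <- st$free_lc8
  # intratrimer ladder: c(1, j+1)/c(1, j) = w(j+1)/w(j) * L / kd_intra
  w <- itcbridge:::.trimer_weights(2, TRUE)
  sp1 <- st$species[st$species$n_trimers == 1, ]
  kd_rec <- (w[3] / w[2]) * L * sp1$conc[1] / sp1$conc[2]
  expect_equal(kd_rec, 0.5e-6, tolerance = 1e-6)
  # bridging: micro-states differing by one bridging LC8 at fixed intra load
  mic <- st$micro
  i1 <- which(mic$ni == 1 & mic$nb == 1)
  i2 <- which(mic$ni == 1 & mic$nb == 2)
  kd_b <- (mic$w[i2] / mic$w[i1]) * L * mic$conc[i1] / mic$conc[i2]
  expect_equal(kd_b, 2e-6, tolerance = 1e-6)
})

test_that("with bridging off the bound fraction matches the closed form", {
  # independent registers, each with a single intratrimer site: the ladder
  # reduces to q independent-site binding with statistical factor 3
  q <- 2; kd <- 0.5e-6
  m <- ladder_model(q, kd, Inf, degeneracy = TRUE)
  st <- speciate(5e-6, 12e-6, m)
  L <- st$free_lc8
  kd_eff <- kd / 3   # per-register effective constant with 3 pair choices
  occ <- L / (kd_eff + L)   # per-register occupancy at free ligand L
  bound_closed <- q * occ * 5e-6
  sp <- st$species
  expect_equal(sum(sp$n_lc8_dimers * sp$conc), bound_closed,
               tolerance = 1e-6)
})

test_that("mass profile reports weight fractions and averages", {
  mt <- mass_table()
  # construct a two-species state: equal molar (1:3) and (2:9), q = 3
  m <- ladder_model(3, 0.3e-6, 1.1e-6)
  st <- speciate(1e-6, 1e-6, m)  # populate, then overwrite concentrations
  st$species$conc <- ifelse(
    st$species$n_trimers == 1 & st$species$n_lc8_dimers == 3, 1e-6,
    ifelse(st$species$n_trimers == 2 & st$species$n_lc8_dimers == 9, 1e-6, 0))
  st$free_trimer <- 0; st$free_lc8 <- 0
  st$totals <- c(trimer = 3e-6, lc8_dimer = 12e-6)
  mp <- mass_profile(st, mt)
  expect_gt(mp$weight_average_mass, 114.6)
  expect_lt(mp$weight_average_mass, 292.8)
  # single populated species: average equals that mass
  st$species$conc[st$species$n_trimers == 2 & st$species$n_lc8_dimers == 9] <- 0
  mp1 <- mass_profile(st, mt)
  expect_equal(mp1$weight_average_mass, 114.6)
  # scale invariance of weight fractions
  st$species$conc <- st$species$conc * 2
  expect_equal(mass_profile(st, mt)$profile$weight_fraction,
               mp1$profile$weight_fraction)
})

test_that("titration profiles separate plateau from direct bridging", {
  eq <- c(0, 0.25, 0.5, 1, 2, 3, 4)
  # comparable affinities: bridged fraction rises without a plateau
  close_kd <- titration_profile(eq, 10e-6, ladder_model(1, 0.3e-6, 1.1e-6))
  # weak bridging: trimer complex accumulates at intermediate equivalents
  weak_kd <- titration_profile(eq, 10e-6, ladder_model(1, 0.3e-6, 50e-6))
  expect_equal(close_kd$summary$free_trimer_fraction[1], 1)
  expect_gt(max(weak_kd$summary$trimer_complex_fraction), 0.9)
  expect_lt(max(weak_kd$summary$bridged_fraction), 0.1)
  expect_gt(max(close_kd$summary$bridged_fraction), 0.5)
  # occupancy bound: bound LC8 never exceeds 3q per 2 trimers
  q <- 1
  expect_true(all(close_kd$summary$bound_lc8 <= 3 * q * 10e-6 / 2 + 1e-12))
})

test_that("measured masses are assigned to nearest composition", {
  c1 <- assign_composition(296, q = 3)
  expect_equal(c1$n_trimers, 2); expect_equal(c1$n_lc8_dimers, 9)
  expect_equal(attr(c1, "mass_error_kDa"), 296 - 292.8, tolerance = 1e-9)
  c2 <- assign_composition(114.6, q = 3)
  expect_equal(c2$n_trimers, 1); expect_equal(c2$n_lc8_dimers, 3)
  expect_equal(attr(c2, "mass_error_kDa"), 0)
  c3 <- assign_composition(69, q = 1)
  expect_equal(c3$n_trimers, 1); expect_equal(c3$n_lc8_dimers, 1)
  expect_equal(attr(c3, "expected_mass_kDa"), 72.2)
  # tie broken toward fewer LC8 dimers
  e <- enumerate_species(3, masses = mass_table())
  mid <- mean(e$expected_mass_kDa[e$species %in% c("bridged:3LC8",
                                                   "bridged:4LC8")])
  c4 <- assign_composition(mid, q = 3)
  expect_equal(c4$n_lc8_dimers, 3)
})
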