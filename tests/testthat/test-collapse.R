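test_that("path discretization reproduces the widening law cell by cell", {
  prof <- build_path_profile(collapse_config(H = 1, delta_l = 0.1,
                                             alpha = 0.2))
  expect_equal(nrow(prof), 10)
  expect_equal(prof$L_mid, seq(0.05, 0.95, by = 0.1))
  # effective diameters against an independent numerical quadrature of the
  # resistance density d(L)^-4
  for (i in c(1, 4, 10)) {
    I <- integrate(function(L) (10 * L^0.2)^-4, (i - 1) * 0.1, i * 0.1,
                   rel.tol = 1e-12)$value
    expect_equal(prof$d_um[i], (0.1 / I)^(1 / 4), tolerance = 1e-8)
  }

  # pipe model: constant diameter
  pipe <- build_path_profile(collapse_config(alpha = 0, d0 = 10, H = 1,
                                             delta_l = 0.01))
  expect_true(all(pipe$d_um == 10))

  widening <- build_path_profile(collapse_config(alpha = 0.23, H = 2,
                                                 delta_l = 0.01))
  expect_true(all(diff(widening$d_um) > 0))
  expect_error(collapse_config(alpha = -0.1), "alpha")
})

test_that("node potentials match the continuum closed form when conduits taper", {
  # For d = d0 L^alpha the continuum potential is
  # psi(L) = psi_leaf + (psi_soil - psi_leaf) * (L/H)^(1 - 4 alpha)
  prof <- path_profile(collapse_config(H = 3, delta_l = 1e-3,
                                       alpha = 0.23))
  analytic <- -4.7 + 3.2 * prof$L_rel^(1 - 4 * 0.23)
  expect_equal(prof$psi_MPa, analytic, tolerance = 1e-9)
})

test_that("segment resistances follow the fourth-power Hagen-Poiseuille law", {
  cfg <- collapse_config(alpha = 0, d0 = 10, H = 1, delta_l = 1e-4)
  prof <- segment_resistances(build_path_profile(cfg))
  expect_equal(length(unique(prof$r_MPa_s_m3)), 1L)
  # direct arithmetic: 128 * 1.002e-9 * 1e-4 / (pi * (1e-5 m)^4)
  expect_equal(prof$r_MPa_s_m3[1], 4.0825152e8, tolerance = 1e-6)
  # doubling the diameter divides resistance by 16
  cfg2 <- collapse_config(alpha = 0, d0 = 20, H = 1, delta_l = 1e-4)
  prof2 <- segment_resistances(build_path_profile(cfg2))
  expect_equal(prof$r_MPa_s_m3[1] / prof2$r_MPa_s_m3[1], 16,
               tolerance = 1e-12)
})

test_that("the water-potential profile honours its boundary conditions", {
  prof <- path_profile(collapse_config(H = 5))
  cfg <- attr(prof, "config")
  # base node recovers psi_soil exactly (algebraic cancellation of R)
  expect_equal(tail(prof$psi_MPa, 1), cfg$psi_soil, tolerance = 1e-9)
  expect_false(is.unsorted(prof$psi_MPa))            # monotone tip->base
  expect_true(all(prof$psi_MPa >= cfg$psi_leaf - 1e-12))
  expect_true(all(prof$r_MPa_s_m3 > 0))
  expect_equal(attr(prof, "R_total"), sum(prof$r_MPa_s_m3))

  # uniform pipe: exactly linear potential profile
  pipe <- path_profile(collapse_config(alpha = 0, H = 5))
  N <- nrow(pipe)
  analytic <- -4.7 + (-1.5 - -4.7) * seq_len(N) / N
  expect_equal(pipe$psi_MPa, analytic, tolerance = 1e-9)
})

test_that("most of the potential drop occurs near the tip when conduits taper", {
  prof <- path_profile(collapse_config(H = 30, alpha = 0.23))
  cfg <- attr(prof, "config")
  drop_total <- cfg$psi_soil - cfg$psi_leaf
  distal <- prof$L_rel <= 0.1
  drop_distal <- max(prof$psi_MPa[distal]) - cfg$psi_leaf
  expect_gt(drop_distal / drop_total, 0.5)
  # analytic oracle: the resistance fraction within the distal tenth is
  # 0.1^(1 - 4 alpha)
  expect_equal(drop_distal / drop_total, 0.1^(1 - 4 * 0.23),
               tolerance = 1e-9)
})

test_that("critical limit endpoints are the analytic boundary values", {
  for (alpha in c(0, 0.17, 0.23, 0.5)) {
    prof <- path_profile(collapse_config(alpha = alpha, H = 3,
                                         delta_l = 1e-3))
    expect_equal(attr(prof, "tb2_crit_tip"), 4.7 * 0.25 / 41.6,
                 tolerance = 1e-12)
    expect_equal(attr(prof, "tb2_crit_base"), 1.5 * 0.25 / 41.6,
                 tolerance = 1e-12)
    expect_false(is.unsorted(rev(prof$tb2_crit)))   # non-increasing
    expect_true(all(prof$tb2_crit > 0))
  }
  # zero tension gives a zero critical limit
  relaxed <- path_profile(collapse_config(psi_soil = 0, psi_leaf = -1,
                                          H = 3, delta_l = 1e-3))
  expect_equal(tail(relaxed$tb2_crit, 1), 0, tolerance = 1e-12)
})

test_that("potentials and critical limits are invariant to d0 and eta", {
  base <- path_profile(collapse_config(H = 3, delta_l = 1e-3))
  scaled <- path_profile(collapse_config(H = 3, delta_l = 1e-3,
                                         d0 = 10 * 1e3, eta = 1.002e-9 * 1e3))
  expect_lt(max(abs(scaled$psi_MPa - base$psi_MPa) / abs(base$psi_MPa)),
            1e-9)
  expect_lt(max(abs(scaled$tb2_crit - base$tb2_crit) /
                pmax(base$tb2_crit, 1e-300)), 1e-9)
})

test_that("halving the segment length leaves the potential profile unchanged", {
  coarse <- path_profile(collapse_config(H = 3, delta_l = 2e-4))
  fine <- path_profile(collapse_config(H = 3, delta_l = 1e-4))
  # coarse node i sits at fine node 2i; the exact-quadrature resistances
  # make the node potentials grid-independent to rounding error
  expect_lt(max(abs(fine$psi_MPa[2 * seq_len(nrow(coarse))] -
                    coarse$psi_MPa) / abs(coarse$psi_MPa)), 1e-9)
})

test_that("safety factors compare observed walls with the local limit", {
  prof <- path_profile(collapse_config())
  rec <- generate_conduits(small_config())
  m <- conduit_metrics(rec)

  # a conduit exactly at the limit is safe; below it is flagged
  tb2_crit_mid <- xylemtaper:::crit_at_L_rel(prof, 0.5)
  probe <- m[1:3, ]
  probe$L_rel <- 0.5
  probe$tb2 <- tb2_crit_mid * c(1, 0.99, 1.5)
  sf <- safety_factors(probe, prof)
  expect_equal(sf$per_conduit$safety_factor, c(1, 0.99, 1.5),
               tolerance = 1e-12)
  expect_equal(sf$per_conduit$collapse_flag, c(FALSE, TRUE, FALSE))
  expect_equal(sf$fraction_safe + mean(sf$per_conduit$collapse_flag), 1)

  # an under-built wall at the leaf tip: 0.0090 / 0.0282 = 0.32
  tip_probe <- probe[1, ]
  tip_probe$L_rel <- 0
  tip_probe$tb2 <- 0.0090
  sf_tip <- safety_factors(tip_probe, prof)
  expect_equal(sf_tip$per_conduit$safety_factor, 0.3186, tolerance = 1e-3)
  expect_true(sf_tip$per_conduit$collapse_flag)

  bad <- probe; bad$L_rel <- 1.2
  expect_error(safety_factors(bad, prof), "L_rel")

  # breakdown tables partition the conduits
  full <- safety_factors(m, prof)
  expect_equal(sum(full$by_wood_type$n), nrow(m))
  expect_equal(sum(full$by_organ$n), nrow(m))
})

test_that("species-specific limits scale inversely with the modulus", {
  rec <- conduit_metrics(generate_conduits(small_config()))
  rec$species <- rep(c("A", "B"), length.out = nrow(rec))
  cfg <- collapse_config()

  same <- species_specific_limits(rec, cfg,
                                  species_sigma = c(A = 41.6, B = 41.6))
  pooled <- safety_factors(rec, path_profile(cfg))
  both <- rbind(same$A$per_conduit, same$B$per_conduit)
  expect_equal(sort(both$safety_factor),
               sort(pooled$per_conduit$safety_factor), tolerance = 1e-12)

  halved <- species_specific_limits(rec, cfg,
                                    species_sigma = c(A = 41.6, B = 20.8))
  expect_equal(halved$B$per_conduit$tb2_crit,
               same$B$per_conduit$tb2_crit * 2, tolerance = 1e-12)
  expect_equal(halved$B$per_conduit$safety_factor,
               same$B$per_conduit$safety_factor / 2, tolerance = 1e-12)

  expect_error(species_specific_limits(rec, cfg,
                                       species_sigma = c(A = 41.6)),
               "B")
})
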