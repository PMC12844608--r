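# Frozen expected values below were computed by direct arithmetic on the
# reference unit means (sdm_ir = 5.06, sdm_c = 4.03, idm_ir = 3.79,
# idm_c = 1.48, z = 0.5/0.5), independently of the index functions.

test_that("partial and total RYT match direct arithmetic", {
  expect_equal(ryt_partial(1.48, 4.03, 0.5), 0.7344913151, tolerance = 1e-9)
  expect_equal(round(ryt_partial(1.48, 4.03, 0.5), 2), 0.73)
  expect_equal(ryt_partial(3.79, 5.06, 0.5), 1.4980237154, tolerance = 1e-9)
  expect_equal(ryt_partial(2.0, 4.0, 0.5), 1.0)
  expect_equal(ryt_total(1.51, 0.73), 2.24)
  expect_equal(ryt_total(1.26, 0.77), 2.03)
  expect_equal(ryt_total(1.0, 1.0), 2.0)
  expect_error(ryt_partial(1, 0, 0.5), class = "intercrop_undefined_index")
  expect_error(ryt_partial(1, 2, 0), class = "intercrop_undefined_index")
})

test_that("LEC variants differ by the sown-proportion denominators", {
  p <- ref_pair()
  expect_equal(lec(p), 1.1002854088, tolerance = 1e-9)
  expect_equal(lec(p, "raw_ratio_product"), 0.2750713522, tolerance = 1e-9)
  half <- stand_pair(sdm_ir = 4, sdm_c = 6, idm_ir = 2, idm_c = 3)
  expect_equal(lec(half), 1.0)
  expect_error(lec(stand_pair(0, 4, 1, 1)), class = "intercrop_undefined_index")
})

test_that("SPI converts clover yield into grass equivalents in kg/ha", {
  expect_equal(spi(ref_pair()), 5648.263027, tolerance = 1e-6)
  no_c <- stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 3.2, idm_c = 0)
  expect_equal(spi(no_c), 3200)
  eq <- stand_pair(sdm_ir = 4, sdm_c = 4, idm_ir = 2.5, idm_c = 1.5)
  expect_equal(spi(eq), (2.5 + 1.5) * 1000)
  # nitrogen basis is already kg/ha: no rescale
  n_pair <- ref_pair(basis = "n")
  expect_equal(spi(n_pair), spi(ref_pair()) / 1000)
})

test_that("ATER reduces to RYT at equal durations and scales with occupancy", {
  expect_equal(ater(1.51, 0.73, 200, 200, 200), 2.24)
  expect_equal(ater(1.26, 0.77, 253, 253, 253), 2.03)
  expect_equal(ater(1.0, 1.0, 100, 100, 200), 1.0)
  expect_error(ater(1, 1, 1, 1, 0), class = "intercrop_undefined_index")
})

test_that("PYD is anchored at 0 for neutral and 100 for compensating mixtures", {
  expect_equal(pyd(ref_pair()), 11.6257515276, tolerance = 1e-9)
  neutral <- stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 2.5, idm_c = 2)
  expect_equal(pyd(neutral), 0)
  full <- stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 5, idm_c = 4)
  expect_equal(pyd(full), 100)
})

test_that("LUE variants and their fixed points", {
  expect_equal(lue(2.04, 2.04), 306)
  expect_equal(lue(2.24, 2.24, "conventional"), 224)
  expect_equal(lue(1.0, 1.0), 150)
  expect_equal(lue(1.0, 1.0, "conventional"), 100)
})

test_that("competitive ratio: value, reciprocity and flagged infinity", {
  cr <- competitive_ratio(ref_pair())
  expect_equal(cr$cr_ir, 2.0395390450, tolerance = 1e-9)
  expect_equal(cr$cr_c, 0.4903068674, tolerance = 1e-9)
  expect_equal(cr$cr_ir * cr$cr_c, 1, tolerance = 1e-15)
  eq <- competitive_ratio(stand_pair(sdm_ir = 4, sdm_c = 6, idm_ir = 2, idm_c = 3))
  expect_equal(eq$cr_ir, 1)
  zero <- competitive_ratio(stand_pair(sdm_ir = 4, sdm_c = 6, idm_ir = 2, idm_c = 0))
  expect_identical(zero$cr_ir, Inf)
  expect_identical(zero$cr_c, 0)
})

test_that("aggressivity is antisymmetric and zero at equal relative performance", {
  a <- aggressivity(ref_pair())
  expect_equal(a$a_ir, 0.7635324003, tolerance = 1e-9)
  expect_identical(a$a_c, -a$a_ir)
  eq <- aggressivity(stand_pair(sdm_ir = 4, sdm_c = 6, idm_ir = 2, idm_c = 3))
  expect_equal(eq$a_ir, 0)
})

test_that("relative crowding coefficient and its degeneracies", {
  r <- rcc(ref_pair())
  expect_equal(r$rcc_ir, 2.9842519685, tolerance = 1e-9)
  expect_equal(r$rcc_c, 0.5803921569, tolerance = 1e-9)
  expect_equal(r$rcc_total, 1.7320364366, tolerance = 1e-9)
  neutral <- rcc(stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 2.5, idm_c = 2))
  expect_equal(neutral$rcc_ir, 1)
  expect_equal(neutral$rcc_c, 1)
  degen <- rcc(stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 5, idm_c = 2))
  expect_identical(degen$rcc_ir, Inf)
  expect_warning(
    over <- rcc(stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 5.5, idm_c = 2,
                           check_z = TRUE)),
    class = "intercrop_dominance_warning"
  )
  expect_lt(over$rcc_ir, 0)
})

test_that("actual yield loss with default and overridden sown shares", {
  a <- ayl(ref_pair())
  expect_equal(a$ayl_ir, 0.4980237154, tolerance = 1e-9)
  expect_equal(a$ayl_c, -0.2655086849, tolerance = 1e-9)
  expect_equal(a$ayl_total, a$ayl_ir + a$ayl_c)
  # effective land-share 0.25 per component
  a25 <- ayl(ref_pair(), z_override_ir = 0.25, z_override_c = 0.25)
  expect_equal(a25$ayl_ir, 1.9960474308, tolerance = 1e-9)
  expect_equal(a25$ayl_c, 0.4689826303, tolerance = 1e-9)
  neutral <- ayl(stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 2.5, idm_c = 2))
  expect_equal(neutral$ayl_ir, 0)
  expect_equal(neutral$ayl_c, 0)
})

test_that("land saved is monotone in RYT with the right anchors", {
  expect_equal(lsav(2.24), 55.3571428571, tolerance = 1e-9)
  expect_equal(lsav(1.0), 0)
  expect_equal(lsav(2.0), 50)
  expect_error(lsav(0), class = "intercrop_undefined_index")
})

test_that("competitive balance index under both log bases", {
  p <- ref_pair()
  expect_equal(cb(p), 0.7127238240, tolerance = 1e-9)
  expect_equal(round(cb(p), 2), 0.71)
  expect_equal(cb(p, "log10"), 0.3095320239, tolerance = 1e-9)
  eq <- stand_pair(sdm_ir = 4, sdm_c = 6, idm_ir = 2, idm_c = 3)
  expect_equal(cb(eq), 0)
  expect_equal(cb(eq, "log10"), 0)
  expect_error(cb(stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 0, idm_c = 2)),
               class = "intercrop_undefined_index")
})

test_that("compute_index_set populates every field and collects issues", {
  s <- compute_index_set(ref_pair())
  expect_true(all(!is.na(s[intercrop:::index_set_cols])))
  expect_equal(round(s$ryt_c, 2), 0.73)
  expect_equal(round(s$cb, 2), 0.71)
  expect_length(attr(s, "issues"), 0)

  # competition-neutral pair (idm_i = sdm_i * z_i): each partial RYT is 1,
  # so the competition indices sit at their no-effect anchors while the
  # system-level indices sit at full replacement-series parity
  neutral <- stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 2.5, idm_c = 2)
  sn <- compute_index_set(neutral)
  expect_equal(sn$ryt_ir, 1)
  expect_equal(sn$ryt_c, 1)
  expect_equal(sn$ryt_total, 2)
  expect_equal(sn$ater, 2)
  expect_equal(sn$a_ir, 0)
  expect_equal(sn$rcc_ir, 1)
  expect_equal(sn$rcc_c, 1)
  expect_equal(sn$ayl_total, 0)
  expect_equal(sn$lsav, 50)
  expect_equal(sn$cb, 0)
  expect_equal(sn$pyd, 0)

  # an undefined constituent is reported, the rest still computed
  zero_c <- stand_pair(sdm_ir = 5, sdm_c = 4, idm_ir = 2.5, idm_c = 0)
  sz <- compute_index_set(zero_c)
  expect_true("cb" %in% names(attr(sz, "issues")))
  expect_true(is.na(sz$cb))
  expect_identical(sz$cr_ir, Inf)
  expect_false(is.na(sz$ryt_total))
})

test_that("algebraic identities hold on randomized stand pairs", {
  set.seed(42)
  pairs <- random_pairs(250)
  for (p in pairs) {
    s <- suppressWarnings(compute_index_set(p))
    expect_equal(s$a_ir + s$a_c, 0)
    expect_equal(s$cr_ir * s$cr_c, 1, tolerance = 1e-12)
    expect_equal(s$ryt_total, s$ryt_ir + s$ryt_c, tolerance = 1e-12)
    expect_equal(s$rcc_total, s$rcc_ir * s$rcc_c, tolerance = 1e-12)
    expect_equal(s$ayl_total, s$ayl_ir + s$ayl_c, tolerance = 1e-12)
    # equal durations: ATER collapses to the total RYT
    expect_equal(s$ater, s$ryt_total, tolerance = 1e-12)
  }
})

test_that("equal sowing links Cb, CR and aggressivity; PYD and LSAV follow RYT", {
  set.seed(43)
  pairs <- random_pairs(100, z_equal = TRUE)
  for (p in pairs) {
    s <- suppressWarnings(compute_index_set(p))
    expect_equal(s$cb, log(s$cr_ir), tolerance = 1e-12)
    expect_equal(sign(s$a_ir), sign(s$cb))
    expect_equal(sign(s$a_ir), sign(s$cr_ir - 1))
    expect_equal(s$pyd, 100 * (s$ryt_total / 2 - 1), tolerance = 1e-9)
    expect_equal(s$lsav, 100 * (1 - 1 / s$ryt_total), tolerance = 1e-9)
  }
})

test_that("every index except SPI is invariant under a common yield rescale", {
  set.seed(44)
  pairs <- random_pairs(50)
  for (p in pairs) {
    k <- runif(1, 0.2, 5)
    q <- p
    for (col in c("sdm_ir", "sdm_c", "idm_ir", "idm_c")) q[[col]] <- p[[col]] * k
    s1 <- suppressWarnings(compute_index_set(p))
    s2 <- suppressWarnings(compute_index_set(q))
    for (col in setdiff(intercrop:::index_set_cols, "spi")) {
      expect_equal(s2[[col]], s1[[col]], tolerance = 1e-9)
    }
    expect_equal(s2$spi, s1$spi * k, tolerance = 1e-9)
  }
})

test_that("both bases run through the identical code path", {
  fx <- generate_table1_fixture()
  s_dmy <- compute_index_set(build_stand_pairs(fx, basis = "dmy"))
  s_n <- compute_index_set(build_stand_pairs(fx, basis = "n"))
  expect_identical(s_dmy$basis, "dmy")
  expect_identical(s_n$basis, "n")
  # fixture concentrations are constant per component, so the grass-side
  # relative performances (hence its partial RYT) coincide across bases
  expect_equal(s_n$ryt_ir, s_dmy$ryt_ir, tolerance = 1e-12)
})
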