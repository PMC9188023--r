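test_that("empty input yields an empty table with the full column schema", {
  tab <- build_trait_table(list())
  expect_s3_class(tab, "deb_trait_table")
  expect_equal(nrow(tab), 0L)
  expect_true(all(deb_mds_traits() %in% names(tab)))
  expect_true(all(c("flag_nonviable", "flag_stalled", "flag_demand_bound")
                  %in% names(tab)))
})

test_that("a trait-table row equals the individually invoked operations", {
  p <- fixture_species()[[1]]
  row <- fixture_traits()[1, ]
  lh <- deb_life_history(p)
  for (tr in c("E_0", "a_b", "a_p", "a_m", "Ww_i", "R_i", "s_s", "s_Hbp",
               "Ww_b", "Ww_p", "r_B", "r_max", "jO2_spec"))
    expect_equal(row[[tr]], lh[[tr]], info = tr)
  expect_equal(row$N_mass_life,
               lifetime_neonate_mass(lh$R_i, lh$a_m, lh$a_p, lh$Ww_b))
  expect_equal(row$E_m, p$p_Am / p$v)
})

test_that("duplicate species ids are rejected", {
  expect_error(build_trait_table(reference_fixture()[c(1, 1)]),
               "duplicate species_id")
})

test_that("table build is order-independent up to row permutation", {
  perm <- c(3, 1, 2)
  t1 <- build_trait_table(reference_fixture()[1:3])
  t2 <- build_trait_table(reference_fixture()[perm])
  expect_equal(t2$species_id, t1$species_id[perm])
  rownames(t1) <- t1$species_id; rownames(t2) <- t2$species_id
  expect_equal(t2[t1$species_id, ], t1[t1$species_id, ],
               ignore_attr = TRUE)
})

test_that("lifetime neonate mass is the product of rate, window and neonate
           weight", {
  expect_equal(lifetime_neonate_mass(0, 1000, 100, 5), 0)
  expect_equal(lifetime_neonate_mass(0.2, 1000, 100, 10),
               2 * lifetime_neonate_mass(0.2, 1000, 100, 5))
  expect_equal(lifetime_neonate_mass(0.2, 1000, 100, 5), 0.2 * 900 * 5)
  expect_equal(lifetime_neonate_mass(0.2, 1000, 100, 5,
                                     window = "lifespan"), 0.2 * 1000 * 5)
  expect_true(is.na(lifetime_neonate_mass(0.2, NA, 100, 5)))
})

test_that("non-viable and stalled species are retained with NA traits and
           raised flags", {
  bad <- deb_params("doomed", p_Am = 200, v = 0.06, kappa = 0.8, p_M = 18,
                    k_J = 5, E_G = 7800, E_Hb = 2e3, E_Hp = 4e5,
                    h_a = 1e-9, s_G = 1e-4)
  tab <- build_trait_table(c(reference_fixture()[1], list(bad)))
  expect_equal(nrow(tab), 2L)
  expect_true(tab$flag_nonviable[2])
  # derived traits are missing, not zero; primary-parameter traits
  # (v, p_M, p_Am, E_m) remain available
  derived <- c("a_b", "a_p", "a_m", "Ww_i", "R_i", "E_0", "s_s", "s_Hbp",
               "Ww_b", "Ww_p", "N_mass_life")
  expect_true(all(is.na(tab[2, derived])))
  expect_false(tab$flag_nonviable[1])
})

test_that("weight ratio at birth/puberty rank-correlates positively with
           the precociality coefficient across a generated family", {
  fam <- generate_parameter_table(synthetic_config(seed = 202, n_species = 25))
  tab <- build_trait_table(fam)
  ok <- !tab$flag_nonviable & !tab$flag_stalled
  rho <- stats::cor(tab$Ww_b[ok] / tab$Ww_p[ok], tab$s_Hbp[ok],
                    method = "spearman")
  expect_gt(rho, 0.9)
  # and all unflagged rows satisfy the trait-range invariants
  expect_true(all(tab$s_s[ok] >= 0 & tab$s_s[ok] <= 4 / 27 + 1e-12))
  expect_true(all(tab$s_Hbp[ok] > 0 & tab$s_Hbp[ok] < 1))
  expect_true(all(tab$a_b[ok] < tab$a_p[ok]))
  expect_true(all(tab$Ww_b[ok] < tab$Ww_p[ok] &
                    tab$Ww_p[ok] < tab$Ww_i[ok]))
})
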