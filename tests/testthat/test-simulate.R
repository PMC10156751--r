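test_that("degenerate generator settings give the expected extraction", {
  s <- default_schedule()
  gp <- group_params("NT", p_facing_social = 1, p_facing_nonsocial = 1,
                     br_social = 0, br_nonsocial = 0, p_social_gaze = 0.5,
                     conf_low_rate = 0)
  st <- generate_session(gp, s, seed = 5)
  pf <- extract_participant(st, s)
  expect_equal(pf$mean_tff_social, 100)
  expect_equal(pf$mean_tff_nonsocial, 100)
  expect_equal(pf$mean_br_social, 0)
  expect_equal(pf$mean_br_nonsocial, 0)
})

test_that("equal seeds give identical streams, different seeds differ", {
  s <- default_schedule()
  gp <- preset_group_params()$AUT
  a <- generate_session(gp, s, seed = 9)
  b <- generate_session(gp, s, seed = 9)
  expect_identical(a, b)
  c <- generate_session(gp, s, seed = 10)
  expect_false(identical(a$yaw_deg, c$yaw_deg))
})

test_that("generated streams satisfy the stream invariants", {
  s <- default_schedule()
  for (gp in preset_group_params()) {
    st <- generate_session(gp, s, seed = 3)
    expect_equal(length(st), 460 * 30)
    expect_true(all(st$au45 >= 0))
    expect_true(all(st$confidence >= 0 & st$confidence <= 1))
    gx <- st$gaze_x_norm
    expect_true(all(gx >= 0 & gx <= 1, na.rm = TRUE))
    # off-screen frames carry no gaze coordinate
    expect_true(all(is.na(gx[!st$gaze_on_screen])))
  }
})

test_that("a planted blink rate is recovered within sampling error", {
  s <- default_schedule()
  gp <- group_params("NT", p_facing_social = 1, p_facing_nonsocial = 1,
                     br_social = 20, br_nonsocial = 20,
                     p_social_gaze = 0.5, conf_low_rate = 0)
  rates <- vapply(1:12, function(i) {
    pf <- extract_participant(generate_session(gp, s, seed = 100 + i), s)
    pf$mean_br_social
  }, numeric(1))
  # Poisson mean recovery: tolerance 3 * sqrt(rate / total social minutes)
  minutes <- 12 * sum(s$duration_s[s$movie_type == "social"]) / 60
  expect_lt(abs(mean(rates) - 20), 3 * sqrt(20 / minutes))
})

test_that("cohort generation is reproducible and matches configured sizes", {
  cfg <- cohort_config(n_per_group = c(NT = 6, AUT = 4), seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$manifest), 10)
  expect_equal(sum(a$manifest$group == "AUT"), 4)
  expect_equal(length(a$streams), 10)
  # clinical scores populated for the autistic group only
  expect_true(all(is.na(a$clinical$ados_sa[a$manifest$group == "NT"])))
  expect_true(all(!is.na(a$clinical$ados_sa[a$manifest$group == "AUT"])))
})

test_that("default configuration mirrors the study cohort composition", {
  cfg <- cohort_config()
  expect_equal(unname(cfg$n_per_group[["NT"]]), 416)
  expect_equal(unname(cfg$n_per_group[["AUT"]]), 43)
  expect_equal(unname(cfg$n_per_group[["LDDD"]]), 0)
})

test_that("zero clinical slopes give null clinical correlations", {
  cfg <- cohort_config(
    n_per_group = c(AUT = 300),
    clinical_effects = list(ados_slope = 0, mullen_slope = 0), seed = 4)
  co <- simulate_feature_table(cfg)
  tab <- clinical_correlations(co)
  expect_true(all(abs(tab$r) < 0.2))
})

test_that("planted clinical effects produce the expected correlation signs", {
  # strong effect, large n: ADOS social affect vs social TFF negative,
  # Mullen composite vs nonsocial TFF negative
  cfg <- cohort_config(
    n_per_group = c(AUT = 500),
    clinical_effects = list(ados_slope = 2, mullen_slope = 12), seed = 8)
  co <- simulate_feature_table(cfg)
  tab <- clinical_correlations(co)
  pick <- function(a, c) tab$r[tab$attention == a & tab$clinical == c]
  expect_lt(pick("mean_tff_social", "ados_sa"), -0.2)
  expect_lt(pick("mean_tff_social", "ados_total"), -0.2)
  expect_lt(pick("mean_tff_nonsocial", "mullen_elc"), -0.2)
  expect_lt(pick("mean_tff_nonsocial", "mullen_vr"), -0.2)
})

test_that("feature-table sampler reproduces planted cell means", {
  cfg <- cohort_config(n_per_group = c(NT = 400, AUT = 400), seed = 31)
  ft <- simulate_feature_table(cfg)
  gp <- preset_group_params()
  for (g in c("NT", "AUT")) {
    sub <- ft[ft$group == g, ]
    expect_lt(abs(mean(sub$mean_tff_social) -
                    100 * gp[[g]]$p_facing_social), 2)
    expect_lt(abs(mean(sub$mean_br_social) - gp[[g]]$br_social),
              0.1 * gp[[g]]$br_social)
    expect_lt(abs(mean(sub$mgps) - 100 * gp[[g]]$p_social_gaze), 3)
  }
})

test_that("TFF and blink rate are not artificially coupled within group", {
  cfg <- cohort_config(n_per_group = c(NT = 300), seed = 13)
  ft <- simulate_feature_table(cfg)
  r <- cor(ft$mean_tff_social, ft$mean_br_social)
  expect_lt(abs(r), 0.5)  # independent mechanisms: no forced +/-1 coupling
})
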