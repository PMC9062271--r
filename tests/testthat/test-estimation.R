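swd_table_fixture <- function() {
  tibble::tibble(species = "Burkea africana", swd_g_cm3 = 0.6, n_samples = 4L)
}

test_that("damage partitioning, reverse assessment and topkill split behave", {
  p <- partition_canopy_losses(100, c(fire = 30))
  expect_equal(unname(p$losses["fire"]), 30)
  expect_equal(p$standing, 70)
  # the 99% cap leaves a 1% floor standing after total topkill
  p2 <- partition_canopy_losses(100, c(fire = 50, elephant = 49))
  expect_equal(p2$standing, 1, tolerance = 1e-12)
  p3 <- partition_canopy_losses(42, c())
  expect_equal(p3$standing, 42)
  expect_error(partition_canopy_losses(10, c(fire = 60, elephant = 45)),
               "invalid damage")
  expect_error(partition_canopy_losses(10, c(goats = 5)), "unknown")

  expect_equal(reverse_damage(50, 50), 100)
  expect_equal(reverse_damage(7, 0), 7)
  expect_equal(reverse_damage(1, 99), 100, tolerance = 1e-12)
  expect_error(reverse_damage(10, 100), "99")

  expect_equal(assign_topkill_loss(100, "fire"), c(fire = 100))
  expect_equal(assign_topkill_loss(100, c("fire", "elephant")),
               c(fire = 50, elephant = 50))
  expect_equal(assign_topkill_loss(60, c("fire", "elephant"), weights = c(2, 1)),
               c(fire = 40, elephant = 20))
  expect_equal(unname(assign_topkill_loss(0, "fire")), 0)
  expect_error(assign_topkill_loss(10, c("a", "b", "c")), "one or two")
})

test_that("reverse damage and forward partition are mutually inverse", {
  set.seed(11)
  for (i in 1:25) {
    pct <- setNames(runif(6, 0, 16), AGENTS) # total <= 96
    post <- runif(1, 0.1, 500)
    pre <- reverse_damage(post, sum(pct))
    p <- partition_canopy_losses(pre, pct)
    expect_equal(p$standing, post, tolerance = 1e-9)
    expect_equal(pre, p$standing + sum(p$losses), tolerance = 1e-9)
  }
})

test_that("dead stems are valued through the reconstruction chain", {
  cal <- default_calibration()
  # chained oracle computed independently: basal 100 -> DBH 25.3629 ->
  # h_est 876.0035 cm -> stem model at 0.6 g cm^-3
  expect_equal(dead_stem_agb(100, 0.6, cal), 187.22925372411692,
               tolerance = 1e-9)
  # alternative-only reading at hx = 0 reduces to the basal case
  expect_equal(dead_stem_agb(NA_real_, 0.6, cal, alt_circ_cm = 100,
                             alt_height_cm = 0),
               dead_stem_agb(100, 0.6, cal), tolerance = 1e-12)
  expect_error(dead_stem_agb(NA_real_, 0.6, cal), "no usable")
})

test_that("healthy adult estimation matches the stem-model oracle and splits losses", {
  cal <- default_calibration()
  swd <- swd_table_fixture()
  intact <- make_individual("A1", height_cm = 1200, growth_class = "AA")
  stems <- make_stem("A1", basal_circ_cm = 130, circ130_cm = 30 * pi)
  res <- estimate_biomass(intact, stems, swd, cal)
  expect_equal(res$agb_standing_kg, 353.2744833716337, tolerance = 1e-9)
  expect_equal(res$agb_ex_kg, res$agb_standing_kg)
  expect_identical(res$model_used, "stem")

  damaged <- intact
  damaged$loss_elephant <- 20
  damaged$growth_class <- "AA"
  res2 <- estimate_biomass(damaged, stems, swd, cal)
  expect_equal(res2$agb_standing_kg, 0.8 * 353.2744833716337, tolerance = 1e-9)
  expect_equal(res2$loss_elephant_kg, 0.2 * 353.2744833716337, tolerance = 1e-9)
  expect_equal(res2$agb_ex_kg, 353.2744833716337, tolerance = 1e-9)
})

test_that("topkilled resprouters combine canopy and dead-stem models", {
  cal <- default_calibration()
  swd <- swd_table_fixture()
  ag3 <- make_individual("G1", height_cm = 300, cd1_m = 2, cd2_m = 2,
                         growth_class = "AG3")
  stems <- make_stem("G1", basal_circ_cm = 100, is_dead = TRUE,
                     topkill_agent_1 = "fire")
  res <- estimate_biomass(ag3, stems, swd, cal)
  expect_equal(res$agb_standing_kg, 149.38667209807525, tolerance = 1e-9)
  expect_equal(res$loss_fire_kg, 187.22925372411692, tolerance = 1e-9)
  expect_equal(res$dead_stem_loss_kg, res$loss_fire_kg)
  expect_equal(res$agb_ex_kg, res$agb_standing_kg + res$loss_fire_kg,
               tolerance = 1e-12)
  expect_identical(res$model_used, "combined")
  # joint topkill agents split the dead stem's biomass equally
  stems2 <- stems
  stems2$topkill_agent_2 <- "elephant"
  res2 <- estimate_biomass(ag3, stems2, swd, cal)
  expect_equal(res2$loss_fire_kg, res2$loss_elephant_kg, tolerance = 1e-12)
  expect_equal(res2$loss_fire_kg + res2$loss_elephant_kg,
               res$dead_stem_loss_kg, tolerance = 1e-12)
})

test_that("gulliver workflows apply the height correction where crowns are damaged", {
  cal <- default_calibration()
  swd <- swd_table_fixture()
  dbh <- 20
  h_obs <- 300 # far below the allometric expectation for DBH 20
  h_est <- exp(cal$height$a + cal$height$b * log(dbh))
  base <- make_stem("x", basal_circ_cm = dbh * pi / cal$dbh$s,
                    circ130_cm = dbh * pi)
  ag1 <- make_individual("x", height_cm = h_obs, growth_class = "AG1",
                         losses = c(elephant = 45))
  res1 <- estimate_biomass(ag1, base, swd, cal)
  pre1 <- stem_agb(0.6, dbh, h_est / 100)
  expect_equal(res1$agb_ex_kg, pre1, tolerance = 1e-9)
  expect_equal(res1$agb_standing_kg, 0.55 * pre1, tolerance = 1e-9)

  dead <- make_stem("x", stem_id = "x-s2", basal_circ_cm = 100,
                    is_dead = TRUE, topkill_agent_1 = "elephant")
  # AG2a: undamaged living crown -> observed height, no correction
  ag2a <- make_individual("x", height_cm = h_obs, growth_class = "AG2a",
                          losses = c(fire = 10))
  res2a <- estimate_biomass(ag2a, dplyr::bind_rows(base, dead), swd, cal)
  pre_living_2a <- stem_agb(0.6, dbh, h_obs / 100)
  expect_equal(res2a$agb_standing_kg, 0.9 * pre_living_2a, tolerance = 1e-9)
  # AG2b: damaged living crown -> corrected height
  ag2b <- make_individual("x", height_cm = h_obs, growth_class = "AG2b",
                          losses = c(fire = 40))
  res2b <- estimate_biomass(ag2b, dplyr::bind_rows(base, dead), swd, cal)
  expect_equal(res2b$agb_standing_kg, 0.6 * pre1, tolerance = 1e-9)
  # the dead stem contributes identically in both and never to standing AGB
  dead_kg <- dead_stem_agb(100, 0.6, cal)
  expect_equal(res2a$loss_elephant_kg, dead_kg, tolerance = 1e-9)
  expect_equal(res2b$dead_stem_loss_kg, dead_kg, tolerance = 1e-9)
  res2b_no_dead <- estimate_biomass(
    make_individual("x", height_cm = h_obs, growth_class = "AG1",
                    losses = c(fire = 40)), base, swd, cal)
  expect_equal(res2b$agb_standing_kg, res2b_no_dead$agb_standing_kg,
               tolerance = 1e-9)
})

test_that("canopy-class estimates are post-disturbance and recover the pre value", {
  swd <- swd_table_fixture()
  sa <- make_individual("s", height_cm = 300, cd1_m = 2.5, cd2_m = 1.5,
                        growth_class = "GS", losses = c(fire = 50))
  res <- estimate_biomass(sa, empty_stems(), swd, default_calibration())
  standing <- canopy_agb(2, 300)
  expect_equal(res$agb_standing_kg, standing, tolerance = 1e-12)
  expect_equal(res$agb_ex_kg, standing / 0.5, tolerance = 1e-9)
  expect_equal(res$loss_fire_kg, standing, tolerance = 1e-9)
})

test_that("missing proxies and unresolved SWD raise estimation errors", {
  cal <- default_calibration()
  swd <- swd_table_fixture()
  no_cd <- make_individual("x", height_cm = 200, growth_class = "SA")
  expect_error(estimate_biomass(no_cd, empty_stems(), swd, cal),
               "crown diameters")
  no_proxy <- make_individual("x", height_cm = 600, growth_class = "AA")
  bare <- make_stem("x")
  expect_error(estimate_biomass(no_proxy, bare, swd, cal), "circumference proxy")
  alien <- make_individual("x", height_cm = 600, species = "Unknownus treeus",
                           growth_class = "AA")
  expect_error(estimate_biomass(alien, make_stem("x", circ130_cm = 60),
                                swd, cal), "wood density unresolved")
})

test_that("biomass conservation holds for every simulated individual", {
  sim <- simulate_inventory(simulation_config(plots_per_site = 2), seed = 19)
  bm <- sim$truth
  resid <- abs(bm$agb_ex_kg - (bm$agb_standing_kg + total_losses_kg(bm)))
  rel <- resid / pmax(bm$agb_ex_kg, .Machine$double.eps)
  expect_lt(max(rel), 1e-9)
  expect_true(all(bm$agb_standing_kg >= 0))
  expect_true(all(as.matrix(bm[, loss_kg_cols()]) >= -1e-12))
})
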