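test_that("growth classification covers every class and its boundaries", {
  cases <- list(
    # living adult stem, light damage -> healthy adult
    list(ind = make_individual("x", height_cm = 800,
                               losses = c(elephant = 5)),
         stems = make_stem("x", basal_circ_cm = 20), expect = "AA"),
    # heavy damage moves the same tree to AG1
    list(ind = make_individual("x", height_cm = 500,
                               losses = c(elephant = 40)),
         stems = make_stem("x", basal_circ_cm = 20), expect = "AG1"),
    # living + dead adult stems, light crown damage -> AG2a
    list(ind = make_individual("x", height_cm = 700,
                               losses = c(fire = 10)),
         stems = dplyr::bind_rows(
           make_stem("x", basal_circ_cm = 40),
           make_stem("x", stem_id = "x-s2", basal_circ_cm = 50,
                     is_dead = TRUE, topkill_agent_1 = "fire")),
         expect = "AG2a"),
    # same but heavy crown damage -> AG2b
    list(ind = make_individual("x", height_cm = 400,
                               losses = c(fire = 35)),
         stems = dplyr::bind_rows(
           make_stem("x", basal_circ_cm = 40),
           make_stem("x", stem_id = "x-s2", basal_circ_cm = 50,
                     is_dead = TRUE, topkill_agent_1 = "fire")),
         expect = "AG2b"),
    # topkilled single stem with crown-measured regrowth -> AG3
    list(ind = make_individual("x", height_cm = 150, cd1_m = 1.5, cd2_m = 1),
         stems = make_stem("x", basal_circ_cm = 40, is_dead = TRUE,
                           topkill_agent_1 = "elephant"), expect = "AG3"),
    # no adult stems, below the height threshold, intact -> juvenile
    list(ind = make_individual("x", height_cm = 90, cd1_m = .4, cd2_m = .3),
         stems = NULL, expect = "JU"),
    # above the height threshold -> sapling
    list(ind = make_individual("x", height_cm = 200, cd1_m = 1, cd2_m = .8),
         stems = NULL, expect = "SA"),
    # heavily damaged sub-adults become gulliver variants
    list(ind = make_individual("x", height_cm = 90, cd1_m = .4, cd2_m = .3,
                               losses = c(fire = 45)),
         stems = NULL, expect = "GJ"),
    list(ind = make_individual("x", height_cm = 200, cd1_m = 1, cd2_m = .8,
                               losses = c(fire = 30)),
         stems = NULL, expect = "GS")
  )
  for (cs in cases) {
    stems <- if (is.null(cs$stems)) empty_stems() else cs$stems
    expect_identical(classify_growth_class(cs$ind, stems), cs$expect)
  }
})

test_that("the adult-size boundary is strictly above 15 cm basal circumference", {
  ind <- make_individual("x", height_cm = 100, cd1_m = .5, cd2_m = .4)
  at <- classify_growth_class(ind, make_stem("x", basal_circ_cm = 15))
  above <- classify_growth_class(ind, make_stem("x", basal_circ_cm = 15 + 1e-9))
  below <- classify_growth_class(ind, make_stem("x", basal_circ_cm = 14.999))
  expect_identical(at, "JU")     # exactly 15 cm is not adult-sized
  expect_identical(above, "AA")
  expect_identical(below, "JU")
})

test_that("raising losses past 30% changes the damage tier but never the size tier", {
  size_tier <- function(gc) {
    switch(gc, JU = , GJ = "juvenile", SA = , GS = "sapling", "adult")
  }
  configs <- list(
    list(h = 90, cd = TRUE, stems = NULL),
    list(h = 250, cd = TRUE, stems = NULL),
    list(h = 600, cd = FALSE, stems = "adult")
  )
  for (cf in configs) {
    for (light_pct in c(0, 10, 29.9)) {
      light <- make_individual("x", height_cm = cf$h,
                               cd1_m = if (cf$cd) 1 else NA_real_,
                               cd2_m = if (cf$cd) .8 else NA_real_,
                               losses = c(fire = light_pct))
      heavy <- light
      heavy$loss_fire <- light_pct + 35
      stems <- if (is.null(cf$stems)) empty_stems() else
        make_stem("x", basal_circ_cm = 30)
      gc_light <- classify_growth_class(light, stems)
      gc_heavy <- classify_growth_class(heavy, stems)
      expect_false(gc_light == gc_heavy)
      expect_identical(size_tier(gc_light), size_tier(gc_heavy))
      expect_true(gc_light %in% c("JU", "SA", "AA"))
      expect_true(gc_heavy %in% c("GJ", "GS", "AG1"))
    }
  }
})

test_that("classification is deterministic and errors are explicit", {
  ind <- make_individual("x", height_cm = NA_real_)
  expect_error(classify_growth_class(ind, empty_stems()), "height")
  # dead adult stem without living-tissue proxies is unclassifiable
  dead <- make_individual("x", height_cm = 100)
  stems <- make_stem("x", basal_circ_cm = 40, is_dead = TRUE,
                     topkill_agent_1 = "fire")
  expect_error(classify_growth_class(dead, stems), "unclassifiable.*cd1_m",
               perl = TRUE)
  ok <- make_individual("x", height_cm = 100, cd1_m = 1, cd2_m = 1)
  expect_identical(classify_growth_class(ok, stems),
                   classify_growth_class(ok, stems))
})

test_that("validation returns named violations and passes clean records", {
  inv <- tiny_inventory()
  expect_identical(nrow(validate_individuals(inv$individuals, inv$stems)), 0L)

  over <- make_individual("x", losses = c(elephant = 60, fire = 50))
  v <- validate_individuals(over, empty_stems())
  expect_true(any(grepl("110 > 99", v$message)))

  unpaired <- make_stem("x", alt_circ_cm = 30)
  v2 <- validate_individuals(make_individual("x"), unpaired)
  expect_identical(nrow(v2), 1L)
  expect_match(v2$message, "together")

  deadless <- make_stem("x", basal_circ_cm = 40, is_dead = TRUE)
  v3 <- validate_individuals(make_individual("x"), deadless)
  expect_true(any(grepl("topkill", v3$message)))
})

test_that("canonical CSV writing then reading is the identity", {
  inv <- tiny_inventory()
  dir <- withr::local_tempdir()
  write_inventory(inv, dir)
  back <- read_inventory(dir)
  expect_equal(as.data.frame(back$individuals), as.data.frame(inv$individuals))
  expect_equal(as.data.frame(back$stems), as.data.frame(inv$stems))
  expect_equal(as.data.frame(back$plots), as.data.frame(inv$plots))
  # loss percentages survive exactly, including non-terminating decimals
  inv$individuals$loss_fire[1] <- 100 / 3
  write_inventory(inv, dir)
  expect_identical(read_inventory(dir)$individuals$loss_fire[1], 100 / 3)
})

test_that("empty tables round-trip and missing columns are named", {
  inv <- tiny_inventory()
  inv$individuals <- inv$individuals[0, ]
  inv$stems <- inv$stems[0, ]
  dir <- withr::local_tempdir()
  write_inventory(inv, dir)
  back <- read_inventory(dir)
  expect_identical(nrow(back$individuals), 0L)
  expect_identical(nrow(back$stems), 0L)
  # drop a mandatory column
  broken <- readr::read_csv(file.path(dir, "individuals.csv"),
                            show_col_types = FALSE)
  broken$height_cm <- NULL
  readr::write_csv(broken, file.path(dir, "individuals.csv"))
  expect_error(read_inventory(dir), "height_cm")
})

test_that("external column mappings are renamed and padded to the canonical schema", {
  tabs <- list(
    individuals = tibble::tibble(ID = "A1", Plot = "P1", Species = "Burkea africana",
                                 Height = 300),
    stems = tibble::tibble(ID = "A1", Stem = "s1", BasalCirc = 40),
    plots = tibble::tibble(Plot = "P1", Veg = "savanna", Dens = "low")
  )
  mapping <- list(
    individuals = list(sheet = "data prop", columns = c(
      individual_id = "ID", plot_id = "Plot", species = "Species",
      height_cm = "Height")),
    stems = list(sheet = "raw", columns = c(
      individual_id = "ID", stem_id = "Stem", basal_circ_cm = "BasalCirc")),
    plots = list(sheet = "coordinates", columns = c(
      plot_id = "Plot", vegetation = "Veg", density_level = "Dens"))
  )
  out <- normalize_mapped_tables(tabs, mapping)
  expect_identical(out$individuals$individual_id, "A1")
  expect_identical(out$individuals$height_cm, 300)
  expect_true(all(is.na(out$individuals$cd1_m)))
  expect_named(out$stems, names(make_stem("x")))
  mapping$stems$columns[["basal_circ_cm"]] <- "NotThere"
  expect_error(normalize_mapped_tables(tabs, mapping), "NotThere")
})
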