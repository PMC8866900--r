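test_that("wide parse converts minutes to hours and keeps 20-min spacing", {
  fx <- write_wide_plate_fixture()
  pl <- read_plate(fx$plate, fx$meta, layout = "wide")
  expect_s3_class(pl, "PlateTimeSeries")
  expect_equal(length(pl$times), 49)
  expect_equal(pl$times[2] - pl$times[1], 1 / 3)
  expect_equal(pl$flags$blank_wells, "B1")
})

test_that("wide and long parses of the same data are identical", {
  fx <- write_wide_plate_fixture()
  wide <- read_plate(fx$plate, fx$meta, layout = "wide")
  long <- read_plate(write_long_plate_fixture(fx), fx$meta, layout = "long")
  expect_equal(wide$times, long$times)
  expect_equal(wide$od, long$od)
  expect_equal(wide$wells, long$wells)
})

test_that("write_plate/read_plate round-trips times and values exactly", {
  sim <- simulate_isocost(seed = 11)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.csv")
  meta <- file.path(dir, "rt_meta.csv")
  write.csv(sim$series$wells, meta, row.names = FALSE, quote = FALSE)
  write_plate(sim$series, path, time_unit = "hours")
  back <- read_plate(path, meta, layout = "long", time_unit = "hours")
  expect_identical(back$times, sim$series$times)
  expect_identical(back$od, sim$series$od)
  expect_identical(back$channels$GFP, sim$series$channels$GFP)
  expect_identical(back$channels$RFP, sim$series$channels$RFP)
})

test_that("non-monotone times and missing metadata are hard errors", {
  fx <- write_wide_plate_fixture()
  w <- read.csv(fx$plate, check.names = FALSE)
  w <- w[rev(seq_len(nrow(w))), ]
  bad <- file.path(withr::local_tempdir(), "desc.csv")
  write.csv(w, bad, row.names = FALSE, quote = FALSE)
  expect_error(read_plate(bad, fx$meta), "strictly increasing")

  meta2 <- file.path(withr::local_tempdir(), "meta2.csv")
  write.csv(data.frame(well = c("A1", "B1"), strain = c("WT", "blank"),
                       medium = "glc", replicate = 1),
            meta2, row.names = FALSE, quote = FALSE)
  expect_error(read_plate(fx$plate, meta2), "A2")
})

test_that("negative OD warns and is clipped at the floor, never dropped", {
  tm <- seq(0, 5, by = 0.5)
  od <- matrix(c(seq(-0.01, 0.2, length.out = length(tm))), ncol = 1,
               dimnames = list(NULL, "A1"))
  meta <- data.frame(well = "A1", strain = "WT", medium = "glc", replicate = 1)
  expect_warning(pl <- plate_time_series(tm, od, meta), "clipped")
  expect_equal(nrow(pl$od), length(tm))
  expect_true(all(pl$od >= pl$od_floor))
  expect_equal(pl$flags$clipped_wells, "A1")
})

test_that("blank correction subtracts the mean blank and is recorded", {
  fx <- write_wide_plate_fixture()
  pl <- read_plate(fx$plate, fx$meta)
  bc <- blank_correct(pl)
  expect_true(bc$flags$blank_corrected)
  expect_false("B1" %in% colnames(bc$od))
  expect_equal(bc$od[, "A2"],
               pmax(pl$od[, "A2"] - pl$od[, "B1"], pl$od_floor),
               ignore_attr = TRUE)
  no_blank <- plate_time_series(pl$times, pl$od[, 1:2],
                                pl$wells[pl$wells$well != "B1", ])
  expect_false(blank_correct(no_blank)$flags$blank_corrected)
})

test_that("config files override defaults and defaults stand alone", {
  cfg <- load_config(NULL)
  expect_equal(cfg$od_floor, 0.005)
  expect_equal(cfg$window_frac, 0.8)
  skip_if_not_installed("yaml")
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  writeLines(c("od_floor: 0.01", "seed: 99"), path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$od_floor, 0.01)
  expect_equal(cfg2$seed, 99)
  expect_equal(cfg2$window_frac, 0.8)
})

test_that("gene table parsing validates columns, ids and flags r_wt = 0", {
  df <- toy_gene_df()
  tab <- read_gene_table(write_gene_table_fixture(df))
  expect_s3_class(tab, "GeneBudgetTable")
  expect_equal(nrow(tab), 5)
  expect_equal(unique(tab$category), "other")
  expect_equal(tab$id[tab$efficiency_undefined], "g3")

  dup <- rbind(df, df[2, ])
  expect_error(read_gene_table(write_gene_table_fixture(dup)), "g2")

  expect_error(
    read_gene_table(write_gene_table_fixture(df[, names(df) != "mw"])),
    "mw")
})
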