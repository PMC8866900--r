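# Shared in-code fixtures; everything is generated, nothing is stored.

# a small wide-format plate CSV + metadata on disk, returning the paths
write_wide_plate_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  times_min <- seq(0, 960, by = 20)           # 16 h at 20-min intervals
  od <- data.frame(
    time = times_min,
    A1 = 0.05 * exp(0.4 * times_min / 60),
    A2 = 0.05 * exp(0.6 * times_min / 60),
    B1 = 0.005 + 0 * times_min)               # blank well
  plate <- file.path(dir, "plate.csv")
  write.csv(od, plate, row.names = FALSE, quote = FALSE)
  meta <- file.path(dir, "meta.csv")
  write.csv(data.frame(well = c("A1", "A2", "B1"),
                       strain = c("WT", "mut", "blank"),
                       medium = "glucose", replicate = c(1, 1, 1)),
            meta, row.names = FALSE, quote = FALSE)
  list(plate = plate, meta = meta, times_min = times_min)
}

# the same content in long format
write_long_plate_fixture <- function(wide_fixture,
                                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- read.csv(wide_fixture$plate, check.names = FALSE)
  long <- do.call(rbind, lapply(setdiff(names(w), "time"), function(well)
    data.frame(well = well, time = w$time, measurement = w[[well]])))
  path <- file.path(dir, "plate_long.csv")
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  path
}

write_gene_table_fixture <- function(df,
                                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "genes.tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

toy_gene_df <- function() {
  data.frame(id = paste0("g", 1:5),
             r_wt = c(100, 50, 0, 200, 10),
             r_mut = c(150, 50, 5, 100, 30),
             copies_wt = c(2000, 1000, 300, 5000, 80),
             mw = c(50000, 30000, 20000, 90000, 12000))
}
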