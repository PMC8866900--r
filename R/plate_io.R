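#' Plate-reader time series container
#'
#' Holds OD600 and optional fluorescence channels for a set of wells on a
#' common, strictly increasing time grid (hours), together with per-well
#' metadata (strain, medium, replicate). Wells whose metadata strain is
#' `"blank"` are retained and flagged so blank correction stays explicit.
#'
#' @param times numeric vector (hours), strictly increasing.
#' @param od numeric matrix, `length(times)` rows, one column per well;
#'   column names are well ids.
#' @param wells data.frame with columns `well`, `strain`, `medium`,
#'   `replicate`; every column of `od` must appear in `wells$well`.
#' @param channels named list of fluorescence matrices with the same
#'   dimensions and column names as `od` (e.g. `GFP`, `RFP`).
#' @param od_floor OD values below this detection floor are clipped (never
#'   dropped) and the affected wells flagged. Default 0.005 OD.
#' @return an object of class `PlateTimeSeries`.
#' @export
plate_time_series <- function(times, od, wells, channels = list(),
                              od_floor = 0.005) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  od <- as.matrix(od)
  if (nrow(od) != length(times))
    stop("od must have one row per time point")
  if (is.null(colnames(od))) stop("od columns must be named by well id")
  for (nm in names(channels)) {
    ch <- as.matrix(channels[[nm]])
    if (!identical(dim(ch), dim(od)))
      stop("channel '", nm, "' dimensions differ from od")
    if (!identical(colnames(ch), colnames(od)))
      stop("channel '", nm, "' wells differ from od")
    channels[[nm]] <- ch
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  required <- c("well", "strain", "medium", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols))
    stop("well metadata missing columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(colnames(od), wells$well)
  if (length(unknown))
    stop("wells missing from metadata: ", paste(unknown, collapse = ", "))
  wells <- wells[match(colnames(od), wells$well), , drop = FALSE]
  rownames(wells) <- NULL
  neg <- od < 0
  if (any(neg)) {
    warning(sum(neg), " negative OD value(s) clipped to floor ", od_floor)
  }
  clipped <- od < od_floor
  od[clipped] <- od_floor
  structure(list(
    times = times, od = od, channels = channels, wells = wells,
    od_floor = od_floor,
    flags = list(
      blank_wells = wells$well[tolower(wells$strain) == "blank"],
      clipped_wells = colnames(od)[colSums(clipped) > 0])),
    class = "PlateTimeSeries")
}

#' @export
print.PlateTimeSeries <- function(x, ...) {
  cat(sprintf("PlateTimeSeries: %d wells x %d time points (%.2f-%.2f h)\n",
              ncol(x$od), length(x$times), min(x$times), max(x$times)))
  if (length(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (length(x$flags$blank_wells))
    cat("  blank wells:", paste(x$flags$blank_wells, collapse = ", "), "\n")
  if (length(x$flags$clipped_wells))
    cat("  wells with OD clipped at floor:",
        paste(x$flags$clipped_wells, collapse = ", "), "\n")
  invisible(x)
}

#' Read a plate-reader export into a PlateTimeSeries
#'
#' Supports the two common export layouts: `"wide"` (a `time` column plus one
#' column per well) and `"long"` (columns `well`, `time`, `measurement` and
#' optionally `channel`). Times are converted to hours internally; growth
#' rates throughout the package are in per-hour units.
#'
#' @param path CSV file with the measurements.
#' @param metadata_path CSV file with columns `well`, `strain`, `medium`,
#'   `replicate`.
#' @param layout `"wide"` or `"long"`.
#' @param time_unit unit of the time column in the file, `"minutes"`
#'   (default, the usual plate-reader export) or `"hours"`.
#' @param channel_paths for wide layout: named list of CSV paths holding
#'   fluorescence channels in the same wide layout.
#' @param od_floor detection floor passed to [plate_time_series()].
#' @return a validated `PlateTimeSeries`.
#' @export
read_plate <- function(path, metadata_path,
                       layout = c("wide", "long"),
                       time_unit = c("minutes", "hours"),
                       channel_paths = list(),
                       od_floor = 0.005) {
  layout <- match.arg(layout)
  time_unit <- match.arg(time_unit)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  to_hours <- function(tm) if (time_unit == "minutes") tm / 60 else tm

  if (layout == "wide") {
    raw <- utils::read.csv(path, check.names = FALSE)
    if (!"time" %in% names(raw)) stop("wide layout needs a 'time' column")
    times <- to_hours(raw$time)
    od <- as.matrix(raw[, setdiff(names(raw), "time"), drop = FALSE])
    channels <- lapply(channel_paths, function(p) {
      ch <- utils::read.csv(p, check.names = FALSE)
      as.matrix(ch[, setdiff(names(ch), "time"), drop = FALSE])
    })
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("well", "time", "measurement")
    if (!all(need %in% names(raw)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    if (!"channel" %in% names(raw)) raw$channel <- "OD"
    times <- to_hours(sort(unique(raw$time)))
    wells_in <- unique(raw$well)
    pivot <- function(sub) {
      m <- matrix(NA_real_, nrow = length(times), ncol = length(wells_in),
                  dimnames = list(NULL, wells_in))
      i <- match(to_hours(sub$time), times)
      j <- match(sub$well, wells_in)
      m[cbind(i, j)] <- sub$measurement
      m
    }
    od <- pivot(raw[raw$channel == "OD", , drop = FALSE])
    ch_names <- setdiff(unique(raw$channel), "OD")
    channels <- lapply(stats::setNames(ch_names, ch_names), function(cn)
      pivot(raw[raw$channel == cn, , drop = FALSE]))
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  plate_time_series(times, od, meta, channels, od_floor = od_floor)
}

#' Write a PlateTimeSeries to the long CSV dialect read_plate() reads
#'
#' @param series a `PlateTimeSeries`.
#' @param path output CSV path.
#' @param time_unit unit for the written time column.
#' @return `path`, invisibly.
#' @export
write_plate <- function(series, path, time_unit = c("minutes", "hours")) {
  time_unit <- match.arg(time_unit)
  tm <- if (time_unit == "minutes") series$times * 60 else series$times
  stack_one <- function(m, cn) {
    # %.17g survives the text round-trip bit-for-bit for doubles
    data.frame(well = rep(colnames(m), each = nrow(m)),
               time = rep(sprintf("%.17g", tm), ncol(m)),
               channel = cn,
               measurement = sprintf("%.17g", as.vector(m)))
  }
  out <- do.call(rbind, c(list(stack_one(series$od, "OD")),
                          lapply(names(series$channels), function(nm)
                            stack_one(series$channels[[nm]], nm))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subtract the mean blank signal from OD and fluorescence channels
#'
#' If the plate has wells whose strain is `"blank"`, their per-time mean is
#' subtracted from every non-blank well (OD and each channel); otherwise the
#' series is returned unchanged. Whether blanking was applied is recorded in
#' `flags$blank_corrected`.
#'
#' @param series a `PlateTimeSeries`.
#' @return a blank-corrected `PlateTimeSeries`.
#' @export
blank_correct <- function(series) {
  blanks <- series$flags$blank_wells
  if (!length(blanks)) {
    series$flags$blank_corrected <- FALSE
    return(series)
  }
  keep <- setdiff(colnames(series$od), blanks)
  corr <- function(m) {
    bl <- rowMeans(m[, blanks, drop = FALSE])
    pmax(m[, keep, drop = FALSE] - bl, 0)
  }
  od <- pmax(corr(series$od), series$od_floor)
  channels <- lapply(series$channels, corr)
  out <- plate_time_series(series$times, od,
                           series$wells[series$wells$well %in% keep, ],
                           channels, od_floor = series$od_floor)
  out$flags$blank_corrected <- TRUE
  out
}

#' Extract one well as a simple time-course list
#' @param series a `PlateTimeSeries`.
#' @param well well id.
#' @return list with `times`, `od` and one numeric vector per channel.
#' @export
get_well <- function(series, well) {
  if (!well %in% colnames(series$od)) stop("unknown well: ", well)
  out <- list(times = series$times, od = series$od[, well])
  for (nm in names(series$channels)) out[[nm]] <- series$channels[[nm]][, well]
  out
}

#' Read a gene-level budget table (TSV)
#'
#' Expects columns `id`, `r_wt`, `r_mut` (transcript abundance in FPKM for
#' wild type and mutant), `copies_wt` (reference protein copies per cell) and
#' `mw` (protein molecular weight, g/mol); optional `direction`
#' (up/down/unchanged) and `category` (growth/hedging/other, defaulting to
#' "other"). Genes with reference copies but zero WT transcript are flagged
#' `efficiency_undefined`: their translation efficiency cannot be formed.
#'
#' @param path TSV file path.
#' @return data.frame of class `GeneBudgetTable` with an
#'   `efficiency_undefined` logical column.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "r_wt", "r_mut", "copies_wt", "mw")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("gene table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  if (!"direction" %in% names(tab)) tab$direction <- "unchanged"
  if (!"category" %in% names(tab)) tab$category <- "other"
  tab$category[is.na(tab$category) | tab$category == ""] <- "other"
  num <- c("r_wt", "r_mut", "copies_wt", "mw")
  for (nm in num) {
    if (any(tab[[nm]] < 0, na.rm = TRUE))
      stop("negative values in column ", nm)
  }
  tab$efficiency_undefined <- tab$r_wt == 0 & tab$copies_wt > 0
  class(tab) <- c("GeneBudgetTable", "data.frame")
  tab
}

#' Load an analysis configuration from YAML, merged over package defaults
#'
#' Recognized keys: `od_floor`, `time_unit`, `layout`, `window_frac`,
#' `prominence_frac`, `min_separation`, `resumption_frac`, `onset_frac`,
#' `od_target`, `od_tolerance`, `seed`.
#'
#' @param path YAML file, or `NULL` for the defaults alone.
#' @return named list of settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(od_floor = 0.005, time_unit = "minutes", layout = "wide",
                   window_frac = 0.8, prominence_frac = 0.10,
                   min_separation = 1, resumption_frac = 0.5,
                   onset_frac = 0.2, od_target = 0.2, od_tolerance = 0.02,
                   seed = 17)
  if (is.null(path)) return(defaults)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a config file requires the 'yaml' package")
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
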