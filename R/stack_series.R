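#' Ordered z-stack time series
#'
#' The raw experiment record: one 3-D intensity array per timepoint, with
#' acquisition times (minutes, strictly increasing) and per-timepoint phase
#' labels. Normalisation needs a pre-label baseline, so at least one control
#' timepoint must precede the first test timepoint.
#'
#' @param stacks list of 3-D numeric arrays (slice, row, col), all the same
#'   shape.
#' @param times numeric acquisition times in minutes, strictly increasing.
#' @param phases character vector, each one of "control", "test", "washout".
#' @param voxel_size numeric (z, y, x) voxel size in um.
#' @return an object of class `stack_series`.
#' @export
stack_series <- function(stacks, times, phases,
                         voxel_size = c(1, 0.41, 0.41)) {
  if (length(stacks) == 0L)
    stop_netrate("a stack series must contain at least one timepoint",
                 "netrate_format_error")
  if (length(stacks) != length(times) || length(times) != length(phases))
    stop_netrate("stacks, times and phases must have equal length",
                 "netrate_format_error")
  shapes <- vapply(stacks, function(s) paste(dim(s), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_netrate("all stacks must share the same shape",
                 "netrate_format_error")
  if (any(vapply(stacks, function(s) length(dim(s)), 0L) != 3L))
    stop_netrate("stacks must be 3-D arrays (slice, row, col)",
                 "netrate_format_error")
  if (is.unsorted(times, strictly = TRUE))
    stop_netrate("times must be strictly increasing", "netrate_format_error")
  if (!all(phases %in% PHASES))
    stop_netrate("phases must be control/test/washout",
                 "netrate_format_error")
  if (any(phases == "test") &&
      !any(phases == "control" & times < min(times[phases == "test"])))
    stop_netrate("at least one control timepoint must precede the first test timepoint",
                 "netrate_format_error")
  structure(list(stacks = stacks, times = as.numeric(times),
                 phases = as.character(phases),
                 voxel_size = as.numeric(voxel_size)),
            class = "stack_series")
}

#' @export
print.stack_series <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat("<stack_series> ", length(x$stacks), " timepoints, stacks ",
      paste(d, collapse = " x "), " px\n", sep = "")
  cat("  phases: ", paste(sprintf("%s (%d)", PHASES,
      vapply(PHASES, function(p) sum(x$phases == p), 0L)), collapse = ", "),
      "\n", sep = "")
  cat("  t = ", min(x$times), " .. ", max(x$times), " min; voxel ",
      paste(x$voxel_size, collapse = " x "), " um\n", sep = "")
  invisible(x)
}

#' @export
length.stack_series <- function(x) length(x$stacks)

# storage helpers ------------------------------------------------------------

# Integer-valued data in 0..65535 goes to 16-bit TIFF (bit-exact round trip,
# what a real detector produces). Anything else is stored as 32-bit samples
# scaled by a power of two recorded in the sidecar: fixed-point with a
# quantisation step of scale * 2^-32, i.e. round-trip accurate to ~1 part in
# 10^9 of the dynamic range.
series_storage <- function(series) {
  mx <- max(vapply(series$stacks, max, 0), 0)
  integral <- all(vapply(series$stacks,
                         function(s) all(s == round(s)), TRUE))
  if (integral && mx <= 65535) {
    list(dtype = "uint16", scale = 65535)
  } else {
    scale <- 2^max(0, ceiling(log2(max(mx, .Machine$double.eps))))
    list(dtype = "scaled32", scale = scale)
  }
}

stack_to_pages <- function(stack, storage) {
  lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ] / storage$scale)
}

pages_to_stack <- function(pages, storage) {
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    arr[z, , ] <- if (storage$dtype == "uint16") p else p * storage$scale
  }
  arr
}

write_one_tiff <- function(pages, path, storage) {
  if (storage$dtype == "uint16") {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  }
}

#' Write a stack series as TIFF + JSON sidecar
#'
#' Writes either one multi-page TIFF per timepoint (`stack_000.tif`, ...,
#' pages = z slices) or a single hyperstack file (`stacks.tif`, pages in
#' T-major then Z order), plus a `series.json` sidecar holding times, phases,
#' voxel size, shape and the storage encoding. Output bytes are deterministic.
#'
#' @param series a [stack_series()].
#' @param path output directory (created if absent).
#' @param hyperstack write one file for the whole series instead of one per
#'   timepoint.
#' @param truth optional ground-truth data.frame to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, hyperstack = FALSE, truth = NULL) {
  stopifnot(inherits(series, "stack_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  storage <- series_storage(series)
  d <- dim(series$stacks[[1]])
  if (hyperstack) {
    pages <- unlist(lapply(series$stacks, stack_to_pages, storage = storage),
                    recursive = FALSE)
    files <- "stacks.tif"
    write_one_tiff(pages, file.path(path, files), storage)
  } else {
    files <- sprintf("stack_%03d.tif", seq_along(series$stacks) - 1L)
    for (i in seq_along(series$stacks))
      write_one_tiff(stack_to_pages(series$stacks[[i]], storage),
                     file.path(path, files[i]), storage)
  }
  sidecar <- list(
    format = "netrate-series", version = 1L,
    times_min = series$times, phases = series$phases,
    voxel_size_um = series$voxel_size,
    shape = as.integer(d), dtype = storage$dtype, scale = storage$scale,
    hyperstack = hyperstack, files = as.list(files))
  if (!is.null(truth)) {
    sidecar$truth <- as.list(as.data.frame(truth))
    bf <- attr(truth, "bleach_factors")
    if (!is.null(bf)) sidecar$bleach_factors <- bf
  }
  jsonlite::write_json(sidecar, file.path(path, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stack series written by [write_series()]
#'
#' Validates the sidecar against the pixel data: every timepoint must share
#' the recorded shape, phases must be a valid protocol sequence, and times
#' must be strictly increasing.
#'
#' @param path directory containing TIFF file(s) and `series.json`.
#' @return a [stack_series()]; any embedded ground truth is attached as
#'   attribute `"truth"`.
#' @export
read_series <- function(path) {
  sidecar_path <- file.path(path, "series.json")
  if (!file.exists(sidecar_path))
    stop_netrate(sprintf("missing sidecar %s", sidecar_path),
                 "netrate_format_error")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("times_min", "phases", "shape", "dtype", "scale"))
    if (is.null(meta[[f]]))
      stop_netrate(sprintf("sidecar %s lacks field '%s'", sidecar_path, f),
                   "netrate_format_error")
  storage <- list(dtype = meta$dtype, scale = meta$scale)
  shape <- as.integer(meta$shape)
  read_pages <- function(file) {
    full <- file.path(path, file)
    if (!file.exists(full))
      stop_netrate(sprintf("missing image file %s", full),
                   "netrate_format_error")
    pages <- tryCatch(
      tiff::readTIFF(full, all = TRUE, as.is = storage$dtype == "uint16"),
      error = function(e) stop_netrate(
        sprintf("cannot read %s: %s", full, conditionMessage(e)),
        "netrate_format_error"))
    if (!is.list(pages)) pages <- list(pages)
    pages
  }
  if (isTRUE(meta$hyperstack)) {
    pages <- read_pages(meta$files[[1]])
    nt <- length(meta$times_min)
    if (length(pages) != nt * shape[1])
      stop_netrate(sprintf("%s: expected %d pages, found %d",
                           meta$files[[1]], nt * shape[1], length(pages)),
                   "netrate_format_error")
    stacks <- lapply(seq_len(nt), function(i)
      pages_to_stack(pages[(i - 1L) * shape[1] + seq_len(shape[1])], storage))
  } else {
    stacks <- lapply(unlist(meta$files), function(f) {
      pages <- read_pages(f)
      st <- pages_to_stack(pages, storage)
      if (!identical(dim(st), c(shape[1], shape[2], shape[3])))
        stop_netrate(sprintf("%s: shape %s does not match series shape %s",
                             f, paste(dim(st), collapse = "x"),
                             paste(shape, collapse = "x")),
                     "netrate_format_error")
      st
    })
  }
  series <- stack_series(stacks, meta$times_min, meta$phases,
                         voxel_size = meta$voxel_size_um %||% c(1, 0.41, 0.41))
  if (!is.null(meta$truth)) {
    tr <- as.data.frame(meta$truth)
    if (!is.null(meta$bleach_factors))
      attr(tr, "bleach_factors") <- meta$bleach_factors
    attr(series, "truth") <- tr
  }
  series
}
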