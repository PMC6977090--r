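#' Terminal region of interest
#'
#' A circular ROI around one nerve terminal: a centre (row, col, 0-based
#' fractional px allowed), a disc radius, the reference z-slice (the slice on
#' which the terminal is brightest in the first control stack), and a
#' surrounding annulus used for local background estimation.
#'
#' @param row,col centre in px (0-based).
#' @param radius disc radius, px (> 0).
#' @param reference_slice z index, 1-based.
#' @param annulus inner/outer background annulus radii, px; the inner radius
#'   must be at least `radius`.
#' @param terminal_id identifier carried through to traces and rate tables.
#' @return an object of class `terminal_roi`.
#' @export
terminal_roi <- function(row, col, radius = 3, reference_slice = 1L,
                         annulus = c(5, 8), terminal_id = NA_integer_) {
  if (radius <= 0)
    stop_netrate("ROI radius must be positive", "netrate_roi_error")
  if (annulus[1] < radius || annulus[2] <= annulus[1])
    stop_netrate("annulus must satisfy inner >= radius and outer > inner",
                 "netrate_roi_error")
  structure(list(terminal_id = terminal_id, row = row, col = col,
                 radius = radius, reference_slice = as.integer(reference_slice),
                 annulus = annulus),
            class = "terminal_roi")
}

#' @export
print.terminal_roi <- function(x, ...) {
  cat(sprintf("<terminal_roi #%s> centre (%.1f, %.1f), r = %g px, slice %d, annulus %g-%g px\n",
              x$terminal_id, x$row, x$col, x$radius, x$reference_slice,
              x$annulus[1], x$annulus[2]))
  invisible(x)
}

roi_as_row <- function(roi) {
  data.frame(terminal_id = roi$terminal_id, row = roi$row, col = roi$col,
             radius = roi$radius, reference_slice = roi$reference_slice,
             annulus_inner = roi$annulus[1], annulus_outer = roi$annulus[2])
}

#' Export / import ROI tables as CSV
#'
#' Columns: terminal_id, row, col, radius, reference_slice, annulus_inner,
#' annulus_outer. Coordinates are 0-based pixel positions.
#'
#' @param rois list of [terminal_roi()] objects.
#' @param path CSV path.
#' @return `write_rois` returns `path` invisibly; `read_rois` a list of
#'   [terminal_roi()].
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, roi_as_row))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    terminal_roi(df$row[i], df$col[i], radius = df$radius[i],
                 reference_slice = df$reference_slice[i],
                 annulus = c(df$annulus_inner[i], df$annulus_outer[i]),
                 terminal_id = df$terminal_id[i]))
}

# pixel index masks (1-based matrix indices) for a disc / annulus at a centre
disc_mask <- function(dims, row, col, r_in, r_out = NULL) {
  r0 <- row + 1; c0 <- col + 1   # 0-based centre -> 1-based grid
  rr <- max(1, floor(r0 - (r_out %||% r_in))):min(dims[1], ceiling(r0 + (r_out %||% r_in)))
  cc <- max(1, floor(c0 - (r_out %||% r_in))):min(dims[2], ceiling(c0 + (r_out %||% r_in)))
  g <- expand.grid(r = rr, c = cc)
  d2 <- (g$r - r0)^2 + (g$c - c0)^2
  keep <- if (is.null(r_out)) d2 <= r_in^2 else d2 > r_in^2 & d2 <= r_out^2
  cbind(g$r[keep], g$c[keep])
}

#' Automated terminal detection on the first control stack
#'
#' Finds varicosities as bright blobs on the per-pixel maximum projection over
#' z, using a multi-scale Laplacian-of-Gaussian response (computed as
#' differences of Gaussians). Candidates below `threshold`, closer than
#' `min_separation` px to a brighter candidate, or too close to the image
#' border for their background annulus are discarded. The reference slice of
#' each detection is the z with maximal disc mean. Raising the threshold can
#' only remove detections, never add them.
#'
#' The reference protocol places ROIs by hand; this detector automates that
#' step for reproducibility, and hand-placed centres can always be supplied
#' directly via [terminal_roi()] (see the `rois` argument of
#' [run_quantify()]).
#'
#' @param stack 3-D array (slice, row, col), typically the first control
#'   stack.
#' @param min_sigma,max_sigma blob scale range, px.
#' @param threshold minimal blob response, a.u.; `NULL` (default) uses an
#'   adaptive threshold of 10 x MAD of the response image, which yields zero
#'   detections on pure-noise fields.
#' @param min_separation minimal centre-to-centre distance, px; of two closer
#'   candidates the brighter is kept.
#' @param radius,annulus ROI geometry given to each detection.
#' @return list of [terminal_roi()] (possibly empty).
#' @export
detect_terminals <- function(stack, min_sigma = 1, max_sigma = 4,
                             threshold = NULL, min_separation = 5,
                             radius = 3, annulus = c(5, 8)) {
  stopifnot(length(dim(stack)) == 3L)
  mp <- apply(stack, c(2, 3), max)
  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = 4))
  resp <- NULL
  for (s in sigmas) {
    r <- EBImage::gblur(mp, s) - EBImage::gblur(mp, 1.6 * s)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  thr <- threshold %||% (10 * mad(resp))
  margin <- ceiling(annulus[2])
  cand <- which(resp >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list())
  inb <- cand[, 1] > margin & cand[, 1] <= nrow(mp) - margin &
         cand[, 2] > margin & cand[, 2] <= ncol(mp) - margin
  cand <- cand[inb, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  # keep only local maxima of the response: skirt pixels of a bright blob
  # pass the threshold but are not peaks
  hw <- max(1L, floor(min_separation / 2))
  is_peak <- vapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    win <- resp[max(1, r0 - hw):min(nrow(mp), r0 + hw),
                max(1, c0 - hw):min(ncol(mp), c0 + hw)]
    resp[r0, c0] >= max(win)
  }, TRUE)
  cand <- cand[is_peak, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  cand <- cand[order(resp[cand], decreasing = TRUE), , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= min_separation^2)
      kept <- rbind(kept, p)
  }
  lapply(seq_len(nrow(kept)), function(i) {
    row0 <- kept[i, 1] - 1; col0 <- kept[i, 2] - 1   # back to 0-based
    mask <- disc_mask(dim(mp), row0, col0, radius)
    zmeans <- vapply(seq_len(dim(stack)[1]),
                     function(z) mean(stack[z, , ][mask]), 0)
    terminal_roi(row0, col0, radius = radius,
                 reference_slice = which.max(zmeans), annulus = annulus,
                 terminal_id = i)
  })
}

#' Background-subtracted per-terminal fluorescence trace
#'
#' For each timepoint, the trace value is the mean intensity of the ROI disc
#' on the reference slice minus the median of the surrounding annulus on the
#' same slice (a robust local background estimate). The ROI position is fixed
#' across timepoints; optional re-centring searches within +/-3 px for the
#' locally brightest position at each timepoint (off by default, matching the
#' restore-the-same-ROI protocol).
#'
#' @param series a [stack_series()].
#' @param roi a [terminal_roi()].
#' @param recenter logical; re-centre the disc within a +/-3 px window at
#'   each timepoint.
#' @return an object of class `fluor_trace`: times, phases and
#'   background-subtracted values (a.u., may be negative).
#' @export
measure_trace <- function(series, roi, recenter = FALSE) {
  stopifnot(inherits(series, "stack_series"), inherits(roi, "terminal_roi"))
  d <- dim(series$stacks[[1]])
  if (roi$reference_slice < 1L || roi$reference_slice > d[1])
    stop_netrate("ROI reference slice outside stack", "netrate_roi_error")
  if (roi$row - roi$annulus[2] < 0 || roi$row + roi$annulus[2] > d[2] - 1 ||
      roi$col - roi$annulus[2] < 0 || roi$col + roi$annulus[2] > d[3] - 1)
    stop_netrate("ROI (incl. background annulus) extends outside the image",
                 "netrate_roi_error")
  dims2 <- d[2:3]
  base_disc <- disc_mask(dims2, roi$row, roi$col, roi$radius)
  base_ann <- disc_mask(dims2, roi$row, roi$col, roi$annulus[1],
                        roi$annulus[2])
  values <- vapply(seq_along(series$stacks), function(i) {
    sl <- series$stacks[[i]][roi$reference_slice, , ]
    disc <- base_disc; ann <- base_ann
    if (recenter) {
      best <- c(0, 0); best_v <- -Inf
      for (dr in -3:3) for (dc in -3:3) {
        m <- disc_mask(dims2, roi$row + dr, roi$col + dc, roi$radius)
        v <- mean(sl[m])
        if (v > best_v) { best_v <- v; best <- c(dr, dc) }
      }
      disc <- disc_mask(dims2, roi$row + best[1], roi$col + best[2],
                        roi$radius)
      ann <- disc_mask(dims2, roi$row + best[1], roi$col + best[2],
                       roi$annulus[1], roi$annulus[2])
    }
    mean(sl[disc]) - median(sl[ann])
  }, 0)
  structure(list(terminal_id = roi$terminal_id, times = series$times,
                 values = values, phases = series$phases),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace #%s> %d timepoints, t = %g..%g min\n",
              x$terminal_id, length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_min = x$times, phase = x$phases,
                   value = signif(x$values, 5)))
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(terminal_id = x$terminal_id, time_min = x$times,
             phase = x$phases, value = x$values)
}
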