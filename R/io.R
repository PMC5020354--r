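# On-disk layout for stacks, decay histograms, maps and reports.
#
# Rasters and decay cubes are stored as multi-page 32-bit TIFF. Counts are
# written as count / 2^24: a float32 mantissa holds 24 bits, so integer counts
# below 2^24 survive the round trip exactly. Acquisition metadata travels in a
# JSON sidecar.

COUNT_SCALE <- 2^24

#' Write a polarized FLIM stack
#'
#' Writes `<prefix>.tif` (page 1 = parallel raster, page 2 = perpendicular),
#' `<prefix>_cube_par.tif` / `<prefix>_cube_perp.tif` (one page per time bin,
#' present only when the stack carries a decay cube) and `<prefix>_meta.json`.
#'
#' @param stack a [polarized_flim_stack()].
#' @param prefix path prefix (no extension).
#' @return Invisibly, the vector of files written.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "polarized_flim_stack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- paste0(prefix, ".tif")
  tiff::writeTIFF(list(stack$raster_par / COUNT_SCALE,
                       stack$raster_perp / COUNT_SCALE),
                  files, bits.per.sample = 32L, compression = "deflate")
  if (!is.null(stack$cube_par)) {
    B <- dim(stack$cube_par)[3]
    for (ch in c("par", "perp")) {
      cube <- stack[[paste0("cube_", ch)]]
      pages <- lapply(seq_len(B), function(b) cube[, , b] / COUNT_SCALE)
      f <- paste0(prefix, "_cube_", ch, ".tif")
      tiff::writeTIFF(pages, f, bits.per.sample = 32L,
                      compression = "deflate")
      files <- c(files, f)
    }
  }
  meta <- list(pixel_size_um = stack$pixel_size_um, G = stack$G,
               bin_width_ns = stack$bin_width_ns,
               n_bins = if (is.null(stack$cube_par)) 0L else
                 dim(stack$cube_par)[3],
               count_scale = COUNT_SCALE)
  mf <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read a polarized FLIM stack written by [write_stack()]
#'
#' @param prefix path prefix used at write time.
#' @return A [polarized_flim_stack()].
#' @export
read_stack <- function(prefix) {
  mf <- paste0(prefix, "_meta.json")
  if (!file.exists(mf)) stop("missing stack metadata: ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  scale <- meta$count_scale
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  to_counts <- function(m) {
    m <- round(m * scale)
    storage.mode(m) <- "integer"
    m
  }
  raster_par <- to_counts(pages[[1]])
  raster_perp <- to_counts(pages[[2]])
  cube_par <- cube_perp <- NULL
  if (meta$n_bins > 0) {
    read_cube <- function(ch) {
      p <- tiff::readTIFF(paste0(prefix, "_cube_", ch, ".tif"), all = TRUE)
      a <- array(0L, c(dim(p[[1]]), length(p)))
      for (b in seq_along(p)) a[, , b] <- to_counts(p[[b]])
      a
    }
    cube_par <- read_cube("par")
    cube_perp <- read_cube("perp")
  }
  polarized_flim_stack(raster_par, raster_perp, cube_par, cube_perp,
                       pixel_size_um = meta$pixel_size_um, G = meta$G,
                       bin_width_ns = if (meta$n_bins > 0) meta$bin_width_ns
                                      else NA_real_)
}

#' Write / read a decay histogram as two-column CSV
#'
#' Columns `time_ns` (bin start) and `counts`; the constant bin width is
#' reconstructed from consecutive times on read.
#'
#' @param hist a [decay_histogram()].
#' @param path CSV file path.
#' @return `write_decay_csv`: the path, invisibly. `read_decay_csv`: a
#'   [decay_histogram()].
#' @export
write_decay_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  e <- hist$bin_edges_ns
  utils::write.csv(
    data.frame(time_ns = e[-length(e)], counts = hist$counts),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @param channel channel tag for the histogram read back.
#' @export
read_decay_csv <- function(path, channel = "total") {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ns", "counts") %in% names(df)))
  bw <- stats::median(diff(df$time_ns))
  decay_histogram(df$counts,
                  bin_edges_ns = c(df$time_ns, df$time_ns[nrow(df)] + bw),
                  channel = channel)
}

#' Write a real-valued map as 32-bit TIFF with a JSON transform sidecar
#'
#' Values are affinely rescaled into \[0, 1\] for float storage; the offset,
#' scale and NA sentinel are recorded in `<path>.json` so [read_map_tiff()]
#' restores the original values (to float32 precision).
#'
#' @param map numeric matrix (NAs allowed).
#' @param path TIFF file path.
#' @return The path, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(is.matrix(map))
  finite <- map[is.finite(map)]
  lo <- if (length(finite)) min(finite) else 0
  hi <- if (length(finite)) max(finite) else 1
  if (hi <= lo) hi <- lo + 1
  scaled <- (map - lo) / (hi - lo) * 0.98 + 0.01
  scaled[!is.finite(map)] <- 0  # sentinel below the data band
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  compression = "deflate")
  jsonlite::write_json(list(offset = lo, scale = hi - lo, band_lo = 0.01,
                            band_width = 0.98, na_sentinel = 0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  tr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  out <- (m - tr$band_lo) / tr$band_width * tr$scale + tr$offset
  out[m <= tr$na_sentinel + 1e-6] <- NA_real_
  out
}

#' Serialize an orientation report
#'
#' CSV carries one row (`nu_deg`, `sigma_nu_deg`, `ratio_R`,
#' `lifetime_ratio_T`, sector totals and lifetimes); JSON mirrors the full
#' report structure.
#'
#' @param report an `orientation_report` from [estimate_orientation()].
#' @param path_csv,path_json output paths (`NULL` skips that format).
#' @return Invisibly, the written paths.
#' @export
write_orientation_report <- function(report, path_csv = NULL,
                                     path_json = NULL) {
  stopifnot(inherits(report, "orientation_report"))
  row <- data.frame(
    nu_deg = report$result$nu_deg, sigma_nu_deg = report$result$sigma_nu_deg,
    cos2nu = report$result$cos2nu, ratio_R = report$result$ratio_R,
    lifetime_ratio_T = report$result$lifetime_ratio_T,
    F_Z = report$sector_Z$F_total, F_Y = report$sector_Y$F_total,
    tau_Z_ns = report$sector_Z$tau_amp_ns,
    tau_Y_ns = report$sector_Y$tau_amp_ns,
    n_pixels_Z = report$sector_Z$n_pixels,
    n_pixels_Y = report$sector_Y$n_pixels,
    aperture_deg = report$aperture_deg)
  if (!is.null(path_csv)) utils::write.csv(row, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(as.list(row), path_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(c(path_csv, path_json))
}

#' Serialize an organization report
#'
#' CSV rows mirror the organization-form table: one row per library form with
#' its amplitude fraction and standard error.
#'
#' @param report an `organization_report`.
#' @param path_csv,path_json output paths (`NULL` skips that format).
#' @return Invisibly, the written paths.
#' @export
write_organization_report <- function(report, path_csv = NULL,
                                      path_json = NULL) {
  stopifnot(inherits(report, "organization_report"))
  df <- data.frame(
    form = names(report$fractions_pct),
    tau_ns = report$fit$components$tau_ns,
    fraction_pct = unname(report$fractions_pct),
    se_pct = if (is.null(report$fractions_se_pct)) NA_real_ else
      unname(report$fractions_se_pct))
  if (!is.null(path_csv)) utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(fractions = df, tau_amp_ns = report$tau_amp_ns,
           chi2_reduced = report$chi2_reduced, n_pixels = report$n_pixels),
      path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_csv, path_json))
}

#' Write / read the generator ground truth
#'
#' @param truth a `ground_truth` from [simulate_guv_stack()].
#' @param path JSON path.
#' @return `write_ground_truth`: the path, invisibly; `read_ground_truth`: the
#'   parsed list.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  cfg$populations <- lapply(cfg$populations, function(p) {
    p$components <- as.list(p$components)
    p
  })
  out <- list(
    nu_deg = if (length(cfg$populations) == 1L &&
                 !cfg$populations[[1]]$isotropic)
      cfg$populations[[1]]$nu_deg else NA,
    expected_nu_deg = truth$expected_nu_deg,
    expected_cos2nu = truth$expected_cos2nu,
    expected_R = truth$expected_R,
    expected_fractions_pct = as.list(truth$expected_fractions_pct),
    center_px = truth$center_px, radius_px = truth$radius_px,
    seed = truth$seed, config = unclass(cfg))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
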