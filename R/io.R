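# File interfaces: multi-page TIFF stacks, localization CSV tables,
# calibration serialization and the pipeline configuration (JSON/YAML).

#' Read a multi-page TIFF into a 3D array
#'
#' @param path TIFF file.
#' @param offset,conversion camera calibration: photons =
#'   `(ADU - offset) * conversion`.
#' @return 3D array `[y, x, frame]` in photons.
#' @export
read_stack_tiff <- function(path, offset = 0, conversion = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  (arr - offset) * conversion
}

#' Write a 3D array as a multi-page 32-bit float TIFF
#'
#' Values are stored divided by 2^16 (the writer's float range is \[0, 1\]),
#' so photon counts up to 65536 round-trip at single precision. Use
#' [read_stack_tiff()] with `conversion = 65536` (the default for files
#' written here is handled by [read_stack_tiff_scaled()]).
#'
#' @param arr 3D array `[y, x, frame]`, values in \[0, 65536).
#' @param path output file.
#' @export
write_stack_tiff <- function(arr, path) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  if (max(arr) >= 65536 || min(arr) < 0)
    stop("values must lie in [0, 65536) for TIFF export")
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65536)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read back a stack written by [write_stack_tiff()]
#' @param path TIFF file.
#' @export
read_stack_tiff_scaled <- function(path) {
  read_stack_tiff(path, offset = 0, conversion = 65536)
}

#' Write a localization table to CSV
#' @param locs data.frame.
#' @param path output path.
#' @export
write_locs <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table (CSV with a one-line header)
#' @param path CSV path.
#' @export
read_locs <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Save a multi-channel calibration
#'
#' Serialized as an RDS file holding the spline coefficients, grid
#' metadata, normalization and the channel transforms.
#'
#' @param calibration a `multichannel_calibration`.
#' @param path output path.
#' @export
save_calibration <- function(calibration, path) {
  saveRDS(calibration, path)
  invisible(path)
}

#' Load a calibration saved by [save_calibration()]
#' @param path RDS path.
#' @export
load_calibration <- function(path) {
  cal <- readRDS(path)
  stopifnot(inherits(cal, "multichannel_calibration"))
  cal
}

#' Read a pipeline configuration (JSON or YAML)
#' @param path configuration file.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

split_channels <- function(img, layout) {
  switch(layout,
         none = list(img),
         leftright = {
           nx <- ncol(img) %/% 2L
           list(img[, seq_len(nx)], img[, nx + seq_len(nx)])
         },
         topbottom = {
           ny <- nrow(img) %/% 2L
           list(img[seq_len(ny), ], img[ny + seq_len(ny), ])
         },
         stop("unknown channel layout: ", layout))
}

#' Run the localization pipeline on a movie
#'
#' Detection (DoG per channel), candidate consolidation, ROI extraction,
#' global fitting, merging across consecutive frames, and quality
#' filtering, driven by a configuration list (see [read_config()]).
#'
#' @param config list with entries `movies` (per-channel TIFF paths, or
#'   one path plus `layout` = "leftright"/"topbottom"), `calibration`
#'   (path to a saved calibration) or `psfs`/`transforms` supplied
#'   directly, `camera` (offset, conversion), `detection`
#'   (sigma_small, sigma_large, k), `fit` (roi_size, link: character
#'   vector of shared parameters), `post` (merge_radius, max_gap,
#'   chi2_quantile, precision_cut).
#' @param verbose print per-stage counts.
#' @return localization data.frame.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cam <- config$camera %||% list(offset = 0, conversion = 1)
  layout <- config$layout %||% "none"
  if (!is.null(config$movies) && length(config$movies) >= 1) {
    stacks <- lapply(config$movies, read_stack_tiff,
                     offset = cam$offset %||% 0,
                     conversion = cam$conversion %||% 1)
    if (length(stacks) == 1 && layout != "none") {
      nfr <- dim(stacks[[1]])[3]
      chans <- split_channels(stacks[[1]][, , 1], layout)
      arrs <- lapply(chans, function(c0) array(0, c(dim(c0), nfr)))
      for (k in seq_len(nfr)) {
        ck <- split_channels(stacks[[1]][, , k], layout)
        for (i in seq_along(arrs)) arrs[[i]][, , k] <- ck[[i]]
      }
      stacks <- arrs
    }
  } else stop("config$movies is required")
  if (!is.null(config$calibration)) {
    cal <- load_calibration(config$calibration)
    psfs <- cal$psfs; transforms <- cal$transforms
  } else {
    psfs <- config$psfs; transforms <- config$transforms
  }
  nch <- length(stacks)
  if (is.null(transforms)) transforms <- rep(list(identity_transform()), nch)
  det <- config$detection %||% list()
  fitc <- config$fit %||% list()
  roi_size <- fitc$roi_size %||% 15
  shared <- fitc$link %||% c("x", "y", "z", "N", "bg")
  Slist <- fitc$S %||% list(N = rep(1 / nch, nch))
  link <- link_spec(nch, shared = shared, S = Slist)
  nfr <- dim(stacks[[1]])[3]
  all_rois <- list()
  for (k in seq_len(nfr)) {
    frames <- lapply(stacks, function(s) s[, , k])
    peaks <- lapply(frames, dog_detect,
                    sigma_small = det$sigma_small %||% 1.0,
                    sigma_large = det$sigma_large %||% 2.5,
                    k = det$k %||% 4)
    if (all(vapply(peaks, nrow, integer(1)) == 0)) next
    cands <- consolidate_candidates(peaks, transforms,
                                    merge_radius = det$merge_radius %||% 2,
                                    frame = k)
    rois <- extract_rois(frames, cands, transforms, roi_size = roi_size)
    all_rois <- c(all_rois, rois)
  }
  if (verbose) message(length(all_rois), " candidate ROIs from ", nfr,
                       " frames")
  if (!length(all_rois)) return(data.frame())
  res <- fit_rois_global(all_rois, psfs, link)
  origins <- t(vapply(all_rois, function(r) as.numeric(r$origin), numeric(2)))
  half <- (roi_size - 1) / 2
  locs <- data.frame(frame = res$frame,
                     x = res[[if ("x" %in% shared) "x" else "x_ch1"]] +
                       origins[, 1] - half,
                     y = res[[if ("y" %in% shared) "y" else "y_ch1"]] +
                       origins[, 2] - half,
                     z = res[[if ("z" %in% shared) "z" else "z_ch1"]],
                     photons = rowSums(res[, grep("^photons_ch",
                                                  names(res)),
                                           drop = FALSE]),
                     bg = res[[if ("bg" %in% shared) "bg" else "bg_ch1"]],
                     chi2 = res$chi2, converged = res$converged)
  for (i in seq_len(nch))
    locs[[paste0("photons_ch", i)]] <- res[[paste0("photons_ch", i)]]
  locs$crlb_x <- res[[if ("x" %in% shared) "crlb_x" else "crlb_x_ch1"]]
  locs$crlb_y <- res[[if ("y" %in% shared) "crlb_y" else "crlb_y_ch1"]]
  locs$crlb_z <- res[[if ("z" %in% shared) "crlb_z" else "crlb_z_ch1"]]
  post <- config$post %||% list()
  if (!is.null(post$merge_radius)) {
    n0 <- nrow(locs)
    locs <- merge_consecutive(locs, radius = post$merge_radius,
                              max_gap = post$max_gap %||% 0L)
    if (verbose) message(n0 - nrow(locs), " localizations merged")
  }
  if (!is.null(post$chi2_quantile) || !is.null(post$precision_cut)) {
    locs <- filter_locs(locs, psfs = psfs, link = link, roi_size = roi_size,
                        chi2_quantile = post$chi2_quantile,
                        precision_cut = post$precision_cut %||% Inf)
    if (verbose) message(attr(locs, "n_removed"), " localizations filtered")
  }
  if (!is.null(config$output)) write_locs(locs, config$output)
  locs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
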