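#' Generate a synthetic digitized-trajectory dataset
#'
#' Emulates a digitized live-cell protrusion dataset: persistent random
#' walk paths are simulated at the integration step, the shape is frozen
#' (validated on airinemes: the part of the path existing at time t does
#' not change as the tip extends, so the sampled time series equals the
#' final contour sampled along its length), tip positions are kept every
#' `imaging_interval` minutes, and isotropic Gaussian position noise of the
#' stated standard deviation is added.
#'
#' Two sampling densities matter in practice: frame-rate sampling
#' (`imaging_interval = 5` min, the acquisition interval, appropriate for
#' MSD and step-length statistics) and dense contour digitization
#' (`imaging_interval ~ 0.7` min, i.e. about one point per 3 um of
#' contour, the density of manual tracings, appropriate for tangent-angle
#' statistics). When `noise_sd = 0` the exact tangent headings are included
#' in the table (`heading_rad`); noisy datasets omit them, as real
#' tracings do.
#'
#' @param params Ground-truth [prw_params()].
#' @param n Number of airinemes (default 70, the digitized dataset size).
#' @param imaging_interval Sampling interval, min; must be a multiple of
#'   `params$dt`.
#' @param noise_sd Isotropic position noise per coordinate, um (>= 0).
#' @param duration_law Either `NULL` (every airineme grows to full length,
#'   duration `lmax / v`), a numeric vector of durations (min, recycled),
#'   or a `function(n)` returning durations; durations are capped at
#'   `lmax / v`.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A `prw_dataset`: list with `trajectories` (tibble
#'   `airineme_id`, `frame`, `t_min`, `x_um`, `y_um`[, `heading_rad`]),
#'   `contacts` (tibble of contact outcomes per airineme), `ground_truth`,
#'   `imaging_interval`, `noise_sd`, `durations`, `seed`.
#' @examples
#' ds <- generate_dataset(prw_params(), n = 5, seed = 1)
#' head(ds$trajectories)
#' @export
generate_dataset <- function(params = prw_params(), n = 70,
                             imaging_interval = 5, noise_sd = 0,
                             duration_law = NULL, seed = 1L) {
  stopifnot(inherits(params, "prw_params"), n >= 1)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  k <- as.integer(round(imaging_interval / params$dt))
  if (k < 1 || abs(imaging_interval - k * params$dt) > 1e-8) {
    stop("`imaging_interval` must be a multiple of params$dt", call. = FALSE)
  }
  durations <- if (is.null(duration_law)) {
    params$lmax / params$v
  } else if (is.function(duration_law)) {
    with_seed(derive_seed(seed, 3L), duration_law(n))
  } else {
    as.numeric(duration_law)
  }
  durations <- pmin(durations, params$lmax / params$v)
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)

  ens <- simulate_ensemble(params, n = n, seed = seed, durations = durations,
                           record_every = k)
  traj <- ens$recorded |>
    dplyr::filter(abs(.data$t_min / imaging_interval -
                        round(.data$t_min / imaging_interval)) < 1e-8) |>
    dplyr::group_by(.data$airineme_id) |>
    dplyr::mutate(frame = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  if (noise_sd > 0) {
    traj <- with_seed(derive_seed(seed, 2L), {
      dplyr::mutate(traj,
                    x_um = .data$x_um + rnorm(dplyr::n(), sd = noise_sd),
                    y_um = .data$y_um + rnorm(dplyr::n(), sd = noise_sd))
    })
    traj$heading_rad <- NULL
  }
  contacts <- ensemble_contacts(ens)
  structure(list(
    trajectories = traj, contacts = contacts, ground_truth = params,
    imaging_interval = imaging_interval, noise_sd = noise_sd,
    durations = durations, seed = as.integer(seed)
  ), class = "prw_dataset")
}

# Per-trajectory contact table of an ensemble.
ensemble_contacts <- function(ens) {
  n <- ens$n
  angle <- rep(NA_real_, n)
  tc <- rep(NA_real_, n)
  hits <- which(ens$contacted)
  angle[hits] <- ens$contact_angles
  tc[hits] <- ens$t_contact
  tibble::tibble(airineme_id = seq_len(n), contacted = ens$contacted,
                 contact_angle_rad = angle, t_contact_min = tc,
                 final_length_um = ens$length_distribution)
}

#' @export
print.prw_dataset <- function(x, ...) {
  cat(sprintf(
    "<prw_dataset> %d airinemes, %d points every %g min, noise sd %g um\n",
    length(unique(x$trajectories$airineme_id)), nrow(x$trajectories),
    x$imaging_interval, x$noise_sd))
  invisible(x)
}

#' Render trajectories as synthetic microscopy images
#'
#' The model-convolution forward step: each path is rasterised as a line of
#' unit flux per micrometre on a pixel canvas, convolved with an isotropic
#' Gaussian point-spread function, and degraded with Gaussian noise scaled
#' so that (peak signal) / (background noise sd) equals the requested
#' signal-to-noise ratio. Re-estimating parameters from such renders
#' measures how much the imaging pipeline biases an estimator.
#'
#' The default pixel size, PSF width and SNR are round placeholder values,
#' not measured microscope properties; calibrate them to your instrument.
#'
#' @param trajectories Trajectory tibble (see [compute_msd()]).
#' @param pixel_size Pixel edge, um.
#' @param psf_sigma PSF standard deviation, um.
#' @param snr Peak-signal to background-noise ratio; `Inf` disables noise.
#' @param seed Seed for the noise.
#' @param flux Line flux per um (scales the whole image linearly).
#' @return A `prw_rendered_stack`: list with `images` (list of matrices,
#'   row = y), `pixel_size`, `psf_sigma`, `snr`, `origins` (per-image world
#'   coordinates of pixel (1,1) centre), `ids`.
#' @export
render_images <- function(trajectories, pixel_size = 0.5, psf_sigma = 1,
                          snr = 5, seed = 1L, flux = 1) {
  stopifnot(pixel_size > 0, psf_sigma > 0, snr > 0)
  paths <- split_paths(trajectories)
  render_one <- function(p) {
    margin <- 4 * psf_sigma + 2 * pixel_size
    x0 <- min(p$x_um) - margin; x1 <- max(p$x_um) + margin
    y0 <- min(p$y_um) - margin; y1 <- max(p$y_um) + margin
    nx <- ceiling((x1 - x0) / pixel_size); ny <- ceiling((y1 - y0) / pixel_size)
    img <- matrix(0, nrow = ny, ncol = nx)
    # dense subsampling of each segment, flux deposited per sample length
    step <- pixel_size / 4
    for (i in seq_len(nrow(p) - 1)) {
      ax <- p$x_um[i]; ay <- p$y_um[i]
      bx <- p$x_um[i + 1]; by <- p$y_um[i + 1]
      len <- sqrt((bx - ax)^2 + (by - ay)^2)
      if (len == 0) next
      m <- max(2, ceiling(len / step) + 1)
      ss <- seq(0, 1, length.out = m)
      xs <- ax + ss * (bx - ax); ys <- ay + ss * (by - ay)
      w <- rep(len / (m - 1), m); w[c(1, m)] <- w[1] / 2  # trapezoid weights
      ix <- pmin(pmax(floor((xs - x0) / pixel_size) + 1, 1), nx)
      iy <- pmin(pmax(floor((ys - y0) / pixel_size) + 1, 1), ny)
      idx <- (ix - 1) * ny + iy
      tab <- rowsum(w * flux / pixel_size^2, idx)  # flux density per pixel area
      img[as.integer(rownames(tab))] <- img[as.integer(rownames(tab))] + tab[, 1]
    }
    img <- gaussian_blur(img, psf_sigma / pixel_size)
    if (is.finite(snr)) {
      noise_sd <- max(img) / snr
      img <- img + matrix(rnorm(length(img), sd = noise_sd),
                          nrow = nrow(img))
    }
    list(img = img, origin = c(x0 + pixel_size / 2, y0 + pixel_size / 2))
  }
  rendered <- with_seed(derive_seed(seed, 11L), lapply(paths, render_one))
  structure(list(
    images = lapply(rendered, `[[`, "img"),
    origins = lapply(rendered, `[[`, "origin"),
    ids = names(paths),
    pixel_size = pixel_size, psf_sigma = psf_sigma, snr = snr
  ), class = "prw_rendered_stack")
}

# Separable Gaussian blur, sigma in pixels, via banded convolution matrices.
gaussian_blur <- function(img, sigma_px) {
  make_k <- function(m) {
    K <- matrix(0, m, m)
    r <- ceiling(4 * sigma_px)
    for (i in seq_len(m)) {
      j <- max(1, i - r):min(m, i + r)
      w <- dnorm(j - i, sd = sigma_px)
      K[i, j] <- w / sum(dnorm((-r):r, sd = sigma_px))
    }
    K
  }
  Ky <- make_k(nrow(img)); Kx <- make_k(ncol(img))
  Ky %*% img %*% t(Kx)
}

#' Write a rendered stack to TIFF files
#'
#' One 32-bit float TIFF per image (values rescaled to `[0, 1]` by the
#' stack maximum), named by airineme id.
#'
#' @param stack A `prw_rendered_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_rendered_stack <- function(stack, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF files", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(unlist(lapply(stack$images, max)), 1e-12)
  paths <- purrr::imap_chr(stack$images, function(img, i) {
    f <- file.path(dir, sprintf("airineme_%s.tif", stack$ids[[i]]))
    tiff::writeTIFF(pmin(pmax(img / mx, 0), 1), f, bits.per.sample = 32L)
    f
  })
  invisible(unname(paths))
}

#' Three-point contact angles on a synthetic dataset
#'
#' Applies the image-analysis angle protocol ([three_point_contact_angle()])
#' to every contacted airineme of a synthetic dataset: origin = the
#' airineme's first point, centre = the target centre perturbed by
#' isotropic Gaussian jitter of sd `center_jitter_sd` (emulating the
#' uncertainty of placing a centre on a highly noncircular cell), contact
#' point = the simulated contact location. With zero jitter the angles
#' equal the simulator's contact angles in degrees.
#'
#' @param dataset A `prw_dataset` from [generate_dataset()].
#' @param center_jitter_sd Centre jitter per coordinate, um.
#' @param seed Seed for the jitter.
#' @return A tibble `airineme_id`, `angle_deg` (empty, with a warning, when
#'   nothing contacted).
#' @export
measure_contact_angles_synthetic <- function(dataset, center_jitter_sd = 0,
                                             seed = 1L) {
  stopifnot(inherits(dataset, "prw_dataset"), center_jitter_sd >= 0)
  con <- dplyr::filter(dataset$contacts, .data$contacted)
  if (nrow(con) == 0) {
    warning("no contacts in dataset; returning empty angle table")
    return(tibble::tibble(airineme_id = integer(0), angle_deg = numeric(0)))
  }
  g <- search_geometry(dataset$ground_truth)
  rt <- dataset$ground_truth$rtarg
  with_seed(derive_seed(seed, 5L), {
    angs <- purrr::map_dbl(seq_len(nrow(con)), function(i) {
      centre <- g$target_center + rnorm(2, sd = center_jitter_sd)
      contact_pt <- rt * c(cos(con$contact_angle_rad[i]),
                           sin(con$contact_angle_rad[i]))
      three_point_contact_angle(g$source_point, centre, contact_pt)
    })
    tibble::tibble(airineme_id = con$airineme_id, angle_deg = angs)
  })
}
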