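#' Synthetic timelapse imaging configuration
#'
#' Geometry and detector model for the renderer: the cell is a horizontal
#' spherocylinder of the trajectory's length and fixed width, with the
#' nucleus drawn as an axial disk sized to a target fraction of the
#' pixel-counted cell area.  Pixel values are
#' `photon_scale * concentration` photons (Poisson), plus Gaussian read
#' noise and a constant background, quantised to 16 bit.  A single plane is
#' rendered (the downstream analysis consumes projected images).
#'
#' @param dt_img acquisition interval (min).
#' @param pixel_size_nm pixel edge (nm).
#' @param cell_width_um cell diameter (um).
#' @param nuclear_fraction target nuclear/cell area fraction, in (0, 1).
#' @param photon_scale photons per concentration unit (the detector gain).
#' @param read_noise Gaussian read noise s.d. (counts).
#' @param background constant background level (counts).
#' @param poisson_noise logical; disable together with `read_noise = 0` for
#'   an exact noise-free forward model.
#' @param frame_px frame size `c(height, width)` in pixels.
#' @return a list of class `"imaging_config"`.
#' @export
imaging_config <- function(dt_img = 5, pixel_size_nm = 130,
                           cell_width_um = 3.5, nuclear_fraction = 0.15,
                           photon_scale = 200, read_noise = 2,
                           background = 100, poisson_noise = TRUE,
                           frame_px = c(64L, 256L)) {
  stop_if_not_scalar(dt_img, "dt_img", lower = 1e-9)
  stop_if_not_scalar(nuclear_fraction, "nuclear_fraction",
                     lower = 1e-6, upper = 1 - 1e-6)
  structure(list(dt_img = dt_img, pixel_size_nm = pixel_size_nm,
                 cell_width_um = cell_width_um,
                 nuclear_fraction = nuclear_fraction,
                 photon_scale = photon_scale, read_noise = read_noise,
                 background = background, poisson_noise = poisson_noise,
                 frame_px = as.integer(frame_px)),
            class = "imaging_config")
}

## pixel masks for a horizontal spherocylinder of length L_um centred in
## the frame, and its axial nuclear disk sized to the area-fraction target
cell_masks <- function(L_um, config) {
  px_um <- config$pixel_size_nm / 1000
  H <- config$frame_px[1]; W <- config$frame_px[2]
  L_px <- L_um / px_um
  r_px <- (config$cell_width_um / 2) / px_um
  if (L_px > W || 2 * r_px > H)
    stop(sprintf("cell (%.1f x %.1f px) does not fit the %d x %d px frame",
                 L_px, 2 * r_px, H, W), call. = FALSE)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  half_axis <- max(L_px / 2 - r_px, 0)   # half-length of the straight part
  xs <- matrix(rep(seq_len(W), each = H), nrow = H)
  ys <- matrix(rep(seq_len(H), times = W), nrow = H)
  dx <- pmax(abs(xs - cx) - half_axis, 0)
  dy <- ys - cy
  cell <- (dx^2 + dy^2) <= r_px^2
  n_cell <- sum(cell)
  r_n <- sqrt(config$nuclear_fraction * n_cell / pi)
  nuc <- ((xs - cx)^2 + dy^2) <= r_n^2 & cell
  list(cell = cell, nucleus = nuc)
}

#' Render a trajectory as a synthetic timelapse
#'
#' Samples the trajectory at the acquisition interval and renders each
#' channel (one per sensor, plus cyclin) as a 16-bit image stack with
#' matching per-frame cell and nuclear masks and a ground-truth table of
#' the compartment concentrations that generated each frame.
#'
#' @param traj a `"cdk_trajectory"`.
#' @param config an [imaging_config()].
#' @param seed integer seed for the photon/read noise.
#' @return object of class `"timelapse_render"`: `images` (named list of
#'   `H x W x T` arrays, counts), `cell_mask`, `nuclear_mask` (logical
#'   arrays), `time`, `truth` (data.frame of per-frame true concentrations),
#'   `config`.
#' @export
render_timelapse <- function(traj, config = imaging_config(), seed = 1L) {
  stopifnot(inherits(traj, "cdk_trajectory"),
            inherits(config, "imaging_config"))
  ratio <- config$dt_img / traj$dt_sim
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("config dt_img must be an integer multiple of the trajectory dt_sim",
         call. = FALSE)
  set.seed(seed)
  idx <- seq(1L, length(traj$time), by = as.integer(round(ratio)))
  tt <- traj$time[idx]
  st <- traj$state[idx, , drop = FALSE]
  phi <- traj$params$phi_n
  H <- config$frame_px[1]; W <- config$frame_px[2]
  chans <- unname(c(vapply(traj$sensors, `[[`, "", "kind"), "cyclin"))
  images <- lapply(chans, function(ch) array(0, dim = c(H, W, length(idx))))
  names(images) <- chans
  cell_mask <- nuclear_mask <- array(FALSE, dim = c(H, W, length(idx)))
  truth <- vector("list", length(idx))
  max_count <- 2^16 - 1
  for (f in seq_along(idx)) {
    masks <- cell_masks(st[f, "L"], config)
    cell_mask[, , f] <- masks$cell
    nuclear_mask[, , f] <- masks$nucleus
    cyto <- masks$cell & !masks$nucleus
    conc <- list()
    for (ch in chans) {
      if (ch == "cyclin") {
        cn <- unname(st[f, "C_n"]); cc <- unname(st[f, "C_c"])
      } else {
        fs <- unname(st[f, paste0("f_", ch)])
        cn <- fs / phi; cc <- (1 - fs) / (1 - phi)
      }
      conc[[ch]] <- c(nuclear = cn, cytoplasmic = cc)
      frame <- matrix(0, H, W)
      lam <- matrix(0, H, W)
      lam[masks$nucleus] <- config$photon_scale * cn
      lam[cyto] <- config$photon_scale * cc
      if (config$poisson_noise) {
        frame[masks$cell] <- stats::rpois(sum(masks$cell), lam[masks$cell])
      } else {
        frame[masks$cell] <- lam[masks$cell]
      }
      frame <- frame + config$background
      if (config$read_noise > 0)
        frame <- frame + matrix(stats::rnorm(H * W, 0, config$read_noise),
                                H, W)
      if (config$poisson_noise || config$read_noise > 0)
        frame <- round(frame)
      images[[ch]][, , f] <- pmin(pmax(frame, 0), max_count)
    }
    truth[[f]] <- data.frame(
      frame = f, time_min = tt[f],
      channel = chans,
      nuclear_conc = vapply(conc, `[`, 0, "nuclear"),
      cytoplasmic_conc = vapply(conc, `[`, 0, "cytoplasmic"),
      length_um = unname(st[f, "L"]), row.names = NULL)
  }
  structure(list(images = images, cell_mask = cell_mask,
                 nuclear_mask = nuclear_mask, time = tt,
                 truth = do.call(rbind, truth), config = config,
                 cell_id = traj$cell_id),
            class = "timelapse_render")
}

#' @export
print.timelapse_render <- function(x, ...) {
  d <- dim(x$cell_mask)
  cat(sprintf("timelapse_render '%s': %d frame(s) of %d x %d px, channels: %s\n",
              x$cell_id, d[3], d[1], d[2],
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Quantify a rendered timelapse back into a trace table
#'
#' Runs either the top-fraction or the nuclear-mask compartment estimator on
#' every frame of a render, producing the shared long-format trace table.
#' The per-frame background estimate is the median of non-cell pixels.
#'
#' @param render a `"timelapse_render"`.
#' @param method `"top_fraction"` or `"mask"`.
#' @param frac top fraction for the top-fraction estimator.
#' @return data.frame in the [sample_traces()] schema plus a `background`
#'   column.
#' @export
quantify_render <- function(render, method = c("top_fraction", "mask"),
                            frac = 0.15) {
  method <- match.arg(method)
  d <- dim(render$cell_mask)
  out <- list()
  for (f in seq_len(d[3])) {
    cm <- render$cell_mask[, , f]
    nm <- render$nuclear_mask[, , f]
    nuc_idx <- which(nm[cm])
    for (ch in names(render$images)) {
      frame <- render$images[[ch]][, , f]
      px <- frame[cm]
      bg <- stats::median(frame[!cm])
      m <- if (method == "top_fraction") compartment_means_topfrac(px, frac)
           else compartment_means_masked(px, nuc_idx)
      L <- render$truth$length_um[render$truth$frame == f][1]
      out[[length(out) + 1L]] <- data.frame(
        cell_id = render$cell_id, time_min = render$time[f], channel = ch,
        nuclear_mean = m[["nuclear_mean"]],
        cytoplasmic_mean = m[["cytoplasmic_mean"]],
        whole_mean = m[["whole_mean"]], length_um = L, background = bg,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a render to multi-page TIFF files
#'
#' One 16-bit multi-page TIFF per channel (`<channel>.tif`) plus binary
#' mask stacks (`cell_mask.tif`, `nuclear_mask.tif`).
#'
#' @param render a `"timelapse_render"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_timelapse_tiff <- function(render, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(render$cell_mask)
  paths <- character(0)
  as_pages <- function(arr, scale) {
    lapply(seq_len(d[3]), function(f) arr[, , f] / scale)
  }
  for (ch in names(render$images)) {
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(as_pages(render$images[[ch]], 2^16 - 1), p,
                    bits.per.sample = 16)
    paths <- c(paths, p)
  }
  for (m in c("cell_mask", "nuclear_mask")) {
    p <- file.path(dir, paste0(m, ".tif"))
    tiff::writeTIFF(as_pages(render[[m]] * 1, 1), p, bits.per.sample = 8)
    paths <- c(paths, p)
  }
  invisible(paths)
}
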