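render_fixture <- function(noise = TRUE, duration = 40, dt_img = 10) {
  cfg <- imaging_config(dt_img = dt_img,
                        poisson_noise = noise,
                        read_noise = if (noise) 2 else 0)
  tr <- simulate_trajectory(default_wt(), default_sensors("NucCDK"),
                            duration = duration, dt_sim = 0.5)
  render_timelapse(tr, cfg, seed = 9)
}

test_that("noise-free rendering is the exact forward model", {
  rd <- render_fixture(noise = FALSE)
  f <- 1
  cm <- rd$cell_mask[, , f]; nm <- rd$nuclear_mask[, , f]
  truth <- rd$truth[rd$truth$frame == f & rd$truth$channel == "cyclin", ]
  img <- rd$images$cyclin[, , f]
  g <- rd$config$photon_scale; b <- rd$config$background
  expect_equal(mean(img[nm]), g * truth$nuclear_conc + b, tolerance = 1e-12)
  expect_equal(mean(img[cm & !nm]), g * truth$cytoplasmic_conc + b,
               tolerance = 1e-12)
  ## all pixels within one compartment identical
  expect_equal(stats::sd(img[nm]), 0)
  ## outside the cell: pure background
  expect_true(all(img[!cm] == b))
})

test_that("nuclear mask area fraction tracks the 15% geometry target", {
  rd <- render_fixture(noise = FALSE)
  for (f in seq_len(dim(rd$cell_mask)[3])) {
    frac <- sum(rd$nuclear_mask[, , f]) / sum(rd$cell_mask[, , f])
    expect_lt(abs(frac - 0.15), 0.01)
  }
})

test_that("a cell longer than the frame is refused naming the frame size", {
  cfg <- imaging_config(frame_px = c(32L, 48L))
  tr <- simulate_trajectory(default_wt(), list(), duration = 20, dt_sim = 0.5)
  expect_error(render_timelapse(tr, cfg), "frame")
})

test_that("quantifying a render recovers concentrations within noise", {
  rd <- render_fixture(noise = TRUE, duration = 60)
  q <- quantify_render(rd, method = "mask")
  cyc <- q[q$channel == "cyclin", ]
  truth <- rd$truth[rd$truth$channel == "cyclin", ]
  g <- rd$config$photon_scale
  rec <- (cyc$nuclear_mean - cyc$background) / g
  expect_lt(max(abs(rec - truth$nuclear_conc) /
                  pmax(truth$nuclear_conc, 0.05)), 0.1)
})

test_that("top-fraction and mask estimators agree on rendered nuclear-bright frames", {
  ## use the late-G2 frames of the nuclear sensor channel, where the
  ## nucleus is clearly the brightest region
  rd <- render_fixture(noise = TRUE, duration = 60)
  qt <- quantify_render(rd, method = "top_fraction")
  qm <- quantify_render(rd, method = "mask")
  sel_t <- qt$channel == "NucCDK"
  sel_m <- qm$channel == "NucCDK"
  rel <- abs(qt$nuclear_mean[sel_t] - qm$nuclear_mean[sel_m]) /
    qm$nuclear_mean[sel_m]
  expect_lt(stats::median(rel), 0.02)
})

test_that("renders round-trip through multi-page TIFF files", {
  rd <- render_fixture(noise = FALSE, duration = 20)
  dir <- tempfile("render")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_timelapse_tiff(rd, dir)
  expect_true(all(file.exists(file.path(dir, c("NucCDK.tif", "cyclin.tif",
                                               "cell_mask.tif",
                                               "nuclear_mask.tif")))))
  pages <- tiff::readTIFF(file.path(dir, "cyclin.tif"), all = TRUE)
  expect_equal(length(pages), dim(rd$cell_mask)[3])
  back <- round(pages[[1]] * (2^16 - 1))
  expect_equal(back, rd$images$cyclin[, , 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})
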