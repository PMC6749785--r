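test_that("band-pass gain peaks at mu, halves at the Gaussian half-width,
           and is radially symmetric", {
  spec <- filter_spec(mu = 0.07, sigma = 120, size = 256L)
  s <- 120 * 0.07 / 256
  expect_equal(wigglecamo:::bandpass_gain(0.07, spec), 1)
  expect_equal(wigglecamo:::bandpass_gain(0.07 + s * sqrt(2 * log(2)), spec),
               0.5, tolerance = 1e-12)
  g <- make_bandpass_filter(spec)
  expect_equal(max(g), 1, tolerance = 1e-4) # nearest discrete frequency bin
  # symmetry: gain depends only on |frequency|, so the four quadrant
  # reflections of any off-axis sample coincide
  expect_equal(g[10, 17], g[256 - 8, 17])
  expect_equal(g[10, 17], g[10, 256 - 15])
  expect_equal(g[10, 17], g[17, 10]) # and on the radius itself
})

test_that("filter spec validation rejects bad parameters", {
  expect_error(filter_spec(mu = 0), "mu")
  expect_error(filter_spec(sigma = -1), "sigma")
  expect_error(filter_spec(size = 255), "even")
})

test_that("two-tone synthesis posterises at the median with two colours", {
  spec <- filter_spec(size = 128L)
  pal <- grey_palette(40, 60)
  for (seed in c(1L, 7L, 42L)) {
    tx <- synthesize_two_tone(spec, pal, seed = seed)
    cols <- unique(matrix(tx$image, ncol = 3))
    expect_equal(nrow(cols), 2L)
    expect_equal(mean(tx$label_map), 0.5, tolerance = 1 / 128)
    expect_true(all(tx$image >= 0 & tx$image <= 1))
  }
  expect_identical(synthesize_two_tone(spec, pal, seed = 5L)$image,
                   synthesize_two_tone(spec, pal, seed = 5L)$image)
  expect_false(identical(synthesize_two_tone(spec, pal, seed = 5L)$label_map,
                         synthesize_two_tone(spec, pal, seed = 6L)$label_map))
})

test_that("patch palette is drawn from the stated lightness percentile bands", {
  pop <- grey_population(4000)
  L <- farver::convert_colour(pop * 255, "rgb", "lab")[, 1]
  q <- quantile(L, c(.35, .45, .55, .65), names = FALSE) # brute-force bands
  for (seed in 1:10) {
    pal <- pick_patch_palette(pop, seed = seed)
    expect_gte(pal$colour_a$L, q[1]); expect_lte(pal$colour_a$L, q[2])
    expect_gte(pal$colour_b$L, q[3]); expect_lte(pal$colour_b$L, q[4])
    expect_lt(pal$colour_a$L, pal$colour_b$L)
  }
  expect_error(pick_patch_palette(pop[1:50, , drop = FALSE]), ">= 100")
  same <- matrix(rep(c(0.5, 0.5, 0.5), each = 200), ncol = 3)
  expect_error(pick_patch_palette(same), "degenerate")
})

test_that("edge enhancement shifts band lightness by the offset and leaves
           the rest untouched", {
  cal <- default_calibration()
  # straight vertical boundary: left half dark, right half light
  lab_map <- matrix(0L, 128, 128); lab_map[, 65:128] <- 1L
  tx <- two_tone_from_labels(lab_map, grey_palette(40, 60))
  ee <- apply_edge_enhancement(tx, ee_spec(0.63, 20), cal)
  half_px <- deg_to_px(cal, 0.63) / 2
  changed <- apply(abs(ee$image - tx$image), c(1, 2), max) > 1e-9
  # no pixel outside the band changes
  expect_true(all(!changed[ee$ee_band == 0]))
  # pre-clipping lightness shift is exactly +/- offset across the band
  expect_true(all(ee$ee_dL[ee$ee_band == 1] == 20))
  expect_true(all(ee$ee_dL[ee$ee_band == -1] == -20))
  # with a modest offset nothing clips, so realised dL matches the offset
  dl <- image_L(ee$image) - image_L(tx$image)
  expect_equal(mean(abs(dl[ee$ee_band != 0])), 20, tolerance = 1e-3)
  # band width across the straight boundary: one row's run of changed
  # pixels; pixel centres within half_px of the boundary plane
  w <- sum(changed[64, ])
  expect_equal(w, 2 * floor(half_px + 0.5))
  expect_lt(abs(px_to_deg(cal, w) - 0.63), px_to_deg(cal, 1))
})

test_that("zero-offset edge enhancement is the identity on the image", {
  lab_map <- matrix(0L, 64, 64); lab_map[, 33:64] <- 1L
  tx <- two_tone_from_labels(lab_map, grey_palette(40, 60))
  ee0 <- apply_edge_enhancement(tx, ee_spec(0.63, 0), default_calibration())
  expect_identical(ee0$image, tx$image)
  expect_identical(ee0$colouration, "edge_enhanced_disruptive")
})

test_that("edge enhancement refuses uniform textures", {
  pal <- grey_palette(40, 60)
  u <- make_uniform_texture(pal, size = 32L)
  expect_error(apply_edge_enhancement(u), "not applicable")
})

test_that("uniform control sits at the CIELAB midpoint of the palette", {
  pal <- grey_palette(40, 60)
  u <- make_uniform_texture(pal, size = 64L)
  expect_equal(nrow(unique(matrix(u$image, ncol = 3))), 1L)
  expect_equal(dim(u$image), c(64L, 64L, 3L))
  expect_equal(image_L(u$image)[1, 1], 50, tolerance = 0.01)
})

test_that("synthesis concentrates power at the filter peak", {
  spec <- filter_spec(size = 256L)
  pal <- grey_palette(40, 60)
  spec_sum <- NULL
  for (seed in 1:5) {
    tx <- synthesize_two_tone(spec, pal, seed = seed)
    ps <- texture_power_spectrum(tx)
    ps <- ps[ps$freq > 0, ]
    spec_sum <- if (is.null(spec_sum)) ps$power else spec_sum + ps$power
  }
  peak <- ps$freq[which.max(spec_sum)]
  expect_equal(peak, 0.07, tolerance = (1 / 256) / 0.07)
})
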