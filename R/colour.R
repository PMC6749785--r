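# sRGB <-> CIELAB plumbing (D65, 2-degree observer), via farver.
# Images are h x w x 3 arrays of sRGB in [0, 1].

srgb_to_lab <- function(rgb01) {
  farver::convert_colour(rgb01 * 255, from = "rgb", to = "lab")
}

lab_to_srgb <- function(lab) {
  out <- farver::convert_colour(lab, from = "lab", to = "rgb") / 255
  pmin(pmax(out, 0), 1) # gamut clip
}

img_to_lab <- function(img) {
  d <- dim(img)
  m <- srgb_to_lab(matrix(img, ncol = 3L))
  list(L = matrix(m[, 1], d[1], d[2]),
       a = matrix(m[, 2], d[1], d[2]),
       b = matrix(m[, 3], d[1], d[2]))
}

lab_to_img <- function(lab) {
  d <- dim(lab$L)
  m <- lab_to_srgb(cbind(as.vector(lab$L), as.vector(lab$a), as.vector(lab$b)))
  array(m, c(d[1], d[2], 3L))
}

# Solid-colour image from one sRGB triple
solid_image <- function(rgb01, nrow, ncol) {
  array(rep(rgb01, each = nrow * ncol), c(nrow, ncol, 3L))
}

# CIELCh (L, chroma, hue in degrees) -> sRGB in [0,1]
lch_to_srgb <- function(l, c, h) {
  lab <- cbind(l, c * cos(h * pi / 180), c * sin(h * pi / 180))
  lab_to_srgb(lab)
}
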