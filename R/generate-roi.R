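# Synthetic ROI rendering.
#
# Shapes are unions of geometric primitives (rotated rods and discs)
# rasterized onto a pixel grid; the analytic biovolume of the generative
# solid (cylinders and spheres) is carried along as ground truth. No
# attempt is made to model the instrument's optics: intensities are flat
# shading plus Gaussian noise, which is all the segmentation and feature
# contracts require.

# primitive constructors: coordinates in um, origin at shape centre
.rod <- function(x0, y0, angle, length, width) {
  list(kind = "rod", x0 = x0, y0 = y0, angle = angle,
       length = length, width = width)
}
.disc <- function(x0, y0, r) list(kind = "disc", x0 = x0, y0 = y0, r = r)

.primitive_inside <- function(p, gx, gy) {
  if (p$kind == "rod") {
    u <- (gx - p$x0) * cos(p$angle) + (gy - p$y0) * sin(p$angle)
    v <- -(gx - p$x0) * sin(p$angle) + (gy - p$y0) * cos(p$angle)
    abs(u) <= p$length / 2 & abs(v) <= p$width / 2
  } else {
    (gx - p$x0)^2 + (gy - p$y0)^2 <= p$r^2
  }
}

.primitive_extent <- function(p) {
  if (p$kind == "rod") {
    h <- sqrt((p$length / 2)^2 + (p$width / 2)^2)
    c(p$x0 - h, p$x0 + h, p$y0 - h, p$y0 + h)
  } else {
    c(p$x0 - p$r, p$x0 + p$r, p$y0 - p$r, p$y0 + p$r)
  }
}

# Build the primitive list and analytic biovolume for one particle.
.sample_shape <- function(taxon) {
  ln <- function(med) rlnorm(1, log(med), taxon$size_spread)
  len <- ln(taxon$length_um)
  wid <- ln(taxon$width_um)
  n_cells <- if (length(taxon$colony_cells) == 1) {
    taxon$colony_cells
  } else {
    sample(taxon$colony_cells, 1)
  }
  cyl_vol <- pi * (wid / 2)^2 * len
  prims <- switch(taxon$shape_family,
    needle = ,
    cylinder_with_chloroplasts = list(.rod(0, 0, runif(1, 0, pi), len, wid)),
    disk = list(.disc(0, 0, len / 2)),
    star_colony = {
      base <- runif(1, 0, 2 * pi)
      lapply(seq_len(n_cells), function(i) {
        a <- base + (i - 1) * 2 * pi / n_cells + rnorm(1, 0, 0.12)
        .rod(len / 2 * cos(a), len / 2 * sin(a), a, len, wid)
      })
    },
    ribbon_colony = {
      a <- runif(1, 0, pi)
      offs <- (seq_len(n_cells) - (n_cells + 1) / 2) * wid
      lapply(offs, function(o) {
        .rod(o * cos(a + pi / 2), o * sin(a + pi / 2), a + pi / 2, len, wid)
      })
    },
    zigzag_colony = {
      base <- runif(1, 0, pi)
      zig <- 0.6 # rad, alternation half-angle
      x <- 0; y <- 0
      prims <- vector("list", n_cells)
      for (i in seq_len(n_cells)) {
        a <- base + ifelse(i %% 2 == 0, zig, -zig)
        cx <- x + len / 2 * cos(a); cy <- y + len / 2 * sin(a)
        prims[[i]] <- .rod(cx, cy, a, len, wid)
        x <- x + len * cos(a); y <- y + len * sin(a)
      }
      prims
    },
    blob = {
      k <- sample(2:4, 1)
      lapply(seq_len(k), function(i) {
        .disc(rnorm(1, 0, len / 4), rnorm(1, 0, len / 4), ln(len / 3) / 2)
      })
    },
    abort(paste0("Unhandled shape family: ", taxon$shape_family))
  )
  true_bv <- switch(taxon$shape_family,
    needle = ,
    cylinder_with_chloroplasts = cyl_vol,
    disk = 4 / 3 * pi * (len / 2)^3,
    star_colony = ,
    ribbon_colony = ,
    zigzag_colony = n_cells * cyl_vol,
    blob = sum(vapply(prims, function(p) 4 / 3 * pi * p$r^3, numeric(1)))
  )
  list(prims = prims, true_biovolume = true_bv, length = len, width = wid)
}

# Replace a cylinder's outline by 2-3 small chloroplast discs along its
# axis (the frustule-loss rendering).
.fragment_prims <- function(shape) {
  rod <- shape$prims[[1]]
  n <- sample(2:3, 1)
  pos <- sort(runif(n, -0.35, 0.35)) * rod$length
  lapply(pos, function(s) {
    .disc(rod$x0 + s * cos(rod$angle), rod$y0 + s * sin(rod$angle),
          runif(1, 1.2, 1.8))
  })
}

#' Generate one synthetic ROI image
#'
#' Renders one particle (cell or colony) of the given taxon on a noisy
#' background and returns the image together with its ground-truth class
#' and the analytic biovolume of the generative solid. For taxa with a
#' positive frustule-loss probability, the rendered object may be only a
#' few small chloroplast discs while the true biovolume remains that of
#' the full cell -- the imaging artifact the small-object filter exists
#' for.
#'
#' @param taxon A [taxon_model()].
#' @param pixel_scale um per px.
#' @param noise_sd Background Gaussian noise sd (intensity units).
#' @param margin_px Background margin around the shape, px.
#' @param frustule_loss Override the taxon's frustule-loss probability
#'   (e.g. after a flash-lamp step); `NULL` uses the taxon's value.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `image` (matrix in `[0, 1]`), `true_class`,
#'   `true_biovolume_um3`, `fragment` (logical), and the sampled
#'   `length_um`/`width_um`.
#' @export
generate_roi <- function(taxon, pixel_scale = 1, noise_sd = 0.03,
                         margin_px = 6, frustule_loss = NULL, seed = NULL) {
  if (!inherits(taxon, "taxon_model")) abort("`taxon` must be a taxon_model.")
  if (pixel_scale <= 0) abort("`pixel_scale` must be positive.")
  if (margin_px < 1) abort("`margin_px` must be >= 1.")
  run <- function() {
    shape <- .sample_shape(taxon)
    p_loss <- frustule_loss %||% taxon$frustule_loss_prob
    fragment <- taxon$shape_family == "cylinder_with_chloroplasts" &&
      runif(1) < p_loss
    prims <- if (fragment) .fragment_prims(shape) else shape$prims

    ext <- vapply(prims, .primitive_extent, numeric(4))
    xr <- range(ext[1:2, ]); yr <- range(ext[3:4, ])
    nc <- max(ceiling(diff(xr) / pixel_scale) + 2 * margin_px, 2 * margin_px)
    nr <- max(ceiling(diff(yr) / pixel_scale) + 2 * margin_px, 2 * margin_px)
    if (nr <= 0 || nc <= 0) abort("Image dimensions must be positive.")
    # pixel-centre coordinates in um, shape centred
    cx <- mean(xr); cy <- mean(yr)
    gx <- matrix((seq_len(nc) - (nc + 1) / 2) * pixel_scale + cx,
                 nr, nc, byrow = TRUE)
    gy <- matrix((seq_len(nr) - (nr + 1) / 2) * pixel_scale + cy, nr, nc)
    inside <- Reduce(`|`, lapply(prims, .primitive_inside, gx = gx, gy = gy))

    img <- matrix(rnorm(nr * nc, 0.12, noise_sd), nr, nc)
    lvl <- if (fragment) 0.72 else 0.55
    img[inside] <- lvl + rnorm(sum(inside), 0, 0.08)
    img <- pmin(pmax(img, 0), 1)
    list(
      image = img, true_class = taxon$name,
      true_biovolume_um3 = shape$true_biovolume,
      fragment = fragment,
      length_um = shape$length, width_um = shape$width
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
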