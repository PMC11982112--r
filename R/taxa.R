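# Taxon models for the synthetic ROI generator.
#
# Each model names a morphotype family, lognormal cell dimensions,
# a colony cell-count distribution, a frustule-loss probability (the
# Urosolenia artifact: only chloroplast blobs render), and a seasonal
# abundance trajectory giving expected images per sample at 2 m.

#' Build a taxon model
#'
#' @param name Class label.
#' @param shape_family One of `star_colony`, `needle`,
#'   `cylinder_with_chloroplasts`, `ribbon_colony`, `zigzag_colony`,
#'   `disk`.
#' @param length_um,width_um Median cell length/width (um) of the
#'   lognormal size distributions (for `disk`, `length_um` is the
#'   diameter and `width_um` is ignored).
#' @param size_spread Lognormal sdlog of the size distributions.
#' @param colony_cells Integer vector of admissible colony cell counts
#'   (sampled uniformly); `1` for solitary taxa.
#' @param frustule_loss_prob Probability in `[0, 1]` that only
#'   chloroplast blobs are rendered instead of the cell outline.
#' @param abundance Function `time -> expected images per sample` (at the
#'   reference 2-m depth); must be non-negative.
#' @return A `taxon_model` object.
#' @export
taxon_model <- function(name, shape_family, length_um, width_um = length_um / 5,
                        size_spread = 0.12,
                        colony_cells = 1L,
                        frustule_loss_prob = 0,
                        abundance = function(time) 5) {
  families <- c(
    "star_colony", "needle", "cylinder_with_chloroplasts",
    "ribbon_colony", "zigzag_colony", "disk", "blob"
  )
  if (!shape_family %in% families) {
    abort(paste0("Unknown `shape_family`: ", shape_family))
  }
  if (length_um <= 0 || width_um <= 0 || size_spread <= 0) {
    abort("Size distribution parameters must be strictly positive.")
  }
  if (frustule_loss_prob < 0 || frustule_loss_prob > 1) {
    abort("`frustule_loss_prob` must be in [0, 1].")
  }
  if (any(colony_cells < 1)) abort("`colony_cells` must be >= 1.")
  structure(
    list(
      name = name, shape_family = shape_family,
      length_um = length_um, width_um = width_um,
      size_spread = size_spread,
      colony_cells = as.integer(colony_cells),
      frustule_loss_prob = frustule_loss_prob,
      abundance = abundance
    ),
    class = "taxon_model"
  )
}

#' @export
print.taxon_model <- function(x, ...) {
  cat("<taxon_model>", x$name, "-", x$shape_family, "\n")
  cat(sprintf("  length %.1f um, width %.1f um, colonies %s, frustule loss %.2f\n",
              x$length_um, x$width_um,
              paste(range(x$colony_cells), collapse = "-"),
              x$frustule_loss_prob))
  invisible(x)
}

# Smooth seasonal trajectory helper: value interpolated over the season
# fraction in [0, 1] through the given knots.
.trajectory <- function(knots) {
  force(knots)
  function(frac) {
    frac <- pmin(pmax(frac, 0), 1)
    x <- seq(0, 1, length.out = length(knots))
    stats::spline(x, knots, xout = frac, method = "natural")$y |>
      pmax(0)
  }
}

#' Default winter diatom community
#'
#' Six morphotypes patterned on the genera that dominate under-ice
#' diatom biovolume in temperate mesotrophic lakes: a star-forming
#' colonial (Asterionella-like), a ribbon-forming colonial
#' (Fragilaria-like), long thin solitary needles (cf. Synedra-like), a
#' zigzag colonial (Tabellaria-like), a delicate cylinder that often
#' images only its chloroplasts (Urosolenia-like), and solitary round
#' cells. Trajectories are expected image counts per 5-mL sample at 2 m
#' as a function of season fraction: early-winter peaks declining
#' towards spring by factors of ~5-10, with a mid-season dip-and-recovery
#' in the needle taxon.
#'
#' @param dip_taxon Optional name of one taxon given a mid-season 30%
#'   dip-and-recovery on top of its base trajectory (`NULL` for none).
#' @return Named list of [taxon_model()] objects.
#' @export
default_taxa <- function(dip_taxon = NULL) {
  taxa <- list(
    taxon_model(
      "Asterionella", "star_colony", length_um = 45, width_um = 3.5,
      colony_cells = 4:7,
      abundance = .trajectory(c(22, 32, 26, 16, 10, 6))
    ),
    taxon_model(
      "Fragilaria", "ribbon_colony", length_um = 30, width_um = 4,
      colony_cells = 3:6,
      abundance = .trajectory(c(24, 18, 13, 8.5, 5.5, 3.5))
    ),
    taxon_model(
      "cf_Synedra", "needle", length_um = 60, width_um = 3,
      abundance = .trajectory(c(28, 21, 10, 16, 8, 5))
    ),
    taxon_model(
      "Tabellaria", "zigzag_colony", length_um = 22, width_um = 5,
      colony_cells = 3:6,
      abundance = .trajectory(c(25, 19, 14, 9.5, 6.5, 4.5))
    ),
    taxon_model(
      "Urosolenia", "cylinder_with_chloroplasts",
      length_um = 30, width_um = 7, frustule_loss_prob = 0.2,
      abundance = .trajectory(c(32, 26, 16, 19, 10, 5))
    ),
    taxon_model(
      "round_diatoms", "disk", length_um = 16,
      abundance = .trajectory(c(22, 18, 14, 9.5, 6, 4.5))
    )
  )
  names(taxa) <- vapply(taxa, `[[`, character(1), "name")
  if (!is.null(dip_taxon)) {
    if (!dip_taxon %in% names(taxa)) abort("Unknown `dip_taxon`.")
    base <- taxa[[dip_taxon]]$abundance
    taxa[[dip_taxon]]$abundance <- function(frac) {
      dip <- 1 - 0.3 * exp(-((frac - 0.5) / 0.08)^2)
      base(frac) * dip
    }
  }
  taxa
}
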