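#' Generate one synthetic tandem-reporter field with ground truth
#'
#' Renders a three-channel fluorescence field emulating cells carrying the
#' tandem mCherry-EGFP-LC3B reporter: nuclei as filled disks with a mild
#' radial intensity falloff, and LC3 vesicles as isotropic 2-D Gaussian
#' spots placed in a cytoplasmic annulus around their parent nucleus.
#' Autophagosomes (class \code{"AP"}) are rendered at full peak in both the
#' red and green channels at the identical position; autolysosomes
#' (\code{"AL"}) at full peak in red but only
#' \code{green_quench_factor} of the peak in green (EGFP quenching).
#' Per-cell vesicle counts are Poisson draws. Optional Poisson shot noise
#' and Gaussian read noise follow the standard fluorescence camera model.
#'
#' Puncta centres keep a minimum separation of \code{3 * punctum_sigma_px}
#' (rejection sampling) so that, with noise off, detected counts are
#' unambiguous against the ground truth (two equal Gaussian spots fuse into
#' a single intensity maximum once their separation drops to 2 sigma).
#'
#' @param params a [sim_field_params()] object.
#' @return list with elements \code{image} (a [field_image()]) and
#'   \code{truth}, a \code{ground_truth} list holding
#'   \code{nuclei_centroids} (0-based (row, col) matrix), \code{puncta}
#'   (data frame with 0-based \code{row}, \code{col} and \code{class}),
#'   and the per-field true counts \code{n_AP}, \code{n_AL}.
#' @examples
#' fld <- generate_field(sim_field_params(n_cells = 4, seed = 1))
#' fld$truth$n_AP + fld$truth$n_AL == nrow(fld$truth$puncta)
#' @export
generate_field <- function(params = sim_field_params()) {
  validate_sim_field_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  h <- params$image_size[1]; w <- params$image_size[2]
  sig <- params$punctum_sigma_px
  annulus <- c(2, 14)  # cytoplasmic shell beyond the nuclear radius, px

  ## --- place nuclei (non-overlapping disks, bounded attempts) -----------
  nuc <- .place_nuclei(params, h, w, annulus_max = annulus[2])

  ## --- place puncta around their parent nucleus -------------------------
  pts <- .place_puncta(params, nuc, h, w, annulus)

  ## --- render ------------------------------------------------------------
  ch_nuc <- matrix(params$background_level, h, w)
  ch_grn <- matrix(params$background_level, h, w)
  ch_red <- matrix(params$background_level, h, w)

  if (nrow(nuc) > 0) {
    for (i in seq_len(nrow(nuc)))
      ch_nuc <- .add_disk(ch_nuc, nuc$row[i], nuc$col[i], nuc$radius[i],
                          params$nucleus_peak_intensity)
  }
  peak_g <- params$punctum_peak_intensity$green
  peak_r <- params$punctum_peak_intensity$red
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      ch_red <- .add_gaussian(ch_red, pts$row[i], pts$col[i], sig, peak_r)
      g_amp <- if (pts$class[i] == "AP") peak_g else
        params$green_quench_factor * peak_g
      ch_grn <- .add_gaussian(ch_grn, pts$row[i], pts$col[i], sig, g_amp)
    }
  }

  ch_nuc <- .apply_noise(ch_nuc, params$noise_model)
  ch_grn <- .apply_noise(ch_grn, params$noise_model)
  ch_red <- .apply_noise(ch_red, params$noise_model)

  truth <- structure(list(
    nuclei_centroids = cbind(row = nuc$row - 1, col = nuc$col - 1),
    puncta = data.frame(row = pts$row - 1, col = pts$col - 1,
                        class = pts$class, stringsAsFactors = FALSE),
    n_AP = sum(pts$class == "AP"),
    n_AL = sum(pts$class == "AL")
  ), class = "ground_truth")

  list(image = field_image(ch_nuc, ch_grn, ch_red,
                           source_id = sprintf("sim_seed%s",
                                               params$seed %||% "NA")),
       truth = truth)
}

# uniform nucleus placement with pairwise non-overlap; margin keeps the
# cytoplasmic annulus (and spot tails) inside the frame
.place_nuclei <- function(params, h, w, annulus_max, max_attempts = 200L) {
  n <- params$n_cells
  rows <- cols <- radii <- numeric(0)
  if (n > 0) {
    for (i in seq_len(n)) {
      r_i <- max(3, stats::rnorm(1, params$nucleus_radius_px[1],
                                 params$nucleus_radius_px[2]))
      margin <- r_i + annulus_max + 3
      if (2 * margin >= min(h, w))
        stop("field too crowded: nucleus does not fit inside the frame",
             call. = FALSE)
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        rr <- stats::runif(1, margin, h - margin)
        cc <- stats::runif(1, margin, w - margin)
        if (length(rows) == 0 ||
            all(sqrt((rows - rr)^2 + (cols - cc)^2) > radii + r_i + 2)) {
          rows <- c(rows, rr); cols <- c(cols, cc); radii <- c(radii, r_i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("field too crowded: could not place all nuclei without overlap",
             call. = FALSE)
    }
  }
  data.frame(row = rows, col = cols, radius = radii)
}

# Poisson counts per cell; spots in an annulus [r + a1, r + a2] around the
# parent nucleus, minimum centre separation 3*sigma (drop after bounded
# attempts so recorded truth always equals what is rendered). Two equal
# Gaussians merge into one maximum at separation <= 2*sigma, so 3*sigma is
# the least separation at which counts stay unambiguous on a pixel grid.
.place_puncta <- function(params, nuc, h, w, annulus, max_attempts = 200L) {
  rows <- cols <- numeric(0); classes <- character(0)
  sep <- 3 * params$punctum_sigma_px
  if (nrow(nuc) > 0) {
    for (i in seq_len(nrow(nuc))) {
      n_ap <- stats::rpois(1, params$puncta_per_cell_AP)
      n_al <- stats::rpois(1, params$puncta_per_cell_AL)
      for (cls in c(rep("AP", n_ap), rep("AL", n_al))) {
        for (a in seq_len(max_attempts)) {
          rad <- stats::runif(1, nuc$radius[i] + annulus[1],
                              nuc$radius[i] + annulus[2])
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- nuc$row[i] + rad * sin(ang)
          cc <- nuc$col[i] + rad * cos(ang)
          ok <- rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            (length(rows) == 0 ||
               all(sqrt((rows - rr)^2 + (cols - cc)^2) >= sep))
          if (ok) {
            rows <- c(rows, rr); cols <- c(cols, cc)
            classes <- c(classes, cls)
            break
          }
        }
      }
    }
  }
  data.frame(row = rows, col = cols, class = classes,
             stringsAsFactors = FALSE)
}

.add_disk <- function(mat, r0, c0, radius, peak) {
  h <- nrow(mat); w <- ncol(mat)
  rs <- max(1, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cs <- max(1, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, `+`)
  inside <- d2 <= radius^2
  # mild parabolic falloff towards the rim keeps a single intensity maximum
  add <- peak * (1 - 0.3 * d2 / radius^2) * inside
  mat[rs, cs] <- mat[rs, cs] + add
  mat
}

.add_gaussian <- function(mat, r0, c0, sigma, peak) {
  if (peak <= 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  ext <- ceiling(4 * sigma)
  rs <- max(1, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, `+`)
  mat[rs, cs] <- mat[rs, cs] + peak * exp(-d2 / (2 * sigma^2))
  mat
}

.apply_noise <- function(mat, noise_model) {
  if (isTRUE(noise_model$poisson_on)) {
    d <- dim(mat)
    mat <- matrix(stats::rpois(length(mat), lambda = mat), d[1], d[2])
  }
  if (noise_model$gaussian_sd > 0)
    mat <- mat + stats::rnorm(length(mat), 0, noise_model$gaussian_sd)
  pmin(pmax(mat, 0), .INT_SCALE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei, %d AP + %d AL puncta\n",
              nrow(x$nuclei_centroids), x$n_AP, x$n_AL))
  invisible(x)
}
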