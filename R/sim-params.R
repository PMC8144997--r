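#' Simulation parameters for a synthetic reporter field
#'
#' Bundles every knob of the synthetic tandem-reporter field generator:
#' geometry of the field and nuclei, expected vesicle loads per cell for the
#' two biological classes, the Gaussian spot model, the EGFP quenching level
#' of autolysosomes, and the camera noise model.
#'
#' Intensities are arbitrary camera units on a 16-bit scale (0-65535).
#' Autophagosomes (AP) carry the full green peak; autolysosomes (AL) carry
#' \code{green_quench_factor} times the green peak, emulating acid quenching
#' of EGFP after lysosomal fusion. For detection-oracle use the quenched
#' green amplitude must stay below the detector's contrast threshold (the
#' default 0.15 x 120 = 18 is well under the default threshold of 40).
#'
#' @param image_size integer length-2, field height and width in pixels
#'   (minimum 64 x 64).
#' @param n_cells number of nuclei to place (>= 0).
#' @param nucleus_radius_px length-2 numeric: mean and sd of the nucleus
#'   radius in pixels.
#' @param puncta_per_cell_AP Poisson mean of autophagosomes per cell.
#' @param puncta_per_cell_AL Poisson mean of autolysosomes per cell.
#' @param punctum_sigma_px isotropic Gaussian spot sigma in pixels.
#' @param punctum_peak_intensity named list with elements \code{green} and
#'   \code{red}: peak amplitude of a vesicle spot in each channel.
#' @param nucleus_peak_intensity peak amplitude of a nucleus disk.
#' @param green_quench_factor fraction in [0, 1] of the green peak retained
#'   by autolysosomes.
#' @param background_level constant background added to all channels.
#' @param noise_model list with \code{poisson_on} (logical; Poisson shot
#'   noise on the signal) and \code{gaussian_sd} (additive read noise sd).
#' @param seed integer seed or NULL; identical seeds give pixel-identical
#'   fields.
#' @return an object of class \code{sim_field_params}.
#' @seealso [generate_field()], [generate_cohort()]
#' @export
sim_field_params <- function(image_size = c(256L, 256L),
                             n_cells = 12L,
                             nucleus_radius_px = c(9, 1),
                             puncta_per_cell_AP = 3,
                             puncta_per_cell_AL = 3,
                             punctum_sigma_px = 2,
                             punctum_peak_intensity = list(green = 120, red = 120),
                             nucleus_peak_intensity = 120,
                             green_quench_factor = 0.15,
                             background_level = 10,
                             noise_model = list(poisson_on = FALSE, gaussian_sd = 0),
                             seed = NULL) {
  p <- list(
    image_size = as.integer(image_size),
    n_cells = as.integer(n_cells),
    nucleus_radius_px = as.numeric(nucleus_radius_px),
    puncta_per_cell_AP = as.numeric(puncta_per_cell_AP),
    puncta_per_cell_AL = as.numeric(puncta_per_cell_AL),
    punctum_sigma_px = as.numeric(punctum_sigma_px),
    punctum_peak_intensity = lapply(punctum_peak_intensity, as.numeric),
    nucleus_peak_intensity = as.numeric(nucleus_peak_intensity),
    green_quench_factor = as.numeric(green_quench_factor),
    background_level = as.numeric(background_level),
    noise_model = list(
      poisson_on = isTRUE(noise_model$poisson_on),
      gaussian_sd = as.numeric(noise_model$gaussian_sd %||% 0)
    ),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "sim_field_params"
  validate_sim_field_params(p)
  p
}

validate_sim_field_params <- function(p) {
  stopifnot(inherits(p, "sim_field_params"))
  if (length(p$image_size) != 2L || any(p$image_size < 64L))
    stop("image_size must be at least 64 x 64 pixels", call. = FALSE)
  if (is.na(p$n_cells) || p$n_cells < 0L)
    stop("n_cells must be >= 0", call. = FALSE)
  if (length(p$nucleus_radius_px) != 2L || p$nucleus_radius_px[1] <= 0 ||
      p$nucleus_radius_px[2] < 0)
    stop("nucleus_radius_px must be (mean > 0, sd >= 0)", call. = FALSE)
  if (p$puncta_per_cell_AP < 0 || p$puncta_per_cell_AL < 0)
    stop("puncta means must be >= 0", call. = FALSE)
  if (p$punctum_sigma_px <= 0)
    stop("punctum_sigma_px must be > 0", call. = FALSE)
  if (!all(c("green", "red") %in% names(p$punctum_peak_intensity)))
    stop("punctum_peak_intensity needs 'green' and 'red' entries", call. = FALSE)
  ints <- c(unlist(p$punctum_peak_intensity), p$nucleus_peak_intensity,
            p$background_level)
  if (any(!is.finite(ints)) || any(ints < 0))
    stop("all intensities must be finite and nonnegative", call. = FALSE)
  if (p$green_quench_factor < 0 || p$green_quench_factor > 1)
    stop("green_quench_factor must lie in [0, 1]", call. = FALSE)
  if (p$noise_model$gaussian_sd < 0)
    stop("gaussian_sd must be >= 0", call. = FALSE)
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
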