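#' Specify a multi-condition cohort of synthetic fields
#'
#' Describes a treatment design (e.g. control, drug, bafilomycin,
#' drug + bafilomycin) as per-condition multipliers on the Poisson means of
#' autophagosome (AP) and autolysosome (AL) puncta per cell. This is how the
#' generator encodes flux biology: a flux-inducing drug raises AL under the
#' drug alone and raises AP when lysosomal fusion is blocked by bafilomycin;
#' a flux-blocking drug raises AP and lowers AL on its own.
#'
#' @param conditions character vector of unique condition labels.
#' @param multipliers named list: for each condition a numeric vector
#'   \code{c(AP = ..., AL = ...)} of strictly positive multipliers applied
#'   to the base Poisson means.
#' @param n_fields fields of view per condition (>= 1).
#' @param timepoint label carried into the sample sheet (e.g. "48h").
#' @param seed integer seed for the whole cohort.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(conditions, multipliers, n_fields = 10L,
                        timepoint = "48h", seed = 1L) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions))
    stop("duplicate condition labels are not allowed", call. = FALSE)
  if (!all(conditions %in% names(multipliers)))
    stop("every condition needs an entry in 'multipliers'", call. = FALSE)
  for (cond in conditions) {
    m <- multipliers[[cond]]
    if (!all(c("AP", "AL") %in% names(m)) || any(m[c("AP", "AL")] <= 0))
      stop(sprintf("multipliers for '%s' must have positive AP and AL entries",
                   cond), call. = FALSE)
  }
  if (n_fields < 1L) stop("n_fields must be >= 1", call. = FALSE)
  structure(list(conditions = conditions,
                 multipliers = multipliers,
                 n_fields = as.integer(n_fields),
                 timepoint = as.character(timepoint),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic fields under a treatment design
#'
#' Applies each condition's AP/AL multipliers to the base field parameters
#' and generates \code{n_fields} seeded fields per condition. Per-field
#' seeds are derived deterministically from the cohort seed, so identical
#' specs reproduce the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @param base a [sim_field_params()] object giving the untreated baseline.
#' @param render if \code{FALSE}, skip image rendering and return ground
#'   truth only (fast path for statistical simulations on true counts).
#' @return list with \code{fields} (list of per-field records:
#'   \code{image} (or NULL), \code{truth}, \code{condition},
#'   \code{timepoint}, \code{field_id}, \code{seed}) and
#'   \code{sample_sheet}, a data frame (file, condition, timepoint, seed)
#'   where \code{file} is the name [write_cohort()] would use.
#' @export
generate_cohort <- function(spec, base = sim_field_params(), render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_sim_field_params(base)
  fields <- list()
  sheet <- NULL
  k <- 0L
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[ci]
    m <- spec$multipliers[[cond]]
    p <- base
    p$puncta_per_cell_AP <- base$puncta_per_cell_AP * m[["AP"]]
    p$puncta_per_cell_AL <- base$puncta_per_cell_AL * m[["AL"]]
    for (fi in seq_len(spec$n_fields)) {
      k <- k + 1L
      p$seed <- (spec$seed %% 10000L) * 100000L + k
      field_id <- sprintf("%s_%s_f%02d", cond, spec$timepoint, fi)
      if (render) {
        fld <- generate_field(p)
        img <- fld$image
        img$source_id <- field_id
        truth <- fld$truth
      } else {
        img <- NULL
        truth <- .truth_only(p)
      }
      fields[[k]] <- list(image = img, truth = truth, condition = cond,
                          timepoint = spec$timepoint, field_id = field_id,
                          seed = p$seed)
      sheet <- rbind(sheet, data.frame(
        file = paste0(field_id, ".tif"), condition = cond,
        timepoint = spec$timepoint, seed = p$seed,
        stringsAsFactors = FALSE))
    }
  }
  list(fields = fields, sample_sheet = sheet)
}

# ground truth without pixel rendering; uses the same RNG call sequence as
# generate_field up to placement, so truths agree with the rendered path
.truth_only <- function(params) {
  validate_sim_field_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  h <- params$image_size[1]; w <- params$image_size[2]
  annulus <- c(2, 14)
  nuc <- .place_nuclei(params, h, w, annulus_max = annulus[2])
  pts <- .place_puncta(params, nuc, h, w, annulus)
  structure(list(
    nuclei_centroids = cbind(row = nuc$row - 1, col = nuc$col - 1),
    puncta = data.frame(row = pts$row - 1, col = pts$col - 1,
                        class = pts$class, stringsAsFactors = FALSE),
    n_AP = sum(pts$class == "AP"),
    n_AL = sum(pts$class == "AL")
  ), class = "ground_truth")
}

#' Write a generated cohort to disk
#'
#' Writes one 16-bit three-page TIFF per field (page order nuclei, green,
#' red), one ground-truth JSON per field, and the cohort sample sheet CSV
#' (columns file, condition, timepoint, seed).
#'
#' @param cohort result of [generate_cohort()] with \code{render = TRUE}.
#' @param dir output directory, created if missing.
#' @return the sample sheet path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fld in cohort$fields) {
    if (is.null(fld$image))
      stop("cohort was generated with render = FALSE; no images to write",
           call. = FALSE)
    write_field_tiff(fld$image, file.path(dir, paste0(fld$field_id, ".tif")))
    truth <- fld$truth
    jsonlite::write_json(
      list(channel_order = c("nuclei", "green", "red"),
           nuclei_centroids = as.data.frame(truth$nuclei_centroids),
           puncta = truth$puncta, n_AP = truth$n_AP, n_AL = truth$n_AL),
      file.path(dir, paste0(fld$field_id, "_truth.json")),
      digits = NA, auto_unbox = TRUE)
  }
  sheet_path <- file.path(dir, "sample_sheet.csv")
  utils::write.csv(cohort$sample_sheet, sheet_path, row.names = FALSE)
  invisible(sheet_path)
}

#' True per-cell vesicle counts of a cohort
#'
#' Convenience extractor: per-field ground-truth AP and AL counts divided by
#' the true nucleus count, in the long format the statistics layer consumes.
#'
#' @param cohort result of [generate_cohort()].
#' @return data frame with field_id, condition, timepoint, n_nuclei, n_AP,
#'   n_AL, per_cell_AP, per_cell_AL.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort$fields, function(fld) {
    n_nuc <- nrow(fld$truth$nuclei_centroids)
    data.frame(field_id = fld$field_id, condition = fld$condition,
               timepoint = fld$timepoint, n_nuclei = n_nuc,
               n_AP = fld$truth$n_AP, n_AL = fld$truth$n_AL,
               per_cell_AP = if (n_nuc > 0) fld$truth$n_AP / n_nuc else NA_real_,
               per_cell_AL = if (n_nuc > 0) fld$truth$n_AL / n_nuc else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
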