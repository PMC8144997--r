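#' Quantify one field of view
#'
#' Composes the full per-field measurement: nuclei counting on the nuclear
#' channel, spot detection on the red and green channels, object-based
#' colocalization into autophagosomes (AP, red and green) and autolysosomes
#' (AL, red only), and per-cell normalization (vesicle count divided by
#' nucleus count; vesicles are not assigned to individual cells).
#'
#' Conservation holds by construction: every detected red vesicle is
#' classified exactly once, so \code{n_AP + n_AL == n_red_total}.
#'
#' @param image a [field_image()].
#' @param params a [quant_params()] object.
#' @return object of class \code{field_quantification}: \code{source_id},
#'   \code{n_nuclei}, \code{n_red_total}, \code{n_AP}, \code{n_AL},
#'   \code{n_green_only}, \code{per_cell_AP}, \code{per_cell_AL} (NA with a
#'   \code{"no nuclei"} qc flag when the denominator is zero),
#'   \code{qc_flags}, plus the detections (\code{red}, \code{green}),
#'   nuclei result and the parameter block used.
#' @export
quantify_field <- function(image, params = quant_params()) {
  stopifnot(inherits(image, "field_image"))
  nuc <- count_nuclei(image$channels$nuclei, params)
  red <- detect_puncta(image$channels$red, params)
  green <- detect_puncta(image$channels$green, params)
  cls <- classify_vesicles(red, green, params$coloc_radius_px)
  qc <- nuc$qc_flags
  if (nuc$count >= 1) {
    per_ap <- cls$n_AP / nuc$count
    per_al <- cls$n_AL / nuc$count
  } else {
    per_ap <- per_al <- NA_real_
    if (!"no nuclei" %in% qc) qc <- c(qc, "no nuclei")
  }
  structure(list(source_id = image$source_id,
                 n_nuclei = nuc$count,
                 n_red_total = nrow(red),
                 n_AP = cls$n_AP, n_AL = cls$n_AL,
                 n_green_only = cls$n_green_only,
                 per_cell_AP = per_ap, per_cell_AL = per_al,
                 qc_flags = qc,
                 nuclei = nuc, red = red, green = green,
                 matching = cls$matching, params = params),
            class = "field_quantification")
}

#' @export
print.field_quantification <- function(x, ...) {
  cat(sprintf("<field_quantification> %s\n", x$source_id))
  cat(sprintf("  nuclei: %d | red vesicles: %d (AP %d, AL %d) | green-only: %d\n",
              x$n_nuclei, x$n_red_total, x$n_AP, x$n_AL, x$n_green_only))
  cat(sprintf("  per cell: AP %.3f, AL %.3f%s\n", x$per_cell_AP, x$per_cell_AL,
              if (length(x$qc_flags)) paste0("  [qc: ",
                paste(x$qc_flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.field_quantification <- function(x, ...) {
  data.frame(source_id = x$source_id, n_nuclei = x$n_nuclei,
             n_red_total = x$n_red_total, n_AP = x$n_AP, n_AL = x$n_AL,
             n_green_only = x$n_green_only,
             per_cell_AP = x$per_cell_AP, per_cell_AL = x$per_cell_AL,
             qc_flags = paste(x$qc_flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quantify a batch of fields listed in a sample sheet
#'
#' Processes every row of a sample sheet (columns \code{file},
#' \code{condition}, \code{timepoint}) in sheet order, independent of
#' filesystem listing order. A missing or unreadable image does not abort
#' the batch: the row is recorded in the error log and processing
#' continues.
#'
#' @param sample_sheet data frame or path to a CSV with columns file,
#'   condition, timepoint.
#' @param image_dir directory containing the TIFFs named in \code{file}.
#' @param params a [quant_params()] object.
#' @param channel_order TIFF page order, passed to [read_field_tiff()].
#' @param out_dir optional; when given, results CSV, error log and a params
#'   JSON are written there.
#' @return list with \code{results} (long data frame, one row per
#'   successfully quantified field, with condition and timepoint) and
#'   \code{errors} (data frame file/message).
#' @export
quantify_batch <- function(sample_sheet, image_dir, params = quant_params(),
                           channel_order = c("nuclei", "green", "red"),
                           out_dir = NULL) {
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.csv(sample_sheet, stringsAsFactors = FALSE)
  need <- c("file", "condition", "timepoint")
  if (!all(need %in% names(sample_sheet)))
    stop(sprintf("sample sheet must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  results <- NULL
  errors <- data.frame(file = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[i, ]
    res <- tryCatch({
      img <- read_field_tiff(file.path(image_dir, row$file),
                             channel_order = channel_order)
      fq <- as.data.frame(quantify_field(img, params))
      cbind(fq, condition = row$condition, timepoint = row$timepoint,
            stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(file = row$file,
                                         message = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      results <- rbind(results, res)
    }
  }
  if (is.null(results))
    results <- data.frame(source_id = character(0), n_nuclei = integer(0),
                          n_red_total = integer(0), n_AP = integer(0),
                          n_AL = integer(0), n_green_only = integer(0),
                          per_cell_AP = numeric(0), per_cell_AL = numeric(0),
                          qc_flags = character(0), condition = character(0),
                          timepoint = character(0), stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "field_results.csv"),
                     row.names = FALSE)
    utils::write.csv(errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(params),
                         file.path(out_dir, "quant_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, errors = errors)
}
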