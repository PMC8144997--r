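#' Detection settings for nuclei and vesicle puncta
#'
#' One serializable parameter block shared by the whole quantification
#' stage; it is stored alongside results for provenance.
#'
#' @param nuclei_smooth_sigma Gaussian pre-smoothing sigma (px) before
#'   thresholding the nuclear channel.
#' @param nuclei_min_area minimum nucleus area (px) kept after splitting.
#' @param punctum_sigma expected spot sigma (px); sets the measurement
#'   window and the non-maximum-suppression distance.
#' @param log_sigma scale (px) of the Laplacian-of-Gaussian filter. Kept
#'   below \code{punctum_sigma} on purpose: the finer scale resolves spot
#'   pairs near the generator's minimum separation of 3 spot sigma that a
#'   matched-scale filter would blur into one maximum.
#' @param min_contrast minimum intensity of a spot peak above the local
#'   background (arbitrary units on the 16-bit scale). Quenched EGFP in
#'   autolysosomes must stay below this for red-only vesicles to be scored
#'   correctly.
#' @param min_area,max_area area bounds (px) on detected puncta.
#' @param background_radius radius (px) of the median filter used as the
#'   local background estimate.
#' @param coloc_radius_px maximum centroid distance (px) for a red and a
#'   green punctum to be called the same vesicle (autophagosome).
#' @return an object of class \code{quant_params}.
#' @export
quant_params <- function(nuclei_smooth_sigma = 2,
                         nuclei_min_area = 40,
                         punctum_sigma = 2,
                         log_sigma = 1,
                         min_contrast = 40,
                         min_area = 3,
                         max_area = 400,
                         background_radius = 15,
                         coloc_radius_px = 2) {
  p <- as.list(environment())
  if (p$coloc_radius_px <= 0)
    stop("coloc_radius_px must be > 0", call. = FALSE)
  if (p$min_contrast <= 0) stop("min_contrast must be > 0", call. = FALSE)
  if (p$min_area < 1 || p$max_area < p$min_area)
    stop("need 1 <= min_area <= max_area", call. = FALSE)
  class(p) <- "quant_params"
  p
}

.check_channel <- function(ch, what = "channel") {
  if (!is.matrix(ch) || !is.numeric(ch))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (any(!is.finite(ch)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  if (any(ch < 0))
    stop(sprintf("%s contains negative intensities", what), call. = FALSE)
  invisible(ch)
}

#' Count nuclei in a nuclear-stain channel
#'
#' Standard nuclei segmentation: Gaussian smoothing, global Otsu
#' threshold, hole filling, size filtering, and a distance-transform
#' watershed to split touching nuclei.
#'
#' @param nuclei_channel 2-D numeric matrix of nonnegative intensities.
#' @param params a [quant_params()] object.
#' @return list with \code{count}, \code{centroids} (0-based (row, col)
#'   matrix), \code{mask} (integer label matrix) and \code{qc_flags}
#'   (character; \code{"no nuclei"} when nothing is found or the image is
#'   blank/constant).
#' @export
count_nuclei <- function(nuclei_channel, params = quant_params()) {
  .check_channel(nuclei_channel, "nuclei channel")
  empty <- list(count = 0L,
                centroids = cbind(row = numeric(0), col = numeric(0)),
                mask = matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                qc_flags = "no nuclei")
  rng <- range(nuclei_channel)
  if (diff(rng) == 0) return(empty)

  img <- EBImage::Image(nuclei_channel / max(rng[2], 1))
  sm <- EBImage::gblur(img, sigma = params$nuclei_smooth_sigma)
  thr <- EBImage::otsu(sm, range = range(sm))
  mask <- sm > thr
  mask <- EBImage::fillHull(mask)
  if (sum(mask) == 0) return(empty)

  lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  lab_m <- EBImage::imageData(lab)
  sizes <- tabulate(lab_m[lab_m > 0])
  keep <- which(sizes >= params$nuclei_min_area)
  if (length(keep) == 0) return(empty)

  relab <- matrix(0L, nrow(lab_m), ncol(lab_m))
  cents <- matrix(NA_real_, length(keep), 2,
                  dimnames = list(NULL, c("row", "col")))
  for (j in seq_along(keep)) {
    idx <- which(lab_m == keep[j], arr.ind = TRUE)
    relab[lab_m == keep[j]] <- j
    cents[j, ] <- colMeans(idx) - 1  # 0-based
  }
  ord <- order(cents[, "row"], cents[, "col"])
  list(count = length(keep), centroids = cents[ord, , drop = FALSE],
       mask = relab, qc_flags = character(0))
}

# scale-normalized Laplacian-of-Gaussian kernel; negated so that bright
# blobs of width ~sigma give positive response maxima
.log_kernel <- function(sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  ax <- seq_len(k) - (k + 1) / 2
  d2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  lg <- (d2 - 2 * sigma^2) / sigma^4 * g
  lg <- lg - mean(lg)          # zero response to constant images
  -sigma^2 * lg
}

#' Detect fluorescent puncta in one channel
#'
#' Blob detection tuned for diffraction-limited vesicles: a median-filter
#' local background estimate, a scale-normalized Laplacian-of-Gaussian
#' filter at the expected spot width, local-maximum extraction with
#' non-maximum suppression (minimum peak separation 2 sigma), a contrast
#' gate (peak must exceed the local background by \code{min_contrast}), and
#' an area filter on the half-contrast support of each spot.
#'
#' @param channel 2-D numeric matrix of nonnegative intensities.
#' @param params a [quant_params()] object.
#' @return data frame with 0-based \code{row}, \code{col} (intensity-
#'   weighted centroids), \code{area_px}, \code{mean_intensity}, sorted by
#'   (row, col). Zero rows is a valid result.
#' @export
detect_puncta <- function(channel, params = quant_params()) {
  .check_channel(channel)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0))
  if (diff(range(channel)) == 0) return(empty)
  h <- nrow(channel); w <- ncol(channel)
  sigma <- params$punctum_sigma

  bg <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(channel / .INT_SCALE), size = params$background_radius)) *
    .INT_SCALE
  sub <- pmax(channel - bg, 0)

  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(sub),
                                              .log_kernel(params$log_sigma)))
  # 3x3 local maxima of the LoG response, above the contrast gate
  mx <- .max3x3(resp)
  cand <- which(resp >= mx & sub >= params$min_contrast & resp > 0,
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(resp[cand], decreasing = TRUE), , drop = FALSE]

  # non-maximum suppression: duplicates of one spot sit within ~log_sigma
  # of each other, distinct spots at least 3 sigma apart (minus pixel
  # quantization), so 1.5 sigma separates the two cases
  min_sep <- 1.5 * sigma
  keep_r <- keep_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    rr <- cand[i, 1]; cc <- cand[i, 2]
    if (length(keep_r) == 0 ||
        all((keep_r - rr)^2 + (keep_c - cc)^2 >= (min_sep - 1e-9)^2)) {
      keep_r <- c(keep_r, rr); keep_c <- c(keep_c, cc)
    }
  }

  half <- params$min_contrast / 2
  win <- ceiling(2 * sigma)
  out <- lapply(seq_along(keep_r), function(i) {
    rs <- max(1, keep_r[i] - win):min(h, keep_r[i] + win)
    cs <- max(1, keep_c[i] - win):min(w, keep_c[i] + win)
    patch <- sub[rs, cs, drop = FALSE]
    on <- patch >= half
    area <- sum(on)
    if (area < params$min_area || area > params$max_area) return(NULL)
    wts <- patch * on
    tot <- sum(wts)
    data.frame(row = sum(outer(rs, rep(1, length(cs))) * wts) / tot - 1,
               col = sum(outer(rep(1, length(rs)), cs) * wts) / tot - 1,
               area_px = as.integer(area),
               mean_intensity = mean(patch[on]))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out[order(out$row, out$col), , drop = FALSE]
}

# 3x3 neighbourhood maximum via shifted copies (replicated borders)
.max3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  mx <- matrix(-Inf, h, w)
  for (dr in 0:2) for (dc in 0:2)
    mx <- pmax(mx, pad[(1 + dr):(h + dr), (1 + dc):(w + dc)])
  mx
}

#' Classify vesicles into autophagosomes and autolysosomes
#'
#' Object-based colocalization: red and green puncta are matched one-to-one
#' greedily in ascending order of centroid distance (ties broken by red
#' index, then green index), subject to the distance cap
#' \code{coloc_radius_px}. A matched red punctum is an autophagosome
#' (red AND green); an unmatched red punctum is an autolysosome (red only,
#' EGFP quenched); unmatched green puncta are reported but excluded from
#' the flux classes.
#'
#' @param red,green punctum data frames as returned by [detect_puncta()]
#'   (only \code{row} and \code{col} are used).
#' @param coloc_radius_px maximum matching distance in pixels (> 0).
#' @return list with \code{n_AP}, \code{n_AL}, \code{n_green_only} and
#'   \code{matching}, a data frame (red_idx, green_idx, dist) of matched
#'   pairs (1-based indices into the input data frames).
#' @export
classify_vesicles <- function(red, green, coloc_radius_px = 2) {
  if (coloc_radius_px <= 0)
    stop("coloc_radius_px must be > 0", call. = FALSE)
  nr <- nrow(red); ng <- nrow(green)
  matching <- data.frame(red_idx = integer(0), green_idx = integer(0),
                         dist = numeric(0))
  if (nr > 0 && ng > 0) {
    d <- sqrt(outer(red$row, green$row, `-`)^2 +
                outer(red$col, green$col, `-`)^2)
    idx <- which(d <= coloc_radius_px, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(d[idx], idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      used_r <- logical(nr); used_g <- logical(ng)
      for (i in seq_len(nrow(idx))) {
        ri <- idx[i, 1]; gi <- idx[i, 2]
        if (!used_r[ri] && !used_g[gi]) {
          used_r[ri] <- TRUE; used_g[gi] <- TRUE
          matching <- rbind(matching, data.frame(
            red_idx = ri, green_idx = gi, dist = d[ri, gi]))
        }
      }
    }
  }
  list(n_AP = nrow(matching),
       n_AL = nr - nrow(matching),
       n_green_only = ng - nrow(matching),
       matching = matching)
}
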