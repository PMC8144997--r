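#' Percent tumor-volume change from baseline
#'
#' Signed percent change \code{100 * (followup - baseline) / baseline},
#' computed per fish from day-1 (treatment start) to follow-up volumes.
#' Scale invariant: multiplying both volumes by a positive constant leaves
#' the result unchanged.
#'
#' @param volume_baseline,volume_followup numeric vectors; baseline must be
#'   strictly positive, follow-up nonnegative.
#' @param fish_id optional ids used in error messages.
#' @return numeric vector of percent changes.
#' @export
volume_change <- function(volume_baseline, volume_followup, fish_id = NULL) {
  bad <- !is.finite(volume_baseline) | volume_baseline <= 0
  if (any(bad)) {
    who <- if (!is.null(fish_id)) paste(fish_id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop(sprintf("nonpositive baseline volume for: %s", who), call. = FALSE)
  }
  if (any(!is.finite(volume_followup) | volume_followup < 0))
    stop("follow-up volumes must be finite and >= 0", call. = FALSE)
  100 * (volume_followup - volume_baseline) / volume_baseline
}

#' RECIST-adapted response classification for zebrafish xenografts
#'
#' Applies the volume-based response thresholds: progressive disease (PD)
#' is at least a 20 percent increase in tumor volume, partial response (PR)
#' at least a 30 percent decrease; everything between is stable disease
#' (SD). Boundaries are inclusive ("at least"), so +20 is PD and -30 is
#' PR.
#'
#' @param pct_change numeric vector of finite percent volume changes.
#' @param pd_threshold,pr_threshold classification thresholds in percent.
#' @return ordered factor with levels PR < SD < PD.
#' @export
classify_response <- function(pct_change, pd_threshold = 20,
                              pr_threshold = -30) {
  if (any(!is.finite(pct_change)))
    stop("pct_change must be finite", call. = FALSE)
  cat_chr <- ifelse(pct_change >= pd_threshold, "PD",
                    ifelse(pct_change <= pr_threshold, "PR", "SD"))
  factor(cat_chr, levels = c("PR", "SD", "PD"), ordered = TRUE)
}

#' Per-arm response summary and waterfall ordering
#'
#' Computes percent volume change and response category per fish, per-arm
#' response rates (exact percentages, with rounded display columns), and
#' the waterfall ordering (percent change descending within arm) used for
#' plotting.
#'
#' @param records data frame with columns fish_id, arm, volume_baseline,
#'   volume_followup. Arms without records are dropped with a warning.
#' @return object of class \code{xeno_summary}: \code{calls} (per-fish
#'   table in waterfall order), \code{summary} (per-arm n, pct_PD, pct_SD,
#'   pct_PR and display-rounded counterparts).
#' @export
cohort_summary <- function(records) {
  need <- c("fish_id", "arm", "volume_baseline", "volume_followup")
  if (!all(need %in% names(records)))
    stop(sprintf("records must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (is.factor(records$arm)) {
    present <- table(droplevels(records$arm))
    dropped <- setdiff(levels(records$arm), names(present))
    if (length(dropped))
      warning(sprintf("empty arm(s) excluded: %s",
                      paste(dropped, collapse = ", ")))
    records$arm <- as.character(records$arm)
  }
  if (nrow(records) == 0) {
    warning("no records supplied; empty summary")
    return(structure(list(
      calls = data.frame(fish_id = character(0), arm = character(0),
                         pct_change = numeric(0),
                         category = factor(character(0),
                                           levels = c("PR", "SD", "PD"),
                                           ordered = TRUE)),
      summary = data.frame(arm = character(0), n = integer(0),
                           pct_PD = numeric(0), pct_SD = numeric(0),
                           pct_PR = numeric(0))), class = "xeno_summary"))
  }
  pct <- volume_change(records$volume_baseline, records$volume_followup,
                       records$fish_id)
  calls <- data.frame(fish_id = records$fish_id, arm = records$arm,
                      pct_change = pct,
                      category = classify_response(pct),
                      stringsAsFactors = FALSE)
  # waterfall: within each arm, largest increase first
  calls <- calls[order(calls$arm, -calls$pct_change), ]
  rownames(calls) <- NULL
  arms <- unique(calls$arm)
  summ <- do.call(rbind, lapply(arms, function(a) {
    cc <- calls$category[calls$arm == a]
    n <- length(cc)
    data.frame(arm = a, n = n,
               pct_PD = 100 * sum(cc == "PD") / n,
               pct_SD = 100 * sum(cc == "SD") / n,
               pct_PR = 100 * sum(cc == "PR") / n,
               stringsAsFactors = FALSE)
  }))
  summ$display_PD <- round(summ$pct_PD)
  summ$display_SD <- round(summ$pct_SD)
  summ$display_PR <- round(summ$pct_PR)
  structure(list(calls = calls, summary = summ), class = "xeno_summary")
}

#' @export
print.xeno_summary <- function(x, ...) {
  cat("<xeno_summary>\n")
  if (nrow(x$summary) == 0) { cat("  (empty)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s (n = %d): PD %d%% | SD %d%% | PR %d%%\n",
                s$arm, s$n, s$display_PD, s$display_SD, s$display_PR))
  }
  invisible(x)
}

#' Waterfall plot of per-fish tumor-volume changes
#'
#' One bar per xenograft, sorted by percent change descending within arm,
#' with dashed guide lines at the PD (+20 percent) and PR (-30 percent)
#' thresholds.
#'
#' @param x a \code{xeno_summary}.
#' @param arm optional single arm to plot; default all arms side by side.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.xeno_summary <- function(x, arm = NULL, ...) {
  calls <- x$calls
  if (!is.null(arm)) calls <- calls[calls$arm == arm, ]
  if (nrow(calls) == 0) stop("nothing to plot", call. = FALSE)
  cols <- c(PD = "firebrick", SD = "grey60", PR = "steelblue")
  graphics::barplot(calls$pct_change,
                    col = cols[as.character(calls$category)],
                    border = NA, ylab = "Tumor volume change (%)",
                    names.arg = rep("", nrow(calls)), ...)
  graphics::abline(h = c(20, -30), lty = 2, col = "grey30")
  graphics::abline(h = 0, col = "black")
  graphics::legend("topright", legend = names(cols), fill = cols,
                   border = NA, bty = "n")
  invisible(x)
}
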