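#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Draws threshold-cycle values from the standard exponential-amplification
#' model: \code{Ct = baseline_ct - log2(relative expression) + noise}, so a
#' gene with true log2 fold change \code{f} in a condition has its mean Ct
#' lowered by \code{f} cycles relative to the control condition. Reference
#' genes are constant (fold change 1) in every condition by construction.
#'
#' @param genes character vector of target gene names.
#' @param conditions character vector; the first element is the control
#'   condition unless \code{control_condition} says otherwise.
#' @param true_log2_fold_changes named list: per target gene either a single
#'   number (applied to every non-control condition) or a named vector of
#'   log2 fold changes per condition. Control is always 0.
#' @param ref_genes reference (housekeeping) gene names; truth is fold
#'   change 1 everywhere.
#' @param noise_sd Gaussian noise sd in Ct cycles.
#' @param n_replicates biological replicates (samples) per condition; at
#'   least 2 so downstream tests are possible.
#' @param seed integer seed.
#' @param control_condition control label; defaults to \code{conditions[1]}.
#' @param baseline_ct baseline cycle threshold, a single number or a named
#'   vector per gene (default 25 for targets, 20 for references).
#' @return data frame (sample_id, condition, gene, replicate, ct) of class
#'   \code{ct_table}, with the truth stored in attribute
#'   \code{"true_log2_fc"}.
#' @export
generate_ct_table <- function(genes, conditions, true_log2_fold_changes,
                              ref_genes = c("SDHA", "HPRT"),
                              noise_sd = 0.2, n_replicates = 3L, seed = 1L,
                              control_condition = conditions[1],
                              baseline_ct = NULL) {
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2", call. = FALSE)
  if (!control_condition %in% conditions)
    stop("control_condition must be one of 'conditions'", call. = FALSE)
  if (any(ref_genes %in% names(true_log2_fold_changes)))
    stop("reference genes must have true fold change 1; do not list them in true_log2_fold_changes",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  all_genes <- c(genes, ref_genes)
  base_ct <- stats::setNames(
    ifelse(all_genes %in% ref_genes, 20, 25), all_genes)
  if (!is.null(baseline_ct)) {
    if (is.null(names(baseline_ct))) base_ct[] <- baseline_ct
    else base_ct[names(baseline_ct)] <- baseline_ct
  }
  log2fc <- function(gene, cond) {
    if (cond == control_condition || gene %in% ref_genes) return(0)
    v <- true_log2_fold_changes[[gene]]
    if (is.null(v)) return(0)
    if (is.null(names(v))) v[1] else if (cond %in% names(v)) v[[cond]] else 0
  }
  rows <- expand.grid(replicate = seq_len(n_replicates), gene = all_genes,
                      condition = conditions, stringsAsFactors = FALSE)
  ct <- mapply(function(g, cond) base_ct[[g]] - log2fc(g, cond),
               rows$gene, rows$condition) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  out <- data.frame(
    sample_id = sprintf("%s_s%d", rows$condition, rows$replicate),
    condition = rows$condition, gene = rows$gene,
    replicate = 1L,  # one technical measurement per biological sample
    ct = ct, stringsAsFactors = FALSE)
  attr(out, "true_log2_fc") <- true_log2_fold_changes
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Generate a synthetic zebrafish xenograft cohort
#'
#' Draws per-fish baseline tumor volumes and percent volume changes per
#' treatment arm, producing the baseline/follow-up table the response
#' classifier consumes. Percent changes are Gaussian per arm and truncated
#' at -100 (a tumor cannot shrink below zero volume).
#'
#' @param arms data frame (or list of lists) with columns/fields
#'   \code{label}, \code{n_fish}, \code{mean_pct_change}, \code{sd}.
#' @param seed integer seed.
#' @param baseline_range uniform range of baseline volumes (arbitrary
#'   volume units, strictly positive).
#' @return data frame (fish_id, arm, volume_baseline, volume_followup)
#'   with the drawn percent change in attribute \code{"true_pct_change"}.
#' @export
generate_xeno_cohort <- function(arms, seed = 1L,
                                 baseline_range = c(8e4, 1.2e5)) {
  if (!is.data.frame(arms)) arms <- do.call(rbind, lapply(arms, as.data.frame))
  stopifnot(all(c("label", "n_fish", "mean_pct_change", "sd") %in% names(arms)))
  if (any(arms$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(arms$n_fish < 1)) stop("n_fish must be >= 1 per arm", call. = FALSE)
  if (any(baseline_range <= 0)) stop("baseline volumes must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  out <- NULL
  for (i in seq_len(nrow(arms))) {
    n <- arms$n_fish[i]
    base <- stats::runif(n, baseline_range[1], baseline_range[2])
    pct <- pmax(stats::rnorm(n, arms$mean_pct_change[i], arms$sd[i]), -100)
    out <- rbind(out, data.frame(
      fish_id = sprintf("%s_fish%02d", arms$label[i], seq_len(n)),
      arm = arms$label[i],
      volume_baseline = base,
      volume_followup = base * (1 + pct / 100),
      true_pct_change = pct,
      stringsAsFactors = FALSE))
  }
  truth <- out$true_pct_change
  out$true_pct_change <- NULL
  attr(out, "true_pct_change") <- truth
  out
}
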