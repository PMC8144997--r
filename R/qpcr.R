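#' Relative expression by the 2^-ddCt method with dual reference genes
#'
#' Classical comparative-Ct quantification. Technical replicates are
#' averaged at the Ct level; per sample,
#' \code{dCt = mean Ct(target) - mean Ct(reference genes)} (the arithmetic
#' mean over the reference genes' Ct equals the geometric mean of their
#' expression); per condition, \code{ddCt = mean dCt(condition) - mean
#' dCt(control)} and \code{fold change = 2^-ddCt}. The control condition
#' therefore has fold change 1 by construction, and adding any constant to
#' all Ct values of a sample cancels out.
#'
#' A target with missing Ct, or Ct above \code{ct_cutoff}, in a sample is
#' treated as not detectable there; if no control sample detects it the
#' gene is flagged not detectable for the whole analysis rather than
#' raising an error. A missing reference gene is a hard error.
#'
#' @param table long-format data frame (sample_id, condition, gene,
#'   replicate, ct), e.g. from [generate_ct_table()] or read from CSV.
#' @param target_genes genes to quantify; default all non-reference genes.
#' @param ref_genes reference gene names (default SDHA and HPRT, the
#'   neuroblastoma housekeeping pair).
#' @param control_condition label of the untreated/control condition.
#' @param ct_cutoff Ct above which a measurement counts as not detectable
#'   (default 40 cycles).
#' @return data frame of class \code{ddct_result}: gene, condition,
#'   delta_ct (condition mean), delta_delta_ct, fold_change
#'   (= 2^-delta_delta_ct exactly), n_samples, detectable. Per-sample fold
#'   changes are kept in attribute \code{"per_sample"}.
#' @export
delta_delta_ct <- function(table, target_genes = NULL,
                           ref_genes = c("SDHA", "HPRT"),
                           control_condition, ct_cutoff = 40) {
  names(table) <- tolower(names(table))
  need <- c("sample_id", "condition", "gene", "ct")
  if (!all(need %in% names(table)))
    stop(sprintf("Ct table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (!control_condition %in% table$condition)
    stop(sprintf("control condition '%s' absent from table", control_condition),
         call. = FALSE)
  if (is.null(target_genes))
    target_genes <- setdiff(unique(table$gene), ref_genes)

  # technical replicates -> one Ct per (sample, gene); NA if undetectable
  agg <- stats::aggregate(ct ~ sample_id + condition + gene, data = table,
                          FUN = mean, na.action = stats::na.pass)
  agg$ct[!is.finite(agg$ct) | agg$ct > ct_cutoff] <- NA_real_

  samples <- unique(agg[, c("sample_id", "condition")])
  ref_ct <- vapply(samples$sample_id, function(s) {
    cts <- agg$ct[agg$sample_id == s & agg$gene %in% ref_genes]
    if (length(cts) < length(ref_genes) || any(is.na(cts)))
      stop(sprintf("reference gene(s) missing or undetectable in sample '%s'", s),
           call. = FALSE)
    mean(cts)
  }, numeric(1))
  names(ref_ct) <- samples$sample_id

  out <- NULL
  per_sample <- NULL
  for (g in target_genes) {
    gct <- agg[agg$gene == g, ]
    dct <- stats::setNames(gct$ct - ref_ct[gct$sample_id], gct$sample_id)
    cond <- stats::setNames(gct$condition, gct$sample_id)
    ctrl_dct <- dct[cond == control_condition]
    detectable <- any(!is.na(ctrl_dct))
    conds <- unique(c(control_condition,
                      setdiff(unique(cond), control_condition)))
    for (cd in conds) {
      d <- dct[cond == cd & !is.na(dct)]
      if (!detectable || length(d) == 0) {
        out <- rbind(out, data.frame(
          gene = g, condition = cd, delta_ct = NA_real_,
          delta_delta_ct = NA_real_, fold_change = NA_real_,
          n_samples = length(d), detectable = FALSE,
          stringsAsFactors = FALSE))
        next
      }
      ddct_s <- d - mean(ctrl_dct, na.rm = TRUE)
      ddct <- mean(ddct_s)
      out <- rbind(out, data.frame(
        gene = g, condition = cd, delta_ct = mean(d),
        delta_delta_ct = ddct, fold_change = 2^(-ddct),
        n_samples = length(d), detectable = TRUE,
        stringsAsFactors = FALSE))
      per_sample <- rbind(per_sample, data.frame(
        gene = g, condition = cd, sample_id = names(d),
        delta_ct = unname(d), delta_delta_ct = unname(ddct_s),
        fold_change = 2^(-unname(ddct_s)), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  attr(out, "control_condition") <- control_condition
  attr(out, "ref_genes") <- ref_genes
  class(out) <- c("ddct_result", "data.frame")
  out
}

#' Fold-change report across independent experiments
#'
#' Aggregates per-experiment fold changes into a per-gene/condition report:
#' geometric mean fold change, dispersion on the log2 scale, and a
#' two-sided one-sample t-test against a fold change of 1 (computed on the
#' log scale via [one_sample_fc_test()]). With a single experiment the fold
#' change is reported but the p-value is omitted with a flag.
#'
#' @param fc_table data frame with columns gene, condition, fold_change and
#'   one row per independent experiment (plus any id columns, ignored).
#' @return data frame: gene, condition, n, fold_change (geometric mean),
#'   log2_sd, statistic, p_value, flag.
#' @export
fc_report <- function(fc_table) {
  need <- c("gene", "condition", "fold_change")
  if (!all(need %in% names(fc_table)))
    stop(sprintf("fc_table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  keys <- unique(fc_table[, c("gene", "condition")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    fc <- fc_table$fold_change[fc_table$gene == keys$gene[i] &
                                 fc_table$condition == keys$condition[i]]
    fc <- fc[is.finite(fc)]
    n <- length(fc)
    if (n == 0) next
    gm <- exp(mean(log(fc)))
    l2sd <- if (n >= 2) stats::sd(log2(fc)) else NA_real_
    if (n >= 2) {
      tt <- one_sample_fc_test(fc, null_value = 1)
      stat <- tt$statistic; p <- tt$p_value; flag <- ""
    } else {
      stat <- NA_real_; p <- NA_real_; flag <- "n_lt_2"
    }
    out <- rbind(out, data.frame(
      gene = keys$gene[i], condition = keys$condition[i], n = n,
      fold_change = gm, log2_sd = l2sd, statistic = stat, p_value = p,
      flag = flag, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
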