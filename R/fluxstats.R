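#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fits a one-way ANOVA across the supplied groups and computes all
#' pairwise Tukey honest-significant-difference comparisons at the given
#' family-wise level, the design used throughout for per-cell vesicle
#' counts across treatment conditions.
#'
#' @param groups named list of numeric vectors, one per condition; at least
#'   two groups with at least two observations each and nonzero pooled
#'   variance.
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame of class \code{flux_comparisons}. The first row is
#'   the omnibus ANOVA (\code{statistic} = F); subsequent rows are Tukey
#'   pairs with \code{estimate} = mean(group2) - mean(group1), adjusted
#'   \code{p_value}, and the simultaneous confidence bounds \code{lwr},
#'   \code{upr}.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) stop("supply a named list of numeric vectors",
                                  call. = FALSE)
  if (length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  if (any(grepl("-", names(groups), fixed = TRUE)))
    stop("group labels must not contain '-'", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("non-finite observations", call. = FALSE)
  cond <- factor(rep(names(groups), sizes), levels = names(groups))
  within_ss <- sum((vals - stats::ave(vals, cond))^2)
  if (within_ss <= 0)
    stop("degenerate input: zero pooled within-group variance", call. = FALSE)

  fit <- stats::aov(vals ~ cond)
  tab <- summary(fit)[[1]]
  out <- data.frame(test = "anova", group1 = NA_character_,
                    group2 = NA_character_, estimate = NA_real_,
                    statistic = tab[1, "F value"],
                    p_value = tab[1, "Pr(>F)"],
                    lwr = NA_real_, upr = NA_real_,
                    stringsAsFactors = FALSE)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cond
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- rbind(out, data.frame(
    test = "tukey",
    group1 = vapply(pairs, `[`, character(1), 2),
    group2 = vapply(pairs, `[`, character(1), 1),
    estimate = tk[, "diff"], statistic = NA_real_,
    p_value = pmin(pmax(tk[, "p adj"], 0), 1),
    lwr = tk[, "lwr"], upr = tk[, "upr"],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("flux_comparisons", "data.frame")
  out
}

#' One-sample t-test of fold changes against a null ratio
#'
#' Tests whether fold changes differ from a null value (default 1) with a
#' two-sided one-sample t-test on the log scale, the appropriate scale for
#' ratio data: symmetric up/down changes (e.g. 0.5 and 2) cancel exactly.
#'
#' @param fold_changes numeric vector of positive ratios, n >= 2.
#' @param null_value null ratio (default 1).
#' @return one-row data frame: test, estimate (geometric mean fold change),
#'   statistic (t), df, p_value.
#' @export
one_sample_fc_test <- function(fold_changes, null_value = 1) {
  if (length(fold_changes) < 2)
    stop("need at least 2 fold changes", call. = FALSE)
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    stop("fold changes must be finite and > 0", call. = FALSE)
  x <- log(fold_changes)
  mu <- log(null_value)
  if (stats::sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), mu))) {
      tt <- list(statistic = 0, parameter = length(x) - 1, p.value = 1)
    } else {
      stop("degenerate input: constant fold changes different from the null",
           call. = FALSE)
    }
  } else {
    ht <- stats::t.test(x, mu = mu, alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  data.frame(test = "one_sample_t", estimate = exp(mean(x)),
             statistic = tt$statistic, df = tt$parameter,
             p_value = tt$p.value, stringsAsFactors = FALSE)
}

#' Interpret autophagic flux from a four-condition design
#'
#' Implements the tandem-reporter decision logic for a
#' control / drug / bafilomycin / drug + bafilomycin design on per-cell
#' vesicle counts (fields of view are the replication unit):
#' \itemize{
#'   \item \strong{flux induced}: the drug alone significantly increases
#'     autolysosomes per cell versus control (more material reaching the
#'     lysosome), AND drug + bafilomycin significantly increases
#'     autophagosomes per cell versus bafilomycin alone (de novo
#'     autophagosomes pile up when late-stage fusion is blocked).
#'   \item \strong{flux blocked}: the drug alone significantly increases
#'     autophagosomes per cell versus control while autolysosomes are not
#'     significantly increased (vesicles accumulate before fusion).
#'   \item otherwise \strong{indeterminate}.
#' }
#' Significance means Tukey-adjusted p < alpha in the stated direction,
#' taken from one-way ANOVA + Tukey HSD across all four conditions.
#'
#' @param quant_table data frame with columns \code{condition},
#'   \code{per_cell_AP}, \code{per_cell_AL} (e.g. [quantify_batch()]
#'   results or [cohort_truth_table()] output). Rows with NA per-cell
#'   values (qc-excluded fields) are dropped.
#' @param roles named character vector mapping the design roles
#'   \code{control}, \code{drug}, \code{baf}, \code{drug_baf} to condition
#'   labels in \code{quant_table}.
#' @param alpha significance level.
#' @return object of class \code{flux_verdict}: \code{verdict} (one of
#'   \code{"flux_induced"}, \code{"flux_blocked"},
#'   \code{"indeterminate"}), the supporting \code{comparisons} (Tukey
#'   tables for AL and AP), per-condition \code{summaries}, and the rule
#'   evaluations in \code{evidence}.
#' @export
interpret_flux <- function(quant_table,
                           roles = c(control = "control", drug = "drug",
                                     baf = "baf", drug_baf = "drug_baf"),
                           alpha = 0.05) {
  need <- c("control", "drug", "baf", "drug_baf")
  if (!all(need %in% names(roles)))
    stop(sprintf("roles must name: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  tab <- quant_table[!is.na(quant_table$per_cell_AP) &
                       !is.na(quant_table$per_cell_AL), , drop = FALSE]
  for (role in need) {
    if (!roles[[role]] %in% tab$condition)
      stop(sprintf("missing condition '%s' (role: %s)", roles[[role]], role),
           call. = FALSE)
  }
  tab <- tab[tab$condition %in% roles[need], , drop = FALSE]
  # fixed internal ordering makes the verdict invariant to input order
  lev <- unname(roles[need])
  split_by <- function(col) {
    g <- split(tab[[col]], factor(tab$condition, levels = lev))
    g[order(names(g))]
  }
  cmp_al <- anova_tukey(split_by("per_cell_AL"), alpha = alpha)
  cmp_ap <- anova_tukey(split_by("per_cell_AP"), alpha = alpha)

  sig_increase <- function(cmp, from, to) {
    rows <- cmp[cmp$test == "tukey", ]
    hit <- (rows$group1 == from & rows$group2 == to)
    rev <- (rows$group1 == to & rows$group2 == from)
    if (any(hit)) {
      r <- rows[hit, ][1, ]; est <- r$estimate
    } else if (any(rev)) {
      r <- rows[rev, ][1, ]; est <- -r$estimate
    } else stop("contrast not found", call. = FALSE)
    list(significant_up = r$p_value < alpha && est > 0,
         estimate = est, p_value = r$p_value)
  }

  al_drug <- sig_increase(cmp_al, roles[["control"]], roles[["drug"]])
  ap_combo <- sig_increase(cmp_ap, roles[["baf"]], roles[["drug_baf"]])
  ap_drug <- sig_increase(cmp_ap, roles[["control"]], roles[["drug"]])

  verdict <- if (al_drug$significant_up && ap_combo$significant_up) {
    "flux_induced"
  } else if (ap_drug$significant_up && !al_drug$significant_up) {
    "flux_blocked"
  } else "indeterminate"

  agg <- function(col, f) vapply(split(tab[[col]], tab$condition), f, numeric(1))
  summaries <- data.frame(
    condition = sort(unique(tab$condition)),
    n_fields = as.integer(table(tab$condition)[sort(unique(tab$condition))]),
    mean_per_cell_AP = agg("per_cell_AP", mean)[sort(unique(tab$condition))],
    mean_per_cell_AL = agg("per_cell_AL", mean)[sort(unique(tab$condition))],
    sd_per_cell_AP = agg("per_cell_AP", stats::sd)[sort(unique(tab$condition))],
    sd_per_cell_AL = agg("per_cell_AL", stats::sd)[sort(unique(tab$condition))],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(verdict = verdict,
                 comparisons = list(AL = cmp_al, AP = cmp_ap),
                 summaries = summaries,
                 evidence = list(AL_drug_vs_control = al_drug,
                                 AP_drugbaf_vs_baf = ap_combo,
                                 AP_drug_vs_control = ap_drug),
                 roles = roles, alpha = alpha),
            class = "flux_verdict")
}

#' @export
print.flux_verdict <- function(x, ...) {
  cat(sprintf("<flux_verdict> %s (alpha = %g)\n", x$verdict, x$alpha))
  e <- x$evidence
  cat(sprintf("  AL drug vs control:      diff %+.3f, Tukey p = %.4g%s\n",
              e$AL_drug_vs_control$estimate, e$AL_drug_vs_control$p_value,
              if (e$AL_drug_vs_control$significant_up) " *up*" else ""))
  cat(sprintf("  AP drug+baf vs baf:      diff %+.3f, Tukey p = %.4g%s\n",
              e$AP_drugbaf_vs_baf$estimate, e$AP_drugbaf_vs_baf$p_value,
              if (e$AP_drugbaf_vs_baf$significant_up) " *up*" else ""))
  cat(sprintf("  AP drug vs control:      diff %+.3f, Tukey p = %.4g%s\n",
              e$AP_drug_vs_control$estimate, e$AP_drug_vs_control$p_value,
              if (e$AP_drug_vs_control$significant_up) " *up*" else ""))
  invisible(x)
}
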