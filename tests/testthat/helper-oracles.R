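# Shared fixtures and independent oracles, built in code at test time.

# quiet camera settings used when the tests need exact ground-truth recovery
oracle_params <- function(seed, n_cells = 6, ...) {
  sim_field_params(n_cells = n_cells, seed = seed,
                   noise_model = list(poisson_on = FALSE, gaussian_sd = 0),
                   ...)
}

moderate_noise <- list(poisson_on = TRUE, gaussian_sd = 6)  # 5% of peak 120

# greedy-free F1 between detected and true spot lists (0-based coords both)
spot_f1_counts <- function(det, tru, tol = 3) {
  if (nrow(det) == 0 || nrow(tru) == 0)
    return(c(tp = 0, fp = nrow(det), fn = nrow(tru)))
  d <- sqrt(outer(det$row, tru$row, `-`)^2 + outer(det$col, tru$col, `-`)^2)
  used <- logical(nrow(tru)); tp <- 0
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= tol && !used[j]) {
      used[j] <- TRUE; tp <- tp + 1
    }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(tru) - tp)
}

f1_score <- function(cnt) unname(2 * cnt["tp"] / (2 * cnt["tp"] + cnt["fp"] + cnt["fn"]))

# split a field_quantification into detected-AP / detected-AL red spot lists
detected_by_class <- function(fq) {
  ap_idx <- fq$matching$red_idx
  list(AP = fq$red[ap_idx, , drop = FALSE],
       AL = fq$red[setdiff(seq_len(nrow(fq$red)), ap_idx), , drop = FALSE])
}

# brute-force assignment oracle: over all one-to-one matchings within the
# radius, maximum cardinality first, then minimum total distance
brute_force_matching <- function(red, green, radius) {
  nr <- nrow(red); ng <- nrow(green)
  d <- sqrt(outer(red$row, green$row, `-`)^2 + outer(red$col, green$col, `-`)^2)
  best <- list(size = -1, total = Inf, pairs = NULL)
  recurse <- function(ri, used_g, pairs, total) {
    if (ri > nr) {
      size <- nrow(pairs)
      if (size > best$size || (size == best$size && total < best$total))
        best <<- list(size = size, total = total, pairs = pairs)
      return(invisible())
    }
    recurse(ri + 1, used_g, pairs, total)  # leave red ri unmatched
    for (gi in seq_len(ng)) {
      if (!used_g[gi] && d[ri, gi] <= radius) {
        used_g[gi] <- TRUE
        recurse(ri + 1, used_g,
                rbind(pairs, data.frame(red_idx = ri, green_idx = gi)),
                total + d[ri, gi])
        used_g[gi] <- FALSE
      }
    }
  }
  recurse(1, logical(ng),
          data.frame(red_idx = integer(0), green_idx = integer(0)), 0)
  best
}

# textbook one-way ANOVA + Tukey HSD evaluated from first principles
hand_anova_tukey <- function(groups, conf = 0.95) {
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  n <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1; df_w <- n - k
  f <- (ss_b / df_b) / (ss_w / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  mse <- ss_w / df_w
  pairs <- utils::combn(names(groups), 2)
  tuk <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(diff) / se
    padj <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    crit <- stats::qtukey(conf, k, df_w) * se
    c(diff = unname(diff), lwr = unname(diff - crit),
      upr = unname(diff + crit), p = unname(padj))
  })
  colnames(tuk) <- paste(pairs[2, ], pairs[1, ], sep = "-")
  list(F = f, p = p, tukey = t(tuk))
}

# four-condition multiplier designs used across the flux tests
flux_induced_design <- list(control = c(AP = 1, AL = 1),
                            drug = c(AP = 0.5, AL = 3),
                            baf = c(AP = 3, AL = 0.3),
                            drug_baf = c(AP = 9, AL = 0.3))
flux_blocked_design <- list(control = c(AP = 1, AL = 1),
                            drug = c(AP = 3, AL = 0.3),
                            baf = c(AP = 3, AL = 0.3),
                            drug_baf = c(AP = 3, AL = 0.3))
null_design <- list(control = c(AP = 1, AL = 1), drug = c(AP = 1, AL = 1),
                    baf = c(AP = 1, AL = 1), drug_baf = c(AP = 1, AL = 1))

truth_table_for <- function(design, seed, n_fields = 10, n_cells = 8) {
  spec <- cohort_spec(names(design), design, n_fields = n_fields, seed = seed)
  cohort_truth_table(generate_cohort(spec, sim_field_params(n_cells = n_cells),
                                     render = FALSE))
}
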