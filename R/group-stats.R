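#' One-way ANOVA across gait conditions
#'
#' Standard fixed-effects one-way analysis of variance on a list of
#' per-condition value vectors (participants treated as independent
#' observations per condition), computed via [stats::aov()].
#'
#' @param groups named list of numeric vectors (k >= 2 groups, each with
#'   >= 2 observations).
#' @return list of class `"anova_result"`: `F`, `df_between`, `df_within`,
#'   `p`, `means`, `sds`, `ns`.
#' @examples
#' one_way_anova(list(a = c(6, 8, 4, 5, 3, 4),
#'                    b = c(8, 12, 9, 11, 6, 8),
#'                    c = c(13, 9, 11, 8, 7, 12)))$F
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  res <- list(F = tab[1, "F value"], df_between = tab[1, "Df"],
              df_within = tab[2, "Df"], p = tab[1, "Pr(>F)"],
              means = vapply(groups, base::mean, numeric(1)),
              sds = vapply(groups, sd, numeric(1)),
              ns = lengths(groups),
              ms_within = tab[2, "Mean Sq"])
  class(res) <- "anova_result"
  res
}

check_groups <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 observations")
  v <- vapply(groups, var, numeric(1))
  if (all(v == 0)) stop("degenerate data: zero within-group variance everywhere")
  invisible(names(groups))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ",", x$df_within, ") =",
      signif(x$F, 4), ", p =", signif(x$p, 3), "\n")
  print(data.frame(mean = round(x$means, 3), sd = round(x$sds, 3),
                   n = x$ns))
  invisible(x)
}

#' Tukey HSD post-hoc comparisons
#'
#' Pairwise comparisons after a one-way ANOVA, using the studentized range
#' distribution: \eqn{q_{ij} = |\bar y_i - \bar y_j| /
#' \sqrt{MS_w (1/n_i + 1/n_j)/2}} (Tukey-Kramer for unequal n), with
#' adjusted p-values from [stats::ptukey()] at (k, df_within).
#'
#' @inheritParams one_way_anova
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `"tukey_result"`: `pairs` data.frame (`group1`,
#'   `group2`, `diff`, `q`, `p_adj`, `significant`), plus `means`, `ns`,
#'   `ms_within`, `df_within`, `alpha`, and `letters` (compact letter
#'   display, see [letter_display()]).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  nm <- check_groups(groups)
  names(groups) <- nm
  an <- one_way_anova(groups)
  k <- length(groups)
  cmb <- utils::combn(k, 2)
  pairs <- data.frame(
    group1 = nm[cmb[1, ]], group2 = nm[cmb[2, ]],
    diff = an$means[cmb[2, ]] - an$means[cmb[1, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(an$ms_within * (1 / an$ns[cmb[1, ]] + 1 / an$ns[cmb[2, ]]) / 2)
  pairs$q <- abs(pairs$diff) / se
  pairs$p_adj <- ptukey(pairs$q, k, an$df_within, lower.tail = FALSE)
  pairs$significant <- pairs$p_adj < alpha
  rownames(pairs) <- NULL
  res <- list(pairs = pairs, means = an$means, ns = an$ns,
              ms_within = an$ms_within, df_within = an$df_within,
              alpha = alpha)
  res$letters <- letter_display(res)
  class(res) <- "tukey_result"
  res
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD (alpha =", x$alpha, "):\n")
  p <- x$pairs
  p$p_adj <- signif(p$p_adj, 3); p$q <- signif(p$q, 3)
  p$diff <- signif(p$diff, 3)
  print(p, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns letters to groups so that groups sharing a letter are not
#' significantly different (insertion algorithm): start from one letter
#' covering all groups; for every significant pair split each letter
#' containing both members into two, then absorb redundant letters.
#'
#' @param tukey a [tukey_hsd()] result (or any list with a `pairs`
#'   data.frame carrying `group1`, `group2`, `significant` and a `means`
#'   vector naming the groups).
#' @return named character vector of letter strings, one per group.
#' @export
letter_display <- function(tukey) {
  nm <- names(tukey$means)
  cols <- list(nm)  # each column = set of groups sharing one letter
  sig <- tukey$pairs[tukey$pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    newcols <- list()
    for (cl in cols) {
      if (a %in% cl && b %in% cl) {
        newcols <- c(newcols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else newcols <- c(newcols, list(cl))
    }
    newcols <- newcols[lengths(newcols) > 0L]
    key <- vapply(newcols, function(cl) paste(sort(cl), collapse = "|"),
                  character(1))
    newcols <- newcols[!duplicated(key)]
    # absorb columns that are proper subsets of another column
    keep <- vapply(seq_along(newcols), function(j) {
      !any(vapply(seq_along(newcols), function(l) {
        l != j && length(newcols[[j]]) < length(newcols[[l]]) &&
          all(newcols[[j]] %in% newcols[[l]])
      }, logical(1)))
    }, logical(1))
    cols <- newcols[keep]
  }
  # order letter columns by their earliest group so the first group reads "A"
  cols <- cols[order(vapply(cols, function(cl) min(match(cl, nm)), numeric(1)))]
  letters_out <- setNames(rep("", length(nm)), nm)
  for (j in seq_along(cols)) {
    for (g in cols[[j]])
      letters_out[g] <- paste0(letters_out[g], LETTERS[j])
  }
  letters_out
}

#' Condition comparison report (per limb and metric)
#'
#' Mirrors the standard study summary: for each limb, metric and
#' comparison family — the three symmetric speeds, and symmetric 1.0 m/s
#' versus the two asymmetric conditions — reports per-condition mean (sd),
#' the one-way ANOVA p-value, and Tukey compact letters.
#'
#' @param metrics data.frame with columns `participant`, `limb`,
#'   `condition`, and one column per metric (default metrics:
#'   `mean_peak_vgrf_bw`, `ar_distance`), as produced by
#'   [analyze_study()] or [simulate_study_metrics()].
#' @param families named list of condition-label vectors; defaults to
#'   `symmetric` = sym_0.75/sym_1.0/sym_1.5 and `asymmetric` =
#'   sym_1.0/asym_0.25/asym_0.50 (families not fully covered by `metrics`
#'   are skipped; if no family is complete the error names the missing
#'   conditions).
#' @param metric_cols metric column names to compare.
#' @param alpha significance level for the letters.
#' @return data.frame of class `"condition_comparison"`; attribute
#'   `"detail"` holds the underlying `anova_result`/`tukey_result`
#'   objects.
#' @export
compare_conditions <- function(metrics,
                               families = list(
                                 symmetric = c("sym_0.75", "sym_1.0", "sym_1.5"),
                                 asymmetric = c("sym_1.0", "asym_0.25", "asym_0.50")),
                               metric_cols = c("mean_peak_vgrf_bw", "ar_distance"),
                               alpha = 0.05) {
  stopifnot(all(c("participant", "limb", "condition") %in% names(metrics)))
  metric_cols <- intersect(metric_cols, names(metrics))
  if (!length(metric_cols)) stop("no metric columns found in 'metrics'")
  rows <- list(); detail <- list(); partial <- character()
  for (fam in names(families)) {
    conds <- families[[fam]]
    present <- conds %in% metrics$condition
    if (!all(present)) {
      # a family only partially covered is skipped; remembered for the error
      # message should no family be complete
      if (any(present))
        partial <- c(partial, paste0(fam, " (missing ",
                                     paste(conds[!present], collapse = ", "),
                                     ")"))
      next
    }
    for (lb in unique(metrics$limb)) {
      for (mc in metric_cols) {
        groups <- lapply(conds, function(cn) {
          v <- metrics[[mc]][metrics$limb == lb & metrics$condition == cn]
          v[!is.na(v)]
        })
        names(groups) <- conds
        if (any(lengths(groups) < 2L))
          stop("missing cells for limb ", lb, ", metric ", mc, ", family ",
               fam, ": ", paste(conds[lengths(groups) < 2L], collapse = ", "))
        tk <- tukey_hsd(groups, alpha = alpha)
        an <- one_way_anova(groups)
        cells <- sprintf("%.1f (%.1f)%s", an$means, an$sds,
                         ifelse(tk$letters == "", "",
                                paste0(" ", tk$letters)))
        row <- data.frame(limb = lb, metric = mc, family = fam,
                          stringsAsFactors = FALSE)
        for (ci in seq_along(conds)) row[[conds[ci]]] <- cells[ci]
        row$p_value <- an$p
        rows[[length(rows) + 1L]] <- row
        detail[[paste(lb, mc, fam, sep = ".")]] <-
          list(anova = an, tukey = tk)
      }
    }
  }
  if (!length(rows))
    stop("no comparison family is fully present in 'metrics'",
         if (length(partial)) paste0("; partially present: ",
                                     paste(partial, collapse = "; ")))
  nmall <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nmall, names(r))] <- NA; r[nmall] })
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  attr(out, "note") <- paste(
    "One-way ANOVA treats participants as independent observations per",
    "condition (repeated measures are not modelled).")
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison: per-condition mean (sd) with Tukey letters;",
      "\ngroups not sharing a letter differ at alpha = 0.05.\n\n")
  y <- as.data.frame(x)
  y$p_value <- signif(y$p_value, 2)
  print(y, row.names = FALSE)
  cat("\nNote:", attr(x, "note"), "\n")
  invisible(x)
}
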