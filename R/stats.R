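# Cohort statistics layer: paired t (position volume changes), Welch t
# (fibrosis dichotomy), one-way ANOVA (three-group comparisons), tie-corrected
# Spearman correlation, and the report tables built from subject results.

.stats_result <- function(test_name, n, statistic, dof, p, estimate,
                          ci95 = c(NA_real_, NA_real_), group_ns = NULL) {
  structure(list(test_name = test_name, n = n, group_ns = group_ns,
                 statistic = unname(statistic), dof = unname(dof),
                 p_two_sided = unname(p), estimate = unname(estimate),
                 ci95 = unname(ci95)),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g (dof %s), p = %.4g, estimate %.4g",
              x$test_name, x$statistic,
              paste(signif(x$dof, 4), collapse = ", "),
              x$p_two_sided, x$estimate))
  if (!anyNA(x$ci95)) cat(sprintf(" [95%% CI %.4g, %.4g]", x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Paired t-test on a vector of within-subject differences
#'
#' Used for prone-minus-supine volume deltas: `t = mean / (sd / sqrt(n))`
#' with `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param deltas Numeric vector of paired differences (n >= 2, positive sd).
#' @return A `stats_result` with the mean difference and its 95% CI.
#' @export
paired_t <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  if (n < 2) stop("paired_t: need at least 2 differences")
  if (sd(deltas) == 0)
    stop("paired_t: zero variance in differences; degenerate input")
  tt <- stats::t.test(deltas)
  .stats_result("paired_t", n, tt$statistic, tt$parameter, tt$p.value,
                tt$estimate, as.numeric(tt$conf.int))
}

#' Welch two-sample t-test
#'
#' Independent-groups comparison with unequal variances
#' (Welch-Satterthwaite degrees of freedom); the default for comparing the
#' mild (<30%) and severe (>=30%) fibrosis groups. A pooled-variance Student
#' test is available with `pooled = TRUE`.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2; at least one with
#'   positive variance).
#' @param pooled Use the pooled-variance Student t instead of Welch.
#' @return A `stats_result` with the mean difference (a minus b) and its CI.
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("welch_t: each group needs at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("welch_t: both groups have zero variance; degenerate input")
  tt <- stats::t.test(group_a, group_b, var.equal = pooled)
  .stats_result(if (pooled) "student_t" else "welch_t",
                length(group_a) + length(group_b),
                tt$statistic, tt$parameter, tt$p.value,
                unname(tt$estimate[1] - tt$estimate[2]),
                as.numeric(tt$conf.int),
                group_ns = c(length(group_a), length(group_b)))
}

#' One-way ANOVA across three or more groups
#'
#' Classical F-test with `(k - 1, N - k)` degrees of freedom, used for
#' three-level fibrosis and CT-pattern comparisons of movement maxima.
#'
#' @param groups List of >= 3 numeric vectors, each with n >= 2.
#' @return A `stats_result`; `statistic` is F, `dof` the numerator dof, with
#'   attribute-free denominator dof in `group_ns`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("oneway_anova: need at least 3 groups (use welch_t for 2)")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("oneway_anova: every group needs at least 2 observations")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  if (sd(y) == 0) {
    # identical groups: F = 0 by convention, p = 1
    return(.stats_result("oneway_anova", length(y), 0,
                         c(k - 1, length(y) - k), 1, NA_real_,
                         group_ns = vapply(groups, length, integer(1))))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  .stats_result("oneway_anova", length(y), ow$statistic,
                unname(as.numeric(ow$parameter)), ow$p.value,
                estimate = NA_real_,
                group_ns = vapply(groups, length, integer(1)))
}

#' Tie-corrected Spearman rank correlation
#'
#' Average-rank (tie-corrected) Spearman rho, computed as the Pearson
#' correlation of mid-ranks, with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Missing values are
#' dropped pairwise.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return A `stats_result`; `estimate` is rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("spearman: x and y must be paired")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman: need at least 3 complete pairs")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (is.na(rho)) stop("spearman: constant input; correlation undefined")
  if (abs(rho) >= 1) {
    p <- 0
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  .stats_result("spearman", n, tstat, n - 2, p, rho)
}

#' Grouping rules for cohort comparisons
#'
#' @param kind `"fibrosis_dichotomy_30"` (mild < 30% vs severe >= 30%, the
#'   threshold assignment sending exactly 30% to the severe group),
#'   `"fibrosis_three_level"` (none 0% / mild < 30% / severe >= 30%), or
#'   `"pattern_three_level"` (normal / UIP-or-probable /
#'   indeterminate-or-alternative).
#' @param threshold Dichotomy threshold percent (default 30).
#' @return A list of class `grouping_rule`.
#' @export
grouping_rule <- function(kind = c("fibrosis_dichotomy_30",
                                   "fibrosis_three_level",
                                   "pattern_three_level"),
                          threshold = 30) {
  kind <- match.arg(kind)
  structure(list(kind = kind, threshold = threshold), class = "grouping_rule")
}

#' Assign subjects to groups under a rule
#' @param subjects List of [subject_record()]s.
#' @param rule A [grouping_rule()].
#' @return Character vector of group names, one per subject.
#' @export
apply_grouping <- function(subjects, rule) {
  ext <- vapply(subjects, function(s) s$fibrosis_extent, numeric(1))
  pat <- vapply(subjects, function(s) s$pattern_group, character(1))
  switch(rule$kind,
         fibrosis_dichotomy_30 = ifelse(ext >= rule$threshold, "severe", "mild"),
         fibrosis_three_level = ifelse(ext == 0, "none",
                                       ifelse(ext >= rule$threshold,
                                              "severe", "mild")),
         pattern_three_level = pat)
}

#' Cohort report tables
#'
#' Builds the per-region paired-t summary of volume deltas (mean, SD, 95% CI,
#' p per region), group comparisons of the movement maxima under each
#' grouping rule (group means +- SD with a Welch t or ANOVA p-value), and
#' Spearman correlations of FVC and fibrosis extent against the LLL volume
#' delta and the movement maxima. QC-failed subjects are excluded by default;
#' p-values are reported raw (no multiple-testing correction) unless
#' `holm = TRUE`.
#'
#' @param results List of [analyze_subject()] results.
#' @param subjects List of matching [subject_record()]s (same order).
#' @param rules List of [grouping_rule()]s (default: the 30% dichotomy and
#'   both three-level rules).
#' @param include_failed Keep QC-failed subjects (default `FALSE`).
#' @param holm Apply a Holm correction within each table (default `FALSE`).
#' @return A list of class `cohort_tables`: `volume_table`,
#'   `movement_tables` (one per rule), `correlations`, `n_used`, `n_excluded`.
#' @export
cohort_tables <- function(results, subjects,
                          rules = list(grouping_rule("fibrosis_dichotomy_30"),
                                       grouping_rule("fibrosis_three_level"),
                                       grouping_rule("pattern_three_level")),
                          include_failed = FALSE, holm = FALSE) {
  stopifnot(length(results) == length(subjects))
  ok <- vapply(results, function(r) isTRUE(r$qc$pass), logical(1))
  if (!include_failed) {
    excluded <- sum(!ok)
    results <- results[ok]
    subjects <- subjects[ok]
  } else {
    excluded <- 0L
  }
  if (length(results) < 3) stop("cohort_tables: fewer than 3 usable subjects")
  df <- results_to_df(results)

  # Table of per-region volume deltas (paired t across subjects)
  vol_rows <- lapply(.regions, function(rg) {
    col <- paste0("delta_", rg, "_ml")
    if (!col %in% names(df) || all(is.na(df[[col]]))) return(NULL)
    d <- df[[col]]
    if (sd(d, na.rm = TRUE) == 0) {
      return(data.frame(region = rg, mean_ml = mean(d, na.rm = TRUE), sd_ml = 0,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    r <- paired_t(d)
    data.frame(region = rg, mean_ml = r$estimate, sd_ml = sd(d, na.rm = TRUE),
               ci_lo = r$ci95[1], ci_hi = r$ci95[2], p = r$p_two_sided,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  volume_table <- do.call(rbind, vol_rows)
  if (holm && !is.null(volume_table))
    volume_table$p <- stats::p.adjust(volume_table$p, "holm")

  axes <- c(x = "max_x_cm", y = "max_y_cm", z = "max_z_cm", `3d` = "max_3d_cm")
  movement_tables <- lapply(rules, function(rule) {
    grp <- apply_grouping(subjects, rule)
    lv <- unique(grp)
    rows <- lapply(names(axes), function(ax) {
      v <- df[[axes[[ax]]]]
      by_g <- split(v, grp)
      means <- vapply(by_g, mean, numeric(1))
      sds <- vapply(by_g, sd, numeric(1))
      p <- if (length(by_g) < 2 || any(vapply(by_g, length, integer(1)) < 2)) {
        NA_real_
      } else if (length(by_g) == 2) {
        welch_t(by_g[[1]], by_g[[2]])$p_two_sided
      } else {
        oneway_anova(by_g)$p_two_sided
      }
      row <- data.frame(axis = ax, stringsAsFactors = FALSE)
      for (g in names(by_g)) {
        row[[paste0("mean_", g)]] <- means[[g]]
        row[[paste0("sd_", g)]] <- sds[[g]]
      }
      row$p <- p
      row
    })
    tab <- do.call(rbind, rows)
    if (holm) tab$p <- stats::p.adjust(tab$p, "holm")
    attr(tab, "rule") <- rule$kind
    attr(tab, "group_ns") <- table(grp)
    tab
  })
  names(movement_tables) <- vapply(rules, function(r) r$kind, character(1))

  fvc <- vapply(subjects, function(s) s$fvc_l, numeric(1))
  ext <- vapply(subjects, function(s) s$fibrosis_extent, numeric(1))
  corr_of <- function(xv, yv) {
    ok2 <- !is.na(xv) & !is.na(yv)
    if (sum(ok2) < 3 || sd(xv[ok2]) == 0 || sd(yv[ok2]) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    r <- spearman(xv, yv)
    c(rho = r$estimate, p = r$p_two_sided)
  }
  corr_targets <- c(delta_LLL_ml = "delta_LLL_ml", max_x_cm = "max_x_cm",
                    max_y_cm = "max_y_cm", max_z_cm = "max_z_cm",
                    max_3d_cm = "max_3d_cm")
  correlations <- do.call(rbind, lapply(names(corr_targets), function(nm) {
    col <- corr_targets[[nm]]
    yv <- if (col %in% names(df)) df[[col]] else rep(NA_real_, nrow(df))
    f <- corr_of(fvc, yv)
    e <- corr_of(ext, yv)
    data.frame(target = nm, rho_fvc = f["rho"], p_fvc = f["p"],
               rho_fibrosis = e["rho"], p_fibrosis = e["p"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  structure(list(volume_table = volume_table,
                 movement_tables = movement_tables,
                 correlations = correlations,
                 n_used = length(results), n_excluded = excluded),
            class = "cohort_tables")
}
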