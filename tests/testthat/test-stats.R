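# Textbook-formula oracles, written independently of the implementations.

oracle_paired_t <- function(d) {
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, dof = n - 1, p = 2 * pt(-abs(t), n - 1),
       ci = m + c(-1, 1) * qt(0.975, n - 1) * s / sqrt(n))
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

oracle_anova <- function(groups) {
  y <- unlist(groups)
  N <- length(y); k <- length(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# brute-force mid-ranks: for each element, count smaller + half the ties
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("paired t matches the textbook formula and handles its edge cases", {
  r <- paired_t(c(1, -1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1)

  r2 <- paired_t(c(2, 0, 2, 0))
  expect_equal(r2$statistic, 1 / (sd(c(2, 0, 2, 0)) / 2), tolerance = 1e-12)
  expect_equal(r2$statistic, 1.732051, tolerance = 1e-6)
  expect_equal(r2$dof, 3)

  expect_error(paired_t(c(5, 5, 5)), "degenerate")
  expect_error(paired_t(5), "at least 2")

  set.seed(101)
  for (i in 1:100) {
    d <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 5))
    if (sd(d) == 0) next
    o <- oracle_paired_t(d)
    r <- paired_t(d)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$dof, o$dof)
    expect_equal(r$p_two_sided, o$p, tolerance = 1e-10)
    expect_equal(r$ci95, o$ci, tolerance = 1e-10)
  }
})

test_that("welch t matches the Welch-Satterthwaite formulas", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")

  o <- oracle_welch(c(0, 0, 1, 1), c(10, 10, 11, 11))
  r <- welch_t(c(0, 0, 1, 1), c(10, 10, 11, 11))
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$dof, o$dof, tolerance = 1e-12)

  set.seed(202)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 4))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 4))
    o <- oracle_welch(a, b)
    r <- welch_t(a, b)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$dof, o$dof, tolerance = 1e-10)
    expect_equal(r$p_two_sided, o$p, tolerance = 1e-10)
    expect_equal(r$estimate, mean(a) - mean(b), tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  groups <- list(c(1, 2, 3), c(1, 2, 3), c(101, 102, 103))
  o <- oracle_anova(groups)
  r <- oneway_anova(groups)
  expect_equal(r$statistic, o$F, tolerance = 1e-10)
  expect_equal(r$dof, c(o$df1, o$df2))
  expect_equal(r$p_two_sided, o$p, tolerance = 1e-10)

  ident <- oneway_anova(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_two_sided, 1)

  expect_error(oneway_anova(list(1:3, 4:6)), "welch_t")

  set.seed(303)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:15, 1), mean = runif(1, -1, 1)))
    o <- oracle_anova(groups)
    r <- oneway_anova(groups)
    expect_equal(r$statistic, o$F, tolerance = 1e-10)
    expect_equal(r$p_two_sided, o$p, tolerance = 1e-10)
  }
})

test_that("spearman uses tie-corrected mid-ranks with the t approximation", {
  up <- spearman(1:10, (1:10)^3)
  expect_equal(up$estimate, 1)
  down <- spearman(1:10, -(1:10)^2)
  expect_equal(down$estimate, -1)

  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman(x, y)$estimate, oracle_spearman_rho(x, y),
               tolerance = 1e-12)

  set.seed(404)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # plenty of ties
    y <- x + rnorm(n, sd = 2)
    rho <- oracle_spearman_rho(x, y)
    r <- spearman(x, y)
    expect_equal(r$estimate, rho, tolerance = 1e-10)
    if (abs(rho) < 1) {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      expect_equal(r$p_two_sided, 2 * pt(-abs(t), n - 2), tolerance = 1e-10)
    }
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(505)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman(x, y)$estimate
  expect_equal(spearman(exp(x), y)$estimate, base, tolerance = 1e-12)
  expect_equal(spearman(x, y^3 + 5 * y)$estimate, base, tolerance = 1e-12)
  # missing values are dropped pairwise
  x2 <- c(x, NA); y2 <- c(y, 4)
  expect_equal(spearman(x2, y2)$estimate, base, tolerance = 1e-12)
})

test_that("the 30% fibrosis dichotomy sends the boundary to the severe group", {
  subs <- lapply(c(10, 20, 30, 40), function(e)
    subject_record(paste0("S", e), e, "normal", 3))
  grp <- apply_grouping(subs, grouping_rule("fibrosis_dichotomy_30"))
  expect_equal(grp, c("mild", "mild", "severe", "severe"))
  g3 <- apply_grouping(list(subject_record("a", 0, "normal"),
                            subject_record("b", 20, "normal"),
                            subject_record("c", 30, "normal")),
                       grouping_rule("fibrosis_three_level"))
  expect_equal(g3, c("none", "mild", "severe"))
})

test_that("cohort tables assemble the volume, movement and correlation reports", {
  # light-weight synthetic subject results (no imaging required)
  set.seed(99)
  n <- 16
  amp <- runif(n, 5, 25)
  ext <- sample(seq(0, 60, 10), n, replace = TRUE)
  mk_res <- function(i) {
    vr <- data.frame(region = c("whole", "right", "left", "RUL", "RML", "RLL",
                                "LUL", "LLL"),
                     supine_ml = 1000, prone_ml = 1000,
                     delta_ml = c(80, 30, 50, -10, -20, 60, -10, 60) +
                       rnorm(8, sd = 15))
    structure(list(subject_id = paste0("S", i),
                   qc = list(pass = i != 1, reasons = if (i == 1)
                     "registration_failure: whole-lung Dice 0.500 < 0.80"
                     else character(0)),
                   volume_report = vr,
                   movement = list(max_abs_x_cm = amp[i] / 20,
                                   max_abs_y_cm = amp[i] / 15,
                                   max_abs_z_cm = amp[i] / 18,
                                   max_3d_cm = amp[i] / 10),
                   dice_whole = 0.97, dice_right = 0.97, dice_left = 0.97),
              class = "subject_result")
  }
  results <- lapply(seq_len(n), mk_res)
  subjects <- lapply(seq_len(n), function(i)
    subject_record(paste0("S", i), ext[i],
                   if (ext[i] >= 30) "UIP_or_probable" else "normal",
                   fvc_l = 1.5 + 0.08 * amp[i]))
  tb <- cohort_tables(results, subjects)
  expect_equal(tb$n_used, n - 1)       # QC-failed subject excluded
  expect_equal(tb$n_excluded, 1)
  expect_equal(nrow(tb$volume_table), 8)
  expect_named(tb$movement_tables,
               c("fibrosis_dichotomy_30", "fibrosis_three_level",
                 "pattern_three_level"))
  # FVC was built as an increasing function of movement: rho must be 1
  r3d <- tb$correlations[tb$correlations$target == "max_3d_cm", ]
  expect_equal(r3d$rho_fvc, 1, tolerance = 1e-9)
})
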