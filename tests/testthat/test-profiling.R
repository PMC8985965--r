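test_that("profile labeling keeps items at or above the threshold in
           descending order", {
  fit <- structure(list(
    k = 2, n = 10, j = 4,
    params = list(prop = c(0.6, 0.4),
                  rho = matrix(c(0.835, 0.400, 0.299, 0.05,
                                 0.30, 0.10, 0.20, 0.25), ncol = 2,
                               dimnames = list(c("r02c05", "r05c06",
                                                 "r19c05", "r20c05"),
                                               NULL))),
    assignment = rep(c(1, 2), each = 5),
    item_names = c("r02c05", "r05c06", "r19c05", "r20c05")
  ), class = "lca_fit")
  lab <- label_profiles(fit)
  c1 <- dplyr::filter(lab, class == 1)
  expect_equal(c1$item, c("r02c05", "r05c06"))      # 0.299 excluded
  expect_equal(c1$probability, c(0.835, 0.400))
  expect_equal(unique(c1$prevalence), 0.5)
  # boundary inclusive: exactly 0.30 is retained
  c2 <- dplyr::filter(lab, class == 2)
  expect_equal(c2$item, "r02c05")
  expect_equal(c2$probability, 0.30)
  # Barell names are joined on for cell-id items
  expect_equal(c1$nature_name, c("Internal organ", "Open wounds"))

  # all-subthreshold class yields an empty defining set with a warning
  fit$params$rho[, 2] <- 0.1
  expect_warning(lab2 <- label_profiles(fit), "no defining item")
  expect_true(is.na(dplyr::filter(lab2, class == 2)$item))
})

test_that("crosstabs report counts and half-up column percentages that
           recompute from their own counts", {
  # a class of 981 with 620 Army -> 63.2%
  covs <- tibble::tibble(
    branch = c(rep("Army", 620), rep("Marine Corps", 361),
               rep("Army", 100), rep("Navy", 100))
  )
  asg <- c(rep(1L, 981), rep(2L, 200))
  ct <- crosstab_by_class(covs, asg, "branch")
  army1 <- dplyr::filter(ct, level == "Army", class == "1")
  expect_equal(army1$n, 620L)
  expect_equal(army1$pct, 63.2)
  # empty level x class combinations are retained as zero rows
  navy1 <- dplyr::filter(ct, level == "Navy", class == "1")
  expect_equal(navy1$n, 0L)
  expect_equal(navy1$pct, 0)
  # within-class percentages over exhaustive levels sum to 100 +- 0.3
  sums <- ct |>
    dplyr::summarise(s = sum(pct), .by = "class")
  expect_true(all(abs(sums$s - 100) <= 0.3))
  # percentages recompute exactly from their own counts
  totals <- c(total = 1181, `1` = 981, `2` = 200)
  expect_equal(ct$pct,
               unname(round_half_up(100 * ct$n / totals[ct$class], 1)))
})

test_that("half-up rounding follows the printed-table convention", {
  expect_equal(round_half_up(c(0.05, 0.15, 0.25) * 10, 0), c(1, 2, 3))
  expect_equal(round_half_up(100 * 981 / 5227, 1), 18.8)
  expect_equal(round_half_up(100 * 2208 / 5227, 1), 42.2)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("the omnibus chi-square is Pearson without continuity
           correction", {
  # identical column distributions: statistic 0, p = 1
  same <- cbind(c(10, 20), c(10, 20))
  out <- class_chisq(same)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  # hand-computed 2x2: (10,20 / 20,10), all expected counts 15
  t22 <- rbind(c(10, 20), c(20, 10))
  out2 <- class_chisq(t22)
  expect_equal(out2$statistic, 4 * 25 / 15, tolerance = 1e-9) # 6.6667
  expect_equal(out2$df, 1)
  expect_equal(out2$p_value, 0.0098, tolerance = 1e-2)
  expect_false(out2$expected_below_5)

  # published age-by-profile and sex-by-profile count tables reproduce
  # their printed omnibus p-values (0.11 and 0.43)
  age <- rbind(`18-24` = c(560, 405, 189, 448, 589, 213, 517),
               `25-29` = c(267, 177, 87, 196, 255, 87, 216),
               `30+`   = c(154, 160, 77, 160, 192, 87, 191))
  expect_equal(round_half_up(class_chisq(age)$p_value, 2), 0.11)
  sizes <- c(981, 742, 353, 804, 1036, 387, 924)
  male <- c(966, 732, 349, 788, 1010, 381, 910)
  sex <- rbind(male = male, female = sizes - male)
  expect_equal(round_half_up(class_chisq(sex)$p_value, 2), 0.43)

  # zero-margin rows are dropped with a warning; too-small tables error
  withzero <- rbind(c(10, 20), c(0, 0), c(20, 10))
  expect_warning(out3 <- class_chisq(withzero), "zero-margin")
  expect_equal(out3$statistic, out2$statistic)
  expect_error(suppressWarnings(class_chisq(rbind(c(5, 5), c(0, 0)))),
               "2 x 2")
  # sparse tables flag low expected counts
  expect_warning(out4 <- class_chisq(rbind(c(2, 1), c(1, 3))),
                 "below 5")
  expect_true(out4$expected_below_5)
})

test_that("Holm adjustment agrees with hand enumeration and brute force", {
  # (0.01, 0.03, 0.04) -> (0.03, 0.06, 0.06)
  expect_equal(oracle_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  # m = 1: adjusted equals raw
  expect_equal(oracle_holm(0.02), 0.02)
  # 21 tied raw p-values of 0.002 all adjust to 0.042
  expect_equal(oracle_holm(rep(0.002, 21)), rep(0.042, 21))
  expect_equal(stats::p.adjust(rep(0.002, 21), "holm"), rep(0.042, 21))

  # brute-force equivalence on 1,000 random p-vectors, plus invariance and
  # the Bonferroni-domination property
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    holm <- stats::p.adjust(p, "holm")
    expect_equal(holm, oracle_holm(p), tolerance = 1e-12)
    # order invariance
    perm <- sample(m)
    expect_equal(stats::p.adjust(p[perm], "holm"), holm[perm],
                 tolerance = 1e-12)
    # Holm rejects whatever Bonferroni rejects
    bonf <- pmin(p * m, 1)
    expect_true(all(holm[bonf < 0.05] < 0.05 + 1e-12))
    expect_true(all(holm >= p - 1e-15) && all(holm <= 1))
  }
})

test_that("pairwise class comparisons form per-level Holm families and
           respect exclusions", {
  counts <- rbind(
    mounted = c(227, 265, 277),
    dismounted = c(645, 277, 35),
    unknown = c(109, 200, 41)
  )
  colnames(counts) <- c("1", "2", "3")
  pw <- pairwise_holm(counts, variable = "posture")
  # unknown is excluded from testing; 2 tested levels x choose(3,2) pairs
  expect_false(any(pw$level == "unknown"))
  expect_equal(nrow(pw), 2 * 3)
  # proportions recompute from the counts
  m12 <- dplyr::filter(pw, level == "mounted", class_a == "1",
                       class_b == "2")
  expect_equal(m12$prop_a, 227 / sum(counts[, 1]))
  expect_equal(m12$prop_b, 265 / sum(counts[, 2]))
  # adjusted >= raw, capped at 1; significance at alpha
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15))
  expect_true(all(pw$p_adj <= 1))
  expect_equal(pw$significant, pw$p_adj < 0.05)
  # the family is the level: adjustment equals Holm over that level's pairs
  mounted <- dplyr::filter(pw, level == "mounted")
  expect_equal(mounted$p_adj, oracle_holm(mounted$p_raw), tolerance = 1e-12)

  # raw p-values match the two-proportion Pearson chi-square
  t22 <- rbind(c(227, 981 - 227), c(265, 742 - 265))
  expect_equal(m12$p_raw,
               suppressWarnings(stats::chisq.test(t22,
                                                  correct = FALSE))$p.value)

  # significance marks condense into superscript letters
  marks <- significance_marks(pw)
  if (nrow(marks) > 0) {
    expect_true(all(grepl("^[a-z](,[a-z])*$", marks$marks)))
  }
})

test_that("the characteristics report assembles crosstabs, omnibus tests,
           and pairwise marks", {
  cfg <- default_template(7, 30, seed = 51)
  coh <- sample_cohort(cfg, n = 1500, seed = 51)
  res <- suppressWarnings(
    profile_characteristics(coh$covariates, coh$truth$true_class,
                            variables = c("mechanism", "posture")))
  tab <- res$table
  expect_setequal(unique(tab$variable), c("mechanism", "posture"))
  # strong true differences in mechanism across classes reach Holm-adjusted
  # significance in the most-separated pair (class 5 vs 7: 0.68 vs 0.34)
  blast <- dplyr::filter(res$pairwise, level == "blast",
                         class_a == "5", class_b == "7")
  expect_true(blast$significant)
  omni <- unique(dplyr::filter(tab, variable == "mechanism")$omnibus_p)
  expect_lt(omni, 0.001)
})
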