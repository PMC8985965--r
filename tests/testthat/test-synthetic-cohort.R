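test_that("the default 7-class template carries the published signal
           structure and class shares", {
  cfg <- default_template(7, 181)
  tmpl <- cfg$item_probability_template
  expect_equal(dim(tmpl), c(7, 181))
  # published high-probability entries at their printed values
  expect_equal(tmpl["class4", "r02c05"], 0.835) # internal organ, Type 2 TBI
  expect_equal(tmpl["class6", "r35c11"], 0.986) # burns, unspecified
  expect_equal(tmpl["class1", "r33c06"], 0.791) # open wounds, lower extremity
  expect_equal(tmpl["class3", "r16c01"], 0.584) # open fracture, lumbar VCI
  # class shares from the printed class sizes; exact simplex
  expect_equal(cfg$mixing_proportions[1], 981 / 5227)
  expect_equal(sum(cfg$mixing_proportions), 1, tolerance = 1e-15)
  # items without published signal sit at the background rate
  signal_cells <- profile_item_probabilities()$cell_id
  others <- setdiff(colnames(tmpl), signal_cells)
  expect_equal(length(others), 181 - 26)
  expect_true(all(tmpl[, others] == cfg$background_probability))
  # covariate model probabilities are class-wise simplices
  for (pm in cfg$covariate_model) {
    expect_equal(unname(colSums(pm)), rep(1, 7), tolerance = 1e-12)
  }
  # mechanism distribution of the burns class matches the printed counts
  expect_equal(unname(cfg$covariate_model$mechanism[, 6]),
               c(368, 4, 15) / 387)
})

test_that("template configuration is validated", {
  expect_error(default_template(7, 20), "j >= 26")
  expect_error(cohort_config(2, 3, mixing_proportions = c(0.6, 0.5),
                             item_probability_template = matrix(0.5, 2, 3)),
               "sum to 1")
  expect_error(cohort_config(2, 3, mixing_proportions = c(0.5, 0.5),
                             item_probability_template = matrix(1.5, 2, 3)),
               "\\[0, 1\\]")
})

test_that("cohort sampling is seed-reproducible and honors edge cases", {
  cfg <- default_template(4, 16, seed = 7)
  a <- sample_cohort(cfg, n = 120, seed = 7)
  b <- sample_cohort(cfg, n = 120, seed = 7)
  expect_identical(a, b)
  c2 <- sample_cohort(cfg, n = 120, seed = 8)
  expect_false(identical(a$indicators, c2$indicators))

  # empty cohort keeps the J-column schema
  e <- sample_cohort(cfg, n = 0)
  expect_equal(nrow(e$indicators), 0L)
  expect_equal(ncol(e$indicators), 16 + 1L)
  expect_error(sample_cohort(cfg, n = -1), "non-negative")

  # degenerate 0/1 probabilities reproduce the template rows exactly
  tmpl <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("r01c05", "r02c05", "r05c06",
                                         "r19c05")))
  dcfg <- cohort_config(2, 4, mixing_proportions = c(0.5, 0.5),
                        item_probability_template = tmpl)
  d <- sample_cohort(dcfg, n = 50, seed = 1)
  m <- as.matrix(d$indicators[-1])
  expect_equal(m, tmpl[d$truth$true_class, ], ignore_attr = TRUE)
})

test_that("empirical item frequencies, class shares, and covariate shares
           match the generator within 3 binomial standard errors", {
  cfg <- default_template(7, 181)
  n <- 20000
  coh <- sample_cohort(cfg, n = n, seed = 123)
  # item marginals vs sum_k pi_k rho_jk
  expected <- as.numeric(cfg$mixing_proportions %*%
                           cfg$item_probability_template)
  observed <- colMeans(as.matrix(coh$indicators[-1]))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) <= 3 * se + 1e-12))
  # class shares vs mixing proportions
  shares <- tabulate(coh$truth$true_class, 7) / n
  se_pi <- sqrt(cfg$mixing_proportions * (1 - cfg$mixing_proportions) / n)
  expect_true(all(abs(shares - cfg$mixing_proportions) <= 3 * se_pi))
  # covariate shares within a class vs the class-conditional model
  for (v in c("mechanism", "posture")) {
    pm <- cfg$covariate_model[[v]]
    for (g in c(1, 6)) {
      idx <- coh$truth$true_class == g
      ng <- sum(idx)
      obs <- table(factor(coh$covariates[[v]][idx],
                          levels = rownames(pm))) / ng
      se_c <- sqrt(pm[, g] * (1 - pm[, g]) / ng)
      expect_true(all(abs(as.numeric(obs) - pm[, g]) <= 3 * se_c + 1e-12))
    }
  }
})

test_that("items are conditionally independent given class", {
  # a single-class cohort of 20,000 isolates the generator's within-class
  # independence: every pairwise |r| stays below 0.05
  cfg1 <- cohort_config(
    1, 181, mixing_proportions = 1,
    item_probability_template =
      default_template(7, 181)$item_probability_template[4, , drop = FALSE]
  )
  coh1 <- sample_cohort(cfg1, n = 20000, seed = 321)
  m1 <- as.matrix(coh1$indicators[-1])
  keep <- apply(m1, 2, stats::sd) > 0
  cc <- stats::cor(m1[, keep])
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.05)

  # within each mixture class, no item pair shows dependence by an exact
  # conditional (hypergeometric) two-sided test at familywise 0.05
  # (Bonferroni over all pairs) — correlations are heavy-tailed for the
  # sparse background items, so the exact test is the right null
  cfg <- default_template(7, 181)
  coh <- sample_cohort(cfg, n = 20000, seed = 321)
  m <- as.matrix(coh$indicators[-1])
  for (g in c(1, 4, 6)) {
    sub <- m[coh$truth$true_class == g, ]
    n_g <- nrow(sub)
    cs <- colSums(sub)
    n11 <- crossprod(sub)
    pair <- which(upper.tri(n11), arr.ind = TRUE)
    x <- n11[pair]
    m1 <- cs[pair[, 1]]
    m2 <- cs[pair[, 2]]
    p_hi <- stats::phyper(x - 1, m1, n_g - m1, m2, lower.tail = FALSE)
    p_lo <- stats::phyper(x, m1, n_g - m1, m2)
    p2 <- pmin(1, 2 * pmin(p_hi, p_lo))
    expect_gt(min(p2) * nrow(pair), 0.05)
  }
})

test_that("record expansion round-trips through coding and respects the
           severity model", {
  cfg <- default_template(7, 40, seed = 2)
  coh <- sample_cohort(cfg, n = 150, seed = 2)
  coh <- sample_injury_records(coh, seed = 2)
  cells <- setdiff(names(coh$indicators), "casualty_id")
  back <- build_indicator_matrix(coh$records, cells = cells,
                                 casualty_ids = coh$indicators$casualty_id)
  expect_equal(as.matrix(back[cells]), as.matrix(coh$indicators[cells]),
               ignore_attr = TRUE)

  # casualty with all-zero indicators gets no records
  zero_ids <- coh$indicators$casualty_id[
    rowSums(coh$indicators[cells]) == 0]
  expect_false(any(coh$records$casualty_id %in% zero_ids))

  # a severity model concentrated on AIS >= 3 pushes everyone over ISS 9
  # when three distinct ISS regions are guaranteed
  tmpl <- matrix(1, nrow = 1, ncol = 3,
                 dimnames = list(NULL, c("r01c05", "r19c05", "r20c05")))
  cfg3 <- cohort_config(1, 3, mixing_proportions = 1,
                        item_probability_template = tmpl)
  coh3 <- sample_cohort(cfg3, n = 40, seed = 4)
  sev <- severity_model(c(0, 0, 1, 0, 0))
  coh3 <- sample_injury_records(coh3, sev = sev, seed = 4)
  expect_true(all(coh3$records$ais == 3))
  iss <- compute_iss(coh3$records)
  expect_true(all(iss$iss == 27))
  expect_equal(length(suppressMessages(filter_by_iss(iss))), 40)

  # unknown cell ids are rejected
  expect_error(severity_model(overrides = list(zz9 = rep(0.2, 5))),
               "unknown cell")
})
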