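test_that("event matching is reciprocal, typed and maximal-overlap", {
  q <- event_table(c("q1", "q2", "q3"), "ES", "g", "chr1", "+",
                   start = c(100, 500, 900), end = c(200, 600, 1000),
                   anchor_up_end = c(50, 450, 850),
                   anchor_down_start = c(250, 650, 1050))
  s <- event_table(c("s1", "s2", "s3", "s4"), "ES", "g", "chr1", "+",
                   start = c(100, 700, 120, 905), end = c(200, 800, 190,
                                                          995),
                   anchor_up_end = c(50, 650, 60, 850),
                   anchor_down_start = c(250, 850, 260, 1050))
  m <- match_events(q, s)
  # identical coordinates match; disjoint q2 does not
  expect_equal(m$subject_id[m$query_id == "q1"], "s1")
  expect_false("q2" %in% m$query_id)
  # nested candidates resolve to the larger overlap: s1 overlaps q1 by
  # 100 bp, s3 only by 70, so s3 stays unmatched
  expect_false("s3" %in% m$subject_id)
  expect_equal(m$subject_id[m$query_id == "q3"], "s4")
  expect_equal(m$overlap[m$query_id == "q3"], 90L)

  # strand and type mismatches block matching
  s_minus <- s; s_minus$strand <- "-"
  expect_equal(nrow(match_events(q, s_minus)), 0L)
  s_mxe <- s; s_mxe$type <- "MXE"
  expect_equal(nrow(match_events(q, s_mxe)), 0L)
})

test_that("PSI-expression correlation is tie-safe and monotone-invariant", {
  set.seed(12)
  n <- 80
  expr <- matrix(rlnorm(2 * n), 2, n,
                 dimnames = list(c("R1", "R2"),
                                 sprintf("s%02d", seq_len(n))))
  psi <- matrix(NA_real_, 3, n,
                dimnames = list(c("inc", "const", "noisy"),
                                colnames(expr)))
  psi["inc", ] <- plogis(log(expr["R1", ]))        # strictly increasing
  psi["const", ] <- 0.4
  psi["noisy", ] <- runif(n)
  out <- correlate_psi_expression(psi, expr, c("R1", "R2"))
  expect_equal(out$rho[out$event_id == "inc" & out$regulator == "R1"], 1)
  expect_true(is.na(out$rho[out$event_id == "const" &
                              out$regulator == "R1"]))

  # Spearman is invariant under strictly monotone transforms
  expr2 <- expr; expr2["R1", ] <- exp(expr["R1", ])
  out2 <- correlate_psi_expression(psi, expr2, "R1")
  expect_equal(out$rho[out$regulator == "R1"],
               out2$rho[out2$regulator == "R1"])

  # too few complete pairs: reported missing
  psi_na <- psi; psi_na["noisy", 10:n] <- NA
  out3 <- correlate_psi_expression(psi_na, expr, "R1", min_pairs = 10)
  expect_true(is.na(out3$rho[out3$event_id == "noisy"]))
})

test_that("median stratification partitions samples and tests PSI shifts", {
  set.seed(2)
  n <- 100
  expr <- matrix(rlnorm(n), 1, n,
                 dimnames = list("R1", sprintf("s%03d", 1:n)))
  strata <- spliceRewire:::median_strata(expr["R1", ])
  expect_equal(sum(table(strata)), n)
  expect_true(all(expr["R1", strata == "high"] >
                    median(expr["R1", ])))

  # a planted shift between strata is recovered and significant
  psi <- matrix(NA_real_, 2, n,
                dimnames = list(c("shifted", "flat"), colnames(expr)))
  psi["shifted", ] <- ifelse(strata == "high", 0.7, 0.4) +
    rnorm(n, 0, 0.03)
  psi["flat", ] <- rep(c(0.5, 0.52), length.out = n)
  out <- stratify_and_test(psi, expr, "R1")
  sh <- out[out$event_id == "shifted", ]
  expect_lt(abs(sh$delta_psi - 0.3), 0.03)
  expect_lt(sh$q_value, 0.05)

  # one usable sample per stratum: skipped with a reason
  psi_small <- psi
  psi_small["flat", 3:n] <- NA
  out2 <- stratify_and_test(psi_small, expr, "R1")
  expect_false(is.na(out2$skipped[out2$event_id == "flat"]))
})

test_that("clinical associations dispatch by covariate type", {
  n <- 60
  values <- setNames(c(seq_len(n / 2), seq_len(n / 2)),
                     sprintf("s%02d", 1:n))
  # the high stratum is values > median; build a 2x2 with rows
  # [20, 10] / [10, 20]
  strata <- spliceRewire:::median_strata(values)
  f <- character(n)
  f[strata == "high"] <- rep(c("A", "B"), c(20, 10))
  f[strata == "low"] <- rep(c("A", "B"), c(10, 20))
  clinical <- data.frame(sample_id = names(values),
                         grp = f,
                         age = as.numeric(values) + rnorm(n, 0, 0.01),
                         mono = "only", stringsAsFactors = FALSE)
  out <- test_clinical(values, clinical)

  # chi-square without continuity correction: closed form on the 2x2
  tab <- matrix(c(10, 20, 20, 10), 2)  # rows A/B x cols low/high
  nA <- sum(tab[1, ]); nB <- sum(tab[2, ])
  nl <- sum(tab[, 1]); nh <- sum(tab[, 2]); N <- sum(tab)
  chi_by_hand <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (nA * nB * nl * nh)
  chi_row <- out[out$covariate == "grp" & out$method == "chi-square", ]
  expect_equal(unname(chi_row$statistic), chi_by_hand)
  expect_equal(chi_by_hand, 20 / 3)
  expect_false(chi_row$unreliable)

  # continuous covariate goes through Spearman and tracks the values
  sp <- out[out$covariate == "age", ]
  expect_equal(sp$method, "spearman")
  expect_gt(sp$estimate, 0.9)

  # single-level covariate is skipped with a reason
  mono <- out[out$covariate == "mono", ]
  expect_equal(mono$skipped, "single level")

  # identical groups give a Kruskal-Wallis statistic of 0
  clin2 <- data.frame(sample_id = names(values),
                      g2 = rep(c("x", "y"), each = n / 2))
  v2 <- setNames(rep(c(1, 2, 3), length.out = n), names(values))
  v2[clin2$g2 == "y"] <- v2[clin2$g2 == "x"]
  out2 <- test_clinical(v2, clin2)
  kw <- out2[out2$method == "kruskal-wallis", ]
  expect_lt(kw$statistic, 1e-9)
})

test_that("survival association estimates stratum hazards and flags", {
  set.seed(44)
  n <- 400
  psi <- matrix(runif(2 * n), 2, n,
                dimnames = list(c("risk", "flat"), sprintf("s%03d", 1:n)))
  high <- psi["risk", ] > median(psi["risk", ])
  rate <- 0.02 * ifelse(high, 0.5, 1)
  clinical <- data.frame(
    sample_id = colnames(psi),
    OS_time = rexp(n, rate) ,
    OS_status = 1L, stringsAsFactors = FALSE)
  out <- survival_association(psi, clinical, "OS")
  risk <- out[out$event_id == "risk", ]
  expect_lt(abs(risk$hr - 0.5), 0.15)
  expect_lt(risk$logrank_p, 1e-6)
  flat <- out[out$event_id == "flat", ]
  expect_gt(flat$logrank_p, 1e-4)

  # constant PSI: one stratum, flagged unestimable
  psi1 <- rbind(const = rep(0.5, n))
  colnames(psi1) <- colnames(psi)
  out1 <- survival_association(psi1, clinical, "OS")
  expect_true(is.na(out1$hr))
  expect_equal(out1$skipped, "one stratum")
})

test_that("log-rank p-values are uniform under a null hazard", {
  set.seed(91)
  n <- 150; n_ev <- 200
  clinical <- data.frame(sample_id = sprintf("s%03d", 1:n),
                         OS_time = rexp(n, 0.02),
                         OS_status = rbinom(n, 1, 0.8))
  psi <- matrix(runif(n_ev * n), n_ev, n,
                dimnames = list(sprintf("e%03d", 1:n_ev),
                                clinical$sample_id))
  out <- survival_association(psi, clinical, "OS")
  ks <- ks.test(out$logrank_p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("pathway scores and correlations behave as constructed", {
  set.seed(6)
  n <- 120
  expr <- matrix(rlnorm(5 * n, 2, 0.7), 5, n,
                 dimnames = list(sprintf("g%d", 1:5),
                                 sprintf("s%03d", 1:n)))
  # singleton gene set: the score is that gene's z-scored log expression
  sc <- pathway_scores(expr, list(solo = "g1"))
  z <- scale(log2(expr["g1", ] + 1))[, 1]
  expect_equal(unname(sc["solo", ]), unname(z / sd(z) * sd(sc["solo", ])),
               tolerance = 1e-9)
  expect_lt(abs(mean(sc["solo", ])), 1e-12)
  expect_equal(sd(sc["solo", ]), 1)

  # an event monotone in the score correlates near 1, and two
  # anticorrelated modules split at k = 2
  driver <- rnorm(n)
  exprA <- t(vapply(1:6, function(i) exp(1 + driver + rnorm(n, 0, 0.3)),
                    numeric(n)))
  exprB <- t(vapply(1:6, function(i) exp(1 - driver + rnorm(n, 0, 0.3)),
                    numeric(n)))
  rownames(exprA) <- sprintf("a%d", 1:6)
  rownames(exprB) <- sprintf("b%d", 1:6)
  expr2 <- rbind(exprA, exprB)
  colnames(expr2) <- sprintf("s%03d", 1:n)
  sets <- list(pwA1 = sprintf("a%d", 1:3), pwA2 = sprintf("a%d", 4:6),
               pwB1 = sprintf("b%d", 1:3), pwB2 = sprintf("b%d", 4:6))
  psi <- matrix(plogis(driver), 1, n,
                dimnames = list("ev1", colnames(expr2)))
  pc <- pathway_correlation(psi, expr2, sets, k = 2)
  expect_gt(pc$correlations["ev1", "pwA1"], 0.9)
  expect_lt(pc$correlations["ev1", "pwB1"], -0.9)
  cl <- pc$clusters
  expect_equal(cl[["pwA1"]], cl[["pwA2"]])
  expect_equal(cl[["pwB1"]], cl[["pwB2"]])
  expect_false(cl[["pwA1"]] == cl[["pwB1"]])
  # reported pairs respect the |r| > 0.3 rule
  expect_true(all(abs(pc$reported$rho) > 0.3))
  expect_true("pwA1" %in% pc$reported$pathway)
})

test_that("group comparisons report dPSI with rank-sum significance", {
  set.seed(3)
  n1 <- 90; n2 <- 40
  groups <- factor(rep(c("tumor", "normal"), c(n1, n2)),
                   levels = c("tumor", "normal"))
  psi <- matrix(NA_real_, 3, n1 + n2,
                dimnames = list(c("down", "same", "gone"),
                                sprintf("s%03d", seq_len(n1 + n2))))
  psi["down", ] <- c(rnorm(n1, 0.3, 0.05), rnorm(n2, 0.63, 0.05))
  psi["same", ] <- rep(seq(0.2, 0.8, length.out = 10),
                       length.out = n1 + n2)
  psi["gone", groups == "normal"] <- NA
  psi["gone", groups == "tumor"] <- 0.5
  out <- compare_groups(psi, groups)
  expect_lt(abs(out$dpsi[out$event_id == "down"] - (-0.33)), 0.04)
  expect_lt(out$q_value[out$event_id == "down"], 0.05)
  expect_false(is.na(out$skipped[out$event_id == "gone"]))
  # identical pools give a zero shift
  expect_lt(abs(out$dpsi[out$event_id == "same"]), 0.05)
})
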