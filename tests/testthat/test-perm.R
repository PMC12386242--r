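test_that("least squares reproduces group-mean identities", {
  # separated two-group data: slope = 1
  y <- c(0, 0, 1, 1); I <- c(0, 0, 1, 1)
  b <- ols_fit(cbind(intercept = 1, I = I), y)
  expect_equal(unname(b["I"]), 1)

  # no-intercept interaction design: b3 = mean(D) - mean(P) - mean(Q)
  y <- c(0.10, 0.10, 0.20, 0.20, 0.40, 0.40)
  ip <- c(1, 1, 0, 0, 1, 1); iq <- c(0, 0, 1, 1, 1, 1)
  b <- ols_fit(cbind(Ip = ip, Iq = iq, IpIq = ip * iq), y)
  expect_equal(unname(b["IpIq"]), 0.10, tolerance = 1e-12)

  # constant response: all non-intercept coefficients zero
  b <- ols_fit(cbind(intercept = 1, I = c(0, 1, 0, 1)), rep(0.3, 4))
  expect_equal(unname(b["I"]), 0, tolerance = 1e-12)

  expect_error(ols_fit(cbind(a = 1:4, b = 2 * (1:4)), rnorm(4)),
               "collinear.*b")
})

test_that("the no-intercept b3 equals the additive-excess closed form", {
  set.seed(101)
  for (i in 1:100) {
    sizes <- sample(2:6, 3, replace = TRUE)
    y <- runif(sum(sizes))
    ip <- rep(c(1, 0, 1), sizes)
    iq <- rep(c(0, 1, 1), sizes)
    b3 <- unname(ols_fit(cbind(ip, iq, ip * iq), y)[3])
    closed <- mean(y[ip == 1 & iq == 1]) - mean(y[ip == 1 & iq == 0]) -
      mean(y[ip == 0 & iq == 1])
    expect_equal(b3, closed, tolerance = 1e-10)
  }
})

test_that("the exceedance p-value estimator follows (n+1)/(N+1)", {
  expect_equal(pvalue_from_exceedances(0, 1e6), 1 / 1000001)
  expect_equal(pvalue_from_exceedances(1e6, 1e6), 1)
  expect_equal(pvalue_from_exceedances(49, 999), 0.05)
  expect_error(pvalue_from_exceedances(10, 9), "exceeds")
  # monotone in n
  p <- vapply(0:10, pvalue_from_exceedances, numeric(1), N = 10)
  expect_true(all(diff(p) > 0))
})

test_that("two-group enumeration matches a full-permutation oracle", {
  # complete separation in 3 vs 3 -> p = 1/20
  y <- c(0, 0, 0, 1, 1, 1); g <- c(0, 0, 0, 1, 1, 1)
  res <- two_group_perm_test(y, g, perm_config())
  expect_true(res$exhaustive)
  expect_equal(res$coefficient, 1)
  expect_equal(res$p_value, 1 / 20)

  # oracle: all 6! label permutations; distinct arrangements collapse 3!3!
  y <- c(0.1, 0.3, 0.2, 0.6, 0.15, 0.55)
  obs <- mean(y[4:6]) - mean(y[1:3])
  stats <- vapply(all_perms(1:6), function(p) {
    yy <- y[p]; mean(yy[4:6]) - mean(yy[1:3])
  }, numeric(1))
  # statistic depends on which y-values carry label 1, so the full-perm
  # fraction equals the distinct-arrangement fraction
  oracle_strict <- mean(stats > obs + 1e-12) + 1 / choose(6, 3)
  res <- two_group_perm_test(y, g, perm_config(tie_rule = "strict"))
  expect_equal(res$p_value, oracle_strict, tolerance = 1e-12)

  # identical constant groups: geq ties give p = 1
  res <- two_group_perm_test(rep(0.5, 6), g, perm_config(tie_rule = "geq"))
  expect_equal(res$p_value, 1)
})

test_that("swapping group roles complements the exceedance count", {
  set.seed(33)
  y <- round(runif(7), 2)
  g <- c(0, 0, 0, 1, 1, 1, 1)
  a <- two_group_perm_test(y, g, perm_config(tie_rule = "strict"))
  b <- two_group_perm_test(y, 1 - g, perm_config(tie_rule = "geq"))
  M <- a$n_permutations
  expect_true(a$exhaustive && b$exhaustive)
  expect_identical(a$exceedances + b$exceedances, M)
})

test_that("Monte-Carlo p-values track the exhaustive enumeration", {
  # under the geq tie rule the exhaustive p is the exact probability that a
  # random arrangement meets the observed statistic, which the Monte-Carlo
  # estimator targets up to O(1/N); under `strict` the two conventions
  # differ deterministically by about 1/M (the identity-arrangement term)
  set.seed(44)
  for (i in 1:3) {
    y <- runif(8)
    g <- rep(c(0, 1), each = 4)
    exh <- two_group_perm_test(y, g, perm_config(tie_rule = "geq"))
    mc <- two_group_perm_test(
      y, g, perm_config(n_permutations = 10000, exhaustive_threshold = 0,
                        tie_rule = "geq", seed = i))
    expect_false(mc$exhaustive)
    se <- sqrt(exh$p_value * (1 - exh$p_value) / 10000)
    expect_lt(abs(mc$p_value - exh$p_value), 3 * se + 2e-4)
    expect_gt(mc$p_value, 0)
    expect_lte(mc$p_value, 1)
  }
})

test_that("orthogonalization removes exactly the nuisance projection", {
  # already-orthogonal input is unchanged
  Z <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  g <- c(1, -1, 2, -2)
  expect_equal(smith_orthogonalize(Z, g), g, tolerance = 1e-12)

  # a regressor inside span(Z) is annihilated and the test refuses to run
  g_in <- Z %*% c(2, -1)
  expect_equal(smith_orthogonalize(Z, as.vector(g_in)), rep(0, 4),
               tolerance = 1e-12)
  y <- c(0.1, 0.2, 0.3, 0.4)
  expect_error(
    interaction_perm_test(y, ip = c(1, 1, 1, 1), iq = c(0, 0, 1, 1)),
    "empty genotype group")

  # dense projector oracle on random designs, incl. the balanced case
  set.seed(55)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    Z <- matrix(rnorm(2 * n), n, 2)
    g <- rnorm(n)
    gp <- smith_orthogonalize(Z, g)
    expect_equal(gp, project_out_oracle(Z, g), tolerance = 1e-10)
    expect_lt(max(abs(crossprod(Z, gp))), 1e-10 * max(1, sqrt(sum(g^2))))
  }
  # balanced three-group design: orthogonalized entries equal within groups
  m <- 4
  ip <- rep(c(1, 0, 1), each = m); iq <- rep(c(0, 1, 1), each = m)
  gp <- smith_orthogonalize(cbind(ip, iq), ip * iq)
  expect_equal(gp, project_out_oracle(cbind(ip, iq), ip * iq),
               tolerance = 1e-12)
  # entries are constant within groups; by symmetry the two single-het
  # groups share one value, so a balanced design has 2 distinct values
  expect_equal(length(unique(round(gp, 10))), 2L)
  for (grp in split(gp, interaction(ip, iq, drop = TRUE)))
    expect_lt(diff(range(grp)), 1e-12)
})

test_that("the synergy test recovers known interaction structure", {
  cfgp <- perm_config()
  # zero-noise synergistic groups: b3 = 0.10 and the observed statistic is
  # the enumeration maximum (3 embryos per group -> 1680 arrangements)
  y <- c(rep(0.10, 3), rep(0.20, 3), rep(0.40, 3))
  ip <- rep(c(1, 0, 1), each = 3); iq <- rep(c(0, 1, 1), each = 3)
  res <- interaction_perm_test(y, ip, iq, cfgp)
  expect_true(res$exhaustive)
  expect_equal(res$coefficient, 0.10, tolerance = 1e-12)
  # balanced design: the orthogonalized regressor takes 2 distinct values
  # (the single-het groups share one), so choose(9, 3) arrangements
  expect_equal(res$n_permutations, choose(9, 3))
  expect_lt(res$p_value, 0.05)

  # exactly additive data: b3 = 0
  y <- c(rep(0.10, 4), rep(0.20, 4), rep(0.30, 4))
  ip <- rep(c(1, 0, 1), each = 4); iq <- rep(c(0, 1, 1), each = 4)
  res <- interaction_perm_test(y, ip, iq, cfgp)
  expect_equal(res$coefficient, 0, tolerance = 1e-12)

  # with an intercept and control embryos (4 groups), a constant response
  # gives interaction coefficient 0 and every permuted statistic ties, so
  # geq gives p = 1
  yc <- rep(0.25, 16)
  ipc <- c(ip, rep(0, 4)); iqc <- c(iq, rep(0, 4))
  res <- interaction_perm_test(yc, ipc, iqc, perm_config(tie_rule = "geq"),
                               with_intercept = TRUE)
  expect_equal(res$coefficient, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # without controls, adding an intercept saturates the three groups and
  # the interaction regressor falls into the nuisance span
  expect_error(
    interaction_perm_test(rep(0.25, 12), ip, iq, perm_config(),
                          with_intercept = TRUE),
    "not identifiable")
  # in the literal no-intercept model a constant response c gives
  # b3 = c - c - c = -c: the double-het mean minus the two single-het means
  res <- interaction_perm_test(rep(0.25, 12), ip, iq, perm_config())
  expect_equal(res$coefficient, -0.25, tolerance = 1e-12)

  expect_error(interaction_perm_test(y, ip * 0, iq, cfgp), "empty genotype")
  expect_error(
    interaction_perm_test(c(y, 0.1), c(ip, 0), c(iq, 0), cfgp),
    "control")
})

test_that("interaction Monte-Carlo agrees with its exhaustive enumeration", {
  set.seed(66)
  y <- round(runif(9), 2)
  ip <- rep(c(1, 0, 1), each = 3); iq <- rep(c(0, 1, 1), each = 3)
  exh <- interaction_perm_test(y, ip, iq, perm_config(tie_rule = "geq"))
  expect_true(exh$exhaustive)
  mc <- interaction_perm_test(
    y, ip, iq, perm_config(n_permutations = 10000, exhaustive_threshold = 0,
                           tie_rule = "geq", seed = 5))
  se <- sqrt(exh$p_value * (1 - exh$p_value) / 10000)
  expect_lt(abs(mc$p_value - exh$p_value), 3 * se + 2e-4)
})

test_that("permutation operates on embryos, not hemisegments", {
  # adding hemisegments to one embryo changes its proportion but not the
  # number of exchangeable units (label arrangements)
  recs <- rbind(
    do.call(rbind, lapply(1:3, function(i) {
      m <- wt_counts(); m[seq_len(i), 1] <- 3
      embryo_records(m, sprintf("a%d", i), genotype = "g0")
    })),
    do.call(rbind, lapply(1:3, function(i)
      embryo_records(wt_counts(), sprintf("b%d", i), genotype = "g1")))
  )
  s1 <- summarize_embryos(recs)
  r1 <- two_group_perm_test(s1$prop_tin_symmetric, s1$genotype, perm_config())

  extra <- embryo_records(matrix(rep(c(3, 2, 2), 4), ncol = 3, byrow = TRUE),
                          "a1", genotype = "g0")
  extra <- extra[1:4, ]; extra$side <- "R"; extra$segment <- paste0("A", 2:5)
  recs2 <- rbind(recs[!(recs$embryo_id == "a1" & recs$side == "R" &
                          recs$segment %in% paste0("A", 2:5)), ], extra)
  s2 <- summarize_embryos(recs2)
  expect_false(isTRUE(all.equal(
    s1$prop_tin_symmetric[s1$embryo_id == "a1"],
    s2$prop_tin_symmetric[s2$embryo_id == "a1"])))
  r2 <- two_group_perm_test(s2$prop_tin_symmetric, s2$genotype, perm_config())
  expect_identical(r1$n_permutations, r2$n_permutations)  # choose(6, 3)
  expect_identical(r1$n_permutations, 20L)
})

test_that("degenerate group sizes warn but still test", {
  expect_warning(
    res <- two_group_perm_test(c(0.1, 0.2, 0.9), c(0, 0, 1), perm_config()),
    "degenerate")
  expect_true(res$degenerate)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("synergy calls follow the sign-and-significance rule", {
  fake <- function(coef, p) structure(
    list(coefficient = coef, p_value = p, alpha = 0.05),
    class = "perm_test")
  expect_equal(synergy_call(fake(0.08, 0.012)), "synergistic")
  expect_equal(synergy_call(fake(0.05, 0.069)), "not_synergistic")
  expect_equal(synergy_call(fake(-0.02, 0.001)), "not_synergistic")
  expect_equal(synergy_call(fake(0.08, 0.012), alpha = 0.01),
               "not_synergistic")
})
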