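# The two-P-value differential scheme, combination, adjustment, fold rule.

test_that("fisher_exact_2x2 matches hand-derived and enumerated values", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact_2x2(12, 0, 0, 12), 2 / 2704156)
  # zero margin carries no information
  expect_equal(fisher_exact_2x2(0, 0, 5, 7), 1)
  expect_equal(fisher_exact_2x2(3, 0, 4, 0), 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_exact_2x2 agrees with the enumeration oracle and fisher.test", {
  set.seed(1)
  for (i in 1:200) {
    tb <- rpois(4, sample(c(2, 10, 40), 1))
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
    if (sum(tb[1:2]) > 0 && sum(tb[3:4]) > 0 && sum(tb[c(1, 3)]) > 0 && sum(tb[c(2, 4)]) > 0) {
      ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-10)
    }
  }
})

test_that("junction P-value uses raw totals and is breed-swap symmetric", {
  expect_equal(junction_pvalue(30, 30, 30, 30), 1)
  expect_equal(junction_pvalue(50, 0, 0, 50), fisher_exact_2x2(50, 0, 0, 50))
  expect_true(is.na(junction_pvalue(0, 0, 0, 0)))
  set.seed(2)
  for (i in 1:20) {
    v <- rpois(4, 20)
    expect_equal(junction_pvalue(v[1], v[2], v[3], v[4]),
                 junction_pvalue(v[3], v[4], v[1], v[2]))
  }
})

test_that("coverage P-value tests exon-vs-rest-of-gene between conditions", {
  expect_equal(coverage_pvalue(50, 100, 50, 100), 1)
  expect_equal(coverage_pvalue(100, 100, 0, 100), fisher_exact_2x2(100, 0, 0, 100))
  expect_equal(coverage_pvalue(30, 90, 10, 80), coverage_pvalue(10, 80, 30, 90))
  expect_error(coverage_pvalue(101, 100, 0, 100), "exceeds")
})

test_that("Fisher's method combination follows the chi-square(4) closed form", {
  expect_equal(combine_pvalues(1, 1), 1)
  # closed form: S(x) = exp(-x/2) * (1 + x/2) at x = -2*log(p1*p2)
  x <- -2 * log(0.05 * 0.05)
  expect_equal(combine_pvalues(0.05, 0.05), exp(-x / 2) * (1 + x / 2))
  expect_equal(combine_pvalues(0.05, 0.05), 0.01747866, tolerance = 1e-6)
  # monotone: decreasing either input never increases the output
  grid <- c(1e-6, 1e-3, 0.05, 0.5, 1)
  for (p2 in grid) {
    out <- combine_pvalues(grid, p2)
    expect_true(all(diff(out) >= 0))
  }
  expect_error(combine_pvalues(0, 0.5), "0, 1")
})

test_that("BH adjustment reproduces the step-up formula and keeps bounds", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  # step-up formula computed independently
  o <- order(p)
  qs <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(q[o], pmin(qs, 1))
  # NA entries stay NA and do not count as tests
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
})

test_that("fold rule implements the >=4-fold and exclusivity clauses", {
  r <- fold_rule(0.8, 0.2)
  expect_equal(r$fold, 4)
  expect_true(r$passes)
  expect_false(r$breed_exclusive)
  r <- fold_rule(0.5, 0.5)
  expect_equal(r$fold, 1)
  expect_false(r$passes)
  r <- fold_rule(0.3, 0)
  expect_true(r$breed_exclusive && r$passes && is.infinite(r$fold))
  r <- fold_rule(0, 0)
  expect_false(r$passes)
  expect_true(is.na(r$fold))
  # swap inverts nothing but the direction
  expect_equal(fold_rule(0.8, 0.1)$fold, fold_rule(0.1, 0.8)$fold)
})

test_that("significance tiers AND the adjusted P with the fold rule", {
  expect_equal(call_significance(0.2, TRUE), "NS")
  expect_equal(call_significance(0.03, TRUE), "SIG")
  expect_equal(call_significance(0.005, TRUE), "EXT")
  expect_equal(call_significance(0.001, FALSE), "NS")
  expect_equal(call_significance(NA, TRUE), "NS")
})

test_that("diff_splice is label-swap symmetric in P-values and inverts fold", {
  cfg <- all_types_config(2L, psi_a = 0.9, psi_b = 0.4, event_depth = 300, seed = 13)
  ann <- generate_annotation(cfg)
  ev <- detect_events(ann$exons)
  sim <- simulate_counts(ann$truth, cfg)
  fwd <- diff_splice(ev, sim$junctions, sim$samples_a, sim$samples_b,
                     coverage = sim$coverage)
  rev <- diff_splice(ev, sim$junctions, sim$samples_b, sim$samples_a,
                     coverage = sim$coverage)
  expect_equal(fwd$p_junction, rev$p_junction)
  expect_equal(fwd$p_coverage, rev$p_coverage)
  expect_equal(fwd$p_combined, rev$p_combined)
  expect_equal(fwd$fold, rev$fold)
  expect_equal(fwd$psi_a, rev$psi_b)
})

test_that("strongly differential events are detected with near-complete power", {
  cfg <- sim_config(events_per_type = c(cassette = 60L), psi_a = 0.9, psi_b = 0.1,
                    event_depth = 500, seed = 17)
  ann <- generate_annotation(cfg)
  ev <- detect_events(ann$exons)
  sim <- simulate_counts(ann$truth, cfg)
  res <- diff_splice(ev, sim$junctions, sim$samples_a, sim$samples_b,
                     coverage = sim$coverage)
  expect_gte(mean(res$tier %in% c("SIG", "EXT")), 0.9)
  expect_true(all(res$fold >= 4 | res$breed_exclusive, na.rm = TRUE))
})
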