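test_that("pore bounds bracket the ladder gap for every call pattern", {
  lad <- table1_ladder()
  radii <- lad$rg_nm
  # independent oracle: enumerate, close monotonically, read off the gap
  for (bits in 0:15) {
    entered <- as.logical(intToBits(bits)[1:4])
    calls <- Map(fake_call, lad$label, as.list(entered))
    closed <- if (any(entered)) radii <= max(radii[entered]) else entered
    exp_lower <- if (any(closed)) max(radii[closed]) else 0
    exp_upper <- if (all(closed)) Inf else min(radii[!closed])
    est <- suppressWarnings(infer_pore_bounds(calls, lad))
    expect_equal(est$lower_bound_nm, exp_lower)
    expect_equal(est$upper_bound_nm, exp_upper)
    if (is.finite(est$upper_bound_nm) && est$lower_bound_nm > 0)
      expect_lt(est$lower_bound_nm, est$upper_bound_nm)
  }
})

test_that("worked interval examples: short pulses, long pulses, no entry", {
  lad <- table1_ladder()
  short <- infer_pore_bounds(Map(fake_call, lad$label,
                                 list(TRUE, FALSE, FALSE, FALSE)), lad)
  expect_equal(round(short$lower_bound_nm, 2), 0.77)
  expect_equal(round(short$upper_bound_nm, 2), 1.59)
  long <- infer_pore_bounds(Map(fake_call, lad$label,
                                list(TRUE, TRUE, TRUE, TRUE)), lad)
  expect_equal(round(long$lower_bound_nm, 2), 5.11)
  expect_equal(long$upper_bound_nm, Inf)
  none <- infer_pore_bounds(Map(fake_call, lad$label,
                                list(FALSE, FALSE, FALSE, FALSE)), lad)
  expect_equal(none$lower_bound_nm, 0)
  expect_equal(round(none$upper_bound_nm, 2), 0.77)
})

test_that("non-monotone patterns are flagged and closed, idempotently", {
  lad <- table1_ladder()
  calls <- Map(fake_call, lad$label, list(FALSE, TRUE, FALSE, FALSE))
  expect_warning(est <- infer_pore_bounds(calls, lad), "non-monotone")
  expect_true(est$non_monotone)
  # bounds equal those of the already-closed pattern {3k in, 10k in}
  closed_calls <- Map(fake_call, lad$label, list(TRUE, TRUE, FALSE, FALSE))
  est2 <- infer_pore_bounds(closed_calls, lad)
  expect_false(est2$non_monotone)
  expect_equal(est$lower_bound_nm, est2$lower_bound_nm)
  expect_equal(est$upper_bound_nm, est2$upper_bound_nm)
  # unknown probe and empty calls are errors
  expect_error(infer_pore_bounds(list(fake_call("500 kDa", TRUE)), lad),
               "absent")
  expect_error(infer_pore_bounds(list(), lad))
})

test_that("penetration calls require both effect size and significance", {
  set.seed(101)
  mk <- function(level, n = 15, sd = 0.02)
    fake_treatment(matrix(pmax(rnorm(n * 10, level, sd), 0), n, 10))
  treated <- mk(0.45); control <- mk(0.02)
  call <- call_penetration(treated, control, probe_label = "3 kDa")
  expect_true(call$entered_cytoplasm)
  expect_gt(call$score, 0.4)
  expect_lt(call$p_value, 0.05)
  # large but non-significant effect in a pathological 2-cell sample
  noisy_t <- fake_treatment(matrix(c(rep(0.9, 10), rep(0.0, 10)), 2, 10,
                                   byrow = TRUE))
  noisy_c <- fake_treatment(matrix(rep(0.02, 20), 2, 10))
  expect_false(call_penetration(noisy_t, noisy_c)$entered_cytoplasm)
  # significant but negligible effect fails the theta condition
  tiny_t <- mk(0.05, sd = 0.001); tiny_c <- mk(0.02, sd = 0.001)
  tiny <- call_penetration(tiny_t, tiny_c)
  expect_lt(tiny$p_value, 0.05)
  expect_false(tiny$entered_cytoplasm)
  expect_error(call_penetration(treated, NULL), "control")
})

test_that("the null comparison rarely produces a false entry", {
  set.seed(202)
  false_calls <- vapply(1:20, function(i) {
    a <- fake_treatment(matrix(pmax(rnorm(150, 0.02, 0.02), 0), 15, 10))
    b <- fake_treatment(matrix(pmax(rnorm(150, 0.02, 0.02), 0), 15, 10))
    call_penetration(a, b)$entered_cytoplasm
  }, logical(1))
  expect_lte(sum(false_calls), 1)
})

test_that("wall entry is called from the wall ratio independently", {
  t_wall <- fake_treatment(matrix(0.01, 12, 10), wall_ratios = rep(2.5, 12))
  t_ctrl <- fake_treatment(matrix(0.01, 12, 10), wall_ratios = rep(0.1, 12))
  call <- call_penetration(t_wall, t_ctrl, probe_label = "3 kDa")
  expect_true(call$entered_wall)
  expect_false(call$entered_cytoplasm)
  expect_false(call_penetration(t_ctrl, t_ctrl)$entered_wall)
})

test_that("study summaries tabulate intervals and wall permeability", {
  lad <- table1_ladder()
  e1 <- infer_pore_bounds(Map(fake_call, lad$label,
                              list(TRUE, FALSE, FALSE, FALSE),
                              wall = list(TRUE, FALSE, FALSE, FALSE),
                              treatment = "PEF 5us"), lad)
  e2 <- infer_pore_bounds(Map(fake_call, lad$label,
                              list(TRUE, TRUE, TRUE, TRUE),
                              wall = list(TRUE, TRUE, TRUE, TRUE),
                              treatment = "PEF 10us"), lad)
  rep <- summarize_study(list(e1, e2))
  expect_equal(nrow(rep$table), 2)
  expect_equal(rep$table$interval,
               c("between 0.77 and 1.59 nm", "at least 5.11 nm"))
  expect_equal(dim(rep$wall_matrix), c(2, 4))
  expect_true(all(rep$wall_matrix["PEF 10us", ]))
  js <- report_to_json(rep)
  expect_match(as.character(js), "unbounded")
  expect_match(as.character(js), "PEF 5us")
  # degenerate inputs
  empty <- summarize_study(list())
  expect_equal(nrow(empty$table), 0)
  single <- summarize_study(list(e1))
  expect_equal(nrow(single$table), 1)
})
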