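test_that("fold_change follows the pseudocounted ratio formula", {
  expect_equal(fold_change(10, 10, 0.5)$fc, 1)
  expect_equal(fold_change(10, 10, 0.5)$log2fc, 0)
  expect_equal(fold_change(20, 10, 0)$fc, 2)
  expect_equal(fold_change(0, 0, 0.5)$fc, 1)   # degenerate zeros
  expect_error(fold_change(-1, 2), ">= 0")
  expect_error(fold_change(1, 0, pseudocount = 0), "pseudocount")
})

test_that("is_changed is symmetric on the ratio scale with inclusive bounds", {
  expect_true(is_changed(1.6, 0.5))
  expect_true(is_changed(0.6, 0.5))      # 0.6 <= 1/1.5
  expect_true(is_changed(1.5, 0.5))      # boundary inclusive
  expect_true(is_changed(1 / 1.5, 0.5))  # symmetric boundary
  expect_false(is_changed(1.49, 0.5))
  expect_false(is_changed(0.7, 0.5))
  # mouse-threshold worked cases
  expect_false(is_changed(1.0, 0.25))
  expect_true(is_changed(1.3, 0.25))
  expect_false(is_changed(0.82, 0.25))   # 0.82 > 1/1.25 = 0.8
})

fc_tab <- function(...) {
  v <- c(...)
  fold_change(mean_case = v, mean_control = rep(1, length(v)), pseudocount = 0,
              mirna_id = names(v))
}

test_that("human_candidate_filter implements both-rule and single-rule", {
  t <- selection_thresholds()
  # both changed > 50%
  expect_equal(human_candidate_filter(fc_tab(m = 1.6), fc_tab(m = 1.7), t), "m")
  # single >= 2-fold with the other inside the no-change band
  expect_equal(human_candidate_filter(fc_tab(m = 2.5), fc_tab(m = 1.05), t), "m")
  # neither branch
  expect_equal(human_candidate_filter(fc_tab(m = 1.6), fc_tab(m = 1.1), t),
               character())
  # big in one, other moderately changed (outside band, below both_change):
  # fails the legend's stricter form
  expect_equal(human_candidate_filter(fc_tab(m = 2.5), fc_tab(m = 1.3), t),
               character())
  expect_error(human_candidate_filter(fc_tab(a = 1), fc_tab(b = 1), t),
               "no miRNAs")
})

test_that("mouse_filter keeps >= 25% symmetric changes and warns on missing", {
  t <- selection_thresholds()
  fcm <- fc_tab(up = 1.3, flat = 1.0, down = 0.82, down2 = 0.79)
  expect_equal(mouse_filter(c("up", "flat", "down", "down2"), fcm, t),
               c("up", "down2"))
  expect_warning(out <- mouse_filter(c("up", "ghost"), fcm, t), "ghost")
  expect_equal(out, "up")
})

test_that("direction_filter requires identical nonzero signs", {
  ids <- "m"
  expect_equal(direction_filter(ids, fc_tab(m = 1.6), fc_tab(m = 1.8),
                                fc_tab(m = 1.3)), "m")
  expect_equal(direction_filter(ids, fc_tab(m = 1.6), fc_tab(m = 1.8),
                                fc_tab(m = 0.7)), character())
  # fc exactly 1 has no sign
  expect_equal(direction_filter(ids, fc_tab(m = 1.6), fc_tab(m = 1.0),
                                fc_tab(m = 1.3)), character())
  expect_equal(direction_filter(ids, fc_tab(m = 0.5), fc_tab(m = 0.6),
                                fc_tab(m = 0.7)), "m")
})

test_that("paralog_filter drops seed-family members and keeps unique seeds", {
  seqs <- c(cand = "AAUAAAGUCCAAAAAAAAAAAA",
            twin = "GAUAAAGUGGAAAAAAAAAAAA",   # same nt 2-8: AUAAAGU
            other = "ACGUACGUACGUAAAAAAAAAA")
  catalog <- mirna_catalog(seqs)
  expect_equal(paralog_filter(c("cand", "other"), catalog), "other")
  # a candidate is not its own paralog
  expect_equal(paralog_filter("other", catalog), "other")
  expect_error(paralog_filter("missing", catalog), "without a mature sequence")
})

test_that("select_candidates returns empty set when nothing changes", {
  ids <- paste0("m", 1:5)
  rpm <- matrix(100, 5, 4, dimnames = list(ids, paste0("s", 1:4)))
  groups <- data.frame(sample_id = paste0("s", 1:4),
                       group = rep(c("case", "control"), each = 2))
  seqs <- setNames(replicate(5, paste(sample(c("A","C","G","U"), 22, TRUE),
                                      collapse = "")), ids)
  rep <- select_candidates(rpm, rpm, rpm, groups, groups, groups,
                           mirna_catalog(seqs))
  expect_length(rep$candidates, 0)
  expect_equal(unname(rep$funnel["universe"]), 5L)
})

test_that("select_candidates recovers noise-free planted effects exactly", {
  # 4 planted concordant miRNAs with |log2fc| >= 1 (human) and >= 0.4
  # (mouse), unique seeds, noise-free group means
  set.seed(42)
  ids <- paste0("m", 1:10)
  planted <- ids[1:4]
  l2h <- setNames(rep(0, 10), ids); l2h[planted] <- c(1.2, 2, -1.2, -2)
  l2m <- setNames(rep(0, 10), ids); l2m[planted] <- c(0.5, 0.6, -0.5, -0.6)
  mk <- function(l2) {
    base <- 100
    m <- cbind(matrix(base * 2^rep(l2, 3), 10, 3),
               matrix(base, 10, 3))
    dimnames(m) <- list(ids, paste0("s", 1:6))
    m
  }
  groups <- data.frame(sample_id = paste0("s", 1:6),
                       group = rep(c("case", "control"), each = 3))
  seqs <- character(10)
  repeat {
    seqs <- vapply(1:10, function(i)
      paste(sample(c("A","C","G","U"), 22, TRUE), collapse = ""), character(1))
    if (!anyDuplicated(substr(seqs, 2, 8))) break
  }
  names(seqs) <- ids
  rep <- select_candidates(mk(l2h), mk(l2h), mk(l2m), groups, groups, groups,
                           mirna_catalog(seqs))
  expect_setequal(rep$candidates, planted)
})

test_that("funnel stages are nested and flags consistent", {
  cfg <- synthetic_config(seed = 8)
  sim <- simulate_counts(cfg)
  catalog <- mirna_catalog(simulate_mirna_catalog(cfg))
  rep <- select_candidates(rpm_normalize(sim$human1$counts),
                           rpm_normalize(sim$human2$counts),
                           rpm_normalize(sim$mouse$counts),
                           sim$human1$groups, sim$human2$groups,
                           sim$mouse$groups, catalog)
  f <- rep$funnel
  expect_true(all(diff(unname(f)) <= 0))   # monotone funnel
  tab <- rep$table
  # final flag equals the conjunction of the recorded flags
  recomputed <- tab$expressed_ds1 & tab$expressed_ds2 & tab$expressed_mouse &
    (tab$both_rule | tab$single_rule) & tab$mouse_rule &
    tab$direction_consistent & tab$paralog_free
  expect_equal(tab$candidate, recomputed)
})

test_that("threshold monotonicity: stricter thresholds never grow the set", {
  inst <- random_cascade_instance(15, seed = 99)
  run <- function(t) select_candidates(
    inst$ds1$rpm, inst$ds2$rpm, inst$mouse$rpm, inst$ds1$groups,
    inst$ds2$groups, inst$mouse$groups, inst$catalog, t)$candidates
  base <- run(selection_thresholds())
  for (t in list(selection_thresholds(both_change = 0.8),
                 selection_thresholds(single_fold = 3),
                 selection_thresholds(mouse_change = 0.5))) {
    expect_true(all(run(t) %in% base))
  }
})

test_that("selection_thresholds validates its invariants", {
  expect_error(selection_thresholds(both_change = 1.2), "single_fold")
  expect_error(selection_thresholds(no_change_band = 0.6), "no_change_band")
  expect_error(selection_thresholds(min_rpm = -1), "positive")
})
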