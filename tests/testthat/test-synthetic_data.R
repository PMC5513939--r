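no_planting <- function(...) {
  synthetic_config(
    planted_mirnas = data.frame(mirna_id = character(),
                                log2fc_human1 = numeric(),
                                log2fc_human2 = numeric(),
                                log2fc_mouse = numeric()), ...)
}

test_that("generators are pure functions of the config", {
  cfg <- synthetic_config(seed = 42)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a, b)
  expect_identical(simulate_mirna_catalog(cfg), simulate_mirna_catalog(cfg))
  expect_identical(simulate_expression_ratios(cfg),
                   simulate_expression_ratios(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # different seeds differ
  expect_false(identical(simulate_counts(synthetic_config(seed = 43)), a))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_counts(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("simulated cohorts have the stated sizes and group labels", {
  sim <- simulate_counts(synthetic_config(seed = 1))
  expect_equal(ncol(sim$human1$counts), 12L)
  expect_equal(ncol(sim$human2$counts), 13L)  # 6 cases + 7 controls
  expect_equal(ncol(sim$mouse$counts), 6L)
  expect_equal(sum(sim$human2$groups$group == "control"), 7L)
  expect_equal(nrow(sim$human1$counts), 300L)
  expect_true(all(sim$human1$counts >= 0))
  expect_true(all(sim$human1$counts == floor(sim$human1$counts)))
})

test_that("zero planting and zero dispersion give balanced group means", {
  cfg <- no_planting(seed = 3, nb_dispersion = 0)
  sim <- simulate_counts(cfg)
  rpm <- rpm_normalize(sim$human1$counts)
  fc <- fold_change_table(rpm, sim$human1$groups)
  high <- fc[fc$mean_control > 1000, ]
  # Poisson-only noise at high expression: ratios hug 1
  expect_lt(max(abs(high$log2fc)), 0.35)
})

test_that("planted fold changes are recovered as dispersion shrinks", {
  cfg <- synthetic_config(seed = 11, nb_dispersion = 0.001)
  sim <- simulate_counts(cfg)
  for (ds in c("human1", "human2")) {
    fc <- fold_change_table(rpm_normalize(sim[[ds]]$counts), sim[[ds]]$groups)
    planted <- cfg$planted_mirnas
    est <- fc$log2fc[match(planted$mirna_id, fc$mirna_id)]
    truth <- planted[[paste0("log2fc_", ds)]]
    expect_equal(est, truth, tolerance = 0.15)
  }
})

test_that("planted miRNA seeds are unique in the simulated catalog", {
  for (s in c(2, 9, 31)) {
    cfg <- synthetic_config(seed = s)
    catalog <- mirna_catalog(simulate_mirna_catalog(cfg))
    fam_size <- table(catalog$family_id)
    planted_fams <- catalog$family_id[match(cfg$planted_mirnas$mirna_id,
                                            catalog$mirna_id)]
    expect_true(all(fam_size[planted_fams] == 1L))
  }
})

test_that("simulate_utrs plants recoverable motifs and reports a manifest", {
  cfg <- synthetic_config(seed = 4)
  mir <- "AAUAAAGUCCAAGGAAGGAAGG"
  sim <- simulate_utrs(cfg, mir, n_utrs = 30, utr_length = 400, n_planted = 6)
  expect_equal(nrow(sim$manifest), 6L)
  expect_equal(nchar(sim$utrs[[1]]), 400L)
  motif <- seed_match_motif(mir)
  for (j in seq_len(nrow(sim$manifest))) {
    utr <- sim$utrs[[sim$manifest$utr_id[j]]]
    pos <- sim$manifest$position[j]
    expect_equal(substr(utr, pos + 1, pos + 7), motif)
  }
  # zero planting -> empty manifest
  none <- simulate_utrs(cfg, mir, n_utrs = 5, utr_length = 100, n_planted = 0)
  expect_equal(nrow(none$manifest), 0L)
})

test_that("background 6mer-core hits match the uniform closed form", {
  # expected false-positive core count per UTR ~ (L - 5) * (1/4)^6
  cfg <- synthetic_config(seed = 12)
  mir <- "ACGUACGUACGUACGUACGUAC"
  sim <- simulate_utrs(cfg, mir, n_utrs = 400, utr_length = 500, n_planted = 0)
  hits <- vapply(sim$utrs, function(u) nrow(scan_utr(u, mir)), numeric(1))
  expected <- (500 - 5) * (1 / 4)^6
  # Poisson-ish: mean over 400 UTRs within 4 standard errors
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(hits) - expected), 4 * se + 0.02)
})

test_that("expression ratios plant below-cutoff targets on a log-normal background", {
  cfg <- synthetic_config(seed = 21)
  expr <- simulate_expression_ratios(cfg)
  expect_equal(nrow(expr$ratios), 10000L)
  expect_length(expr$targets, 947L)
  expect_length(expr$planted_targets, 100L)
  planted_ratios <- expr$ratios$ratio[expr$ratios$gene_id %in% expr$planted_targets]
  expect_true(all(planted_ratios < 0.8))
  # background pass fraction tracks the log-normal CDF at 0.8
  bg <- expr$ratios$ratio[!(expr$ratios$gene_id %in% expr$planted_targets)]
  expected_frac <- pnorm(log(0.8) / cfg$ratio_sdlog)
  expect_lt(abs(mean(bg < 0.8) - expected_frac), 0.02)
})

test_that("simulate_gene_sets plants an enriched term with tunable strength", {
  cfg <- synthetic_config(seed = 14)
  expr <- simulate_expression_ratios(cfg)
  sets <- simulate_gene_sets(cfg, expr$planted_targets, expr$ratios$gene_id)
  expect_length(sets, 50L)
  expect_true(all(vapply(sets, function(s) length(s$members) >= 1L, logical(1))))
  planted <- sets$GO_SYN_PLANTED
  expect_equal(length(planted$members), 150L)
  overlap <- length(intersect(planted$members, expr$planted_targets))
  # at least the deliberately planted 60% of 150; the random remainder may
  # add a couple of planted genes by chance
  expect_gte(overlap, round(0.6 * 150))
  expect_lte(overlap, round(0.6 * 150) + 5)
  # zero strength -> no preferential overlap beyond chance
  cfg0 <- synthetic_config(seed = 14, enrichment_strength = 0)
  sets0 <- simulate_gene_sets(cfg0, expr$planted_targets, expr$ratios$gene_id)
  overlap0 <- length(intersect(sets0$GO_SYN_PLANTED$members,
                               expr$planted_targets))
  expect_lt(overlap0, 10)
})

test_that("simulate_qpcr plants the RQ fold change", {
  # sigma -> 0 limit: estimated treated/untreated RQ ratio equals the fold
  cfg <- synthetic_config(seed = 5, qpcr_fold = 2, qpcr_sigma = 1e-8)
  q <- simulate_qpcr(cfg)
  rq <- relative_quantity(q, "untreated")
  expect_equal(mean(rq$rq[rq$group == "treated"]), 2, tolerance = 1e-6)
  # null fold: group means ~ 1
  cfg1 <- synthetic_config(seed = 5, qpcr_fold = 1, qpcr_sigma = 0.05)
  rq1 <- relative_quantity(simulate_qpcr(cfg1), "untreated")
  expect_equal(mean(rq1$rq[rq1$group == "treated"]), 1, tolerance = 0.2)
})

test_that("simulate_bundle writes a complete, reloadable bundle", {
  dir <- tempfile("bundle")
  cfg <- synthetic_config(seed = 2)
  bundle <- simulate_bundle(cfg, outdir = dir)
  files <- c("counts_human1.tsv", "groups_human1.tsv", "counts_human2.tsv",
             "groups_human2.tsv", "counts_mouse.tsv", "groups_mouse.tsv",
             "mirna.fa", "utrs.fa", "ratios.tsv", "targets.txt",
             "gene_sets.gmt", "qpcr.tsv", "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))
  # round-trip: written tables equal the in-memory bundle
  expect_equal(read_table_tsv(file.path(dir, "counts_human1.tsv"),
                              integral = TRUE),
               bundle$counts$human1$counts)
  fa <- read_fasta(file.path(dir, "mirna.fa"))
  expect_equal(unname(fa[names(bundle$mirna_sequences)]),
               unname(bundle$mirna_sequences))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$planted_term, "GO_SYN_PLANTED")
  expect_setequal(manifest$planted_mirnas$mirna_id,
                  cfg$planted_mirnas$mirna_id)
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(synthetic_config(n_mirnas = 2), "planted")
  expect_error(synthetic_config(nb_dispersion = -1), "dispersion")
  expect_error(synthetic_config(n_targets = 20000), "n_targets")
  expect_error(synthetic_config(enrichment_strength = 2), "enrichment_strength")
  expect_error(synthetic_config(n_mouse = c(case = 3, control = 4)), "paired")
})
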