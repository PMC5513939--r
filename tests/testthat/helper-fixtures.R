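# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the cascade oracle re-reads the selection
# rules literally per miRNA; the hypergeometric oracle enumerates subsets.

options(mircascade.verbose = FALSE)

# --- tiny in-code file fixtures ---------------------------------------------

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, sep = "\n")
  path
}

# A miRNA x sample matrix with given dimensions, filled deterministically.
toy_counts <- function(n_mirna = 4, n_sample = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_mirna * n_sample, 50), nrow = n_mirna,
              dimnames = list(paste0("miR-", seq_len(n_mirna)),
                              paste0("s", seq_len(n_sample))))
  storage.mode(m) <- "double"
  m
}

# --- independent cascade oracle (acceptance criterion: oracle equivalence) --

# Evaluates the written selection rules per miRNA, straight from their
# definitions, against raw RPM matrices. No calls into the package's filter
# functions.
brute_force_cascade <- function(rpm1, rpm2, rpm_mouse, groups1, groups2,
                                groups_mouse, catalog,
                                min_rpm = 5, both_change = 0.5,
                                single_fold = 2, no_change_band = 0.2,
                                mouse_change = 0.25, pseudocount = 0.5) {
  group_means <- function(rpm, groups, lab) {
    cols <- groups$sample_id[groups$group == lab]
    rowMeans(rpm[, colnames(rpm) %in% cols, drop = FALSE])
  }
  fc_of <- function(rpm, groups) {
    (group_means(rpm, groups, "case") + pseudocount) /
      (group_means(rpm, groups, "control") + pseudocount)
  }
  changed <- function(fc, f) fc >= 1 + f || fc <= 1 / (1 + f)
  fc1 <- fc_of(rpm1, groups1); fc2 <- fc_of(rpm2, groups2)
  fcm <- fc_of(rpm_mouse, groups_mouse)
  universe <- intersect(intersect(rownames(rpm1), rownames(rpm2)),
                        rownames(rpm_mouse))
  seed_of <- function(seq) substr(seq, 2, 8)
  keep <- character()
  for (m in universe) {
    if (!(mean(rpm1[m, ]) > min_rpm)) next
    if (!(mean(rpm2[m, ]) > min_rpm)) next
    if (!(mean(rpm_mouse[m, ]) > min_rpm)) next
    f1 <- fc1[[m]]; f2 <- fc2[[m]]; fm <- fcm[[m]]
    both <- changed(f1, both_change) && changed(f2, both_change)
    big1 <- f1 >= single_fold || f1 <= 1 / single_fold
    big2 <- f2 >= single_fold || f2 <= 1 / single_fold
    single <- (big1 && !big2 && !changed(f2, no_change_band)) ||
      (big2 && !big1 && !changed(f1, no_change_band))
    if (!(both || single)) next
    if (!changed(fm, mouse_change)) next
    s1 <- sign(log2(f1)); s2 <- sign(log2(f2)); sm <- sign(log2(fm))
    if (!(s1 != 0 && s1 == s2 && s1 == sm)) next
    my_seed <- seed_of(catalog$sequence[catalog$mirna_id == m])
    others <- catalog$sequence[catalog$mirna_id != m]
    if (any(vapply(others, seed_of, character(1)) == my_seed)) next
    keep <- c(keep, m)
  }
  keep
}

# Random RPM-table instance for the oracle-equivalence checks: small
# universes, RPM scaled so expression filters bite for some miRNAs.
random_cascade_instance <- function(n_mirna = 12, seed = 1) {
  set.seed(seed)
  ids <- paste0("m", seq_len(n_mirna))
  mk_rpm <- function(n_case, n_control) {
    n <- n_case + n_control
    base <- exp(runif(n_mirna, log(0.5), log(5000)))
    m <- matrix(base * exp(rnorm(n_mirna * n, 0, 0.8)), nrow = n_mirna,
                dimnames = list(ids, paste0("s", seq_len(n))))
    list(rpm = m,
         groups = data.frame(sample_id = colnames(m),
                             group = rep(c("case", "control"),
                                         c(n_case, n_control))))
  }
  # catalog with occasional shared seeds (paralogs)
  seqs <- vapply(seq_len(n_mirna), function(i)
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
    character(1))
  if (n_mirna >= 4 && runif(1) < 0.7) {
    # force one paralog pair: same nucleotides 2-8
    substr(seqs[2], 2, 8) <- substr(seqs[1], 2, 8)
  }
  names(seqs) <- ids
  list(ds1 = mk_rpm(3, 3), ds2 = mk_rpm(3, 4), mouse = mk_rpm(2, 2),
       catalog = mircascade::mirna_catalog(seqs))
}

# --- hypergeometric enumeration oracle --------------------------------------

# P(X >= k) by exhaustive enumeration of all size-n subsets of a universe
# with K annotated elements. Only feasible for small N.
hypergeom_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else stop("infeasible"))
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)  # elements 1..K are the annotated ones
  mean(overlap >= k)
}

# --- rank-sum permutation oracle (via the null distribution in base R) ------

rank_sum_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  p_le <- stats::pwilcox(u, nx, ny)
  p_ge <- 1 - if (u >= 1) stats::pwilcox(u - 1, nx, ny) else 0
  min(1, 2 * min(p_le, p_ge))
}

# Bundle builder used by pipeline/CLI tests: writes a full synthetic bundle
# and the matching run_config.
build_bundle_config <- function(seed, dir, outdir = file.path(dir, "out")) {
  cfg <- synthetic_config(seed = seed)
  simulate_bundle(cfg, outdir = dir)
  run_config(
    counts_human1 = file.path(dir, "counts_human1.tsv"),
    groups_human1 = file.path(dir, "groups_human1.tsv"),
    counts_human2 = file.path(dir, "counts_human2.tsv"),
    groups_human2 = file.path(dir, "groups_human2.tsv"),
    counts_mouse = file.path(dir, "counts_mouse.tsv"),
    groups_mouse = file.path(dir, "groups_mouse.tsv"),
    mirna_fasta = file.path(dir, "mirna.fa"),
    utr_fasta = file.path(dir, "utrs.fa"),
    ratios = file.path(dir, "ratios.tsv"),
    targets = file.path(dir, "targets.txt"),
    gmt = file.path(dir, "gene_sets.gmt"),
    outdir = outdir)
}
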