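# The cross-dataset, cross-species miRNA candidate cascade: expression
# filter -> per-dataset fold change -> two-cohort human rule -> mouse-model
# concordance filter -> direction-consistency filter -> paralog exclusion.

#' Selection thresholds for the candidate cascade
#'
#' Bundles and validates the tunable thresholds of the selection funnel.
#' "More than f change" is interpreted symmetrically on the ratio scale:
#' up-regulation `fc >= 1 + f` or down-regulation `fc <= 1/(1 + f)`,
#' boundaries inclusive.
#'
#' @param min_rpm Mean-RPM expression threshold per dataset (strict, default 5).
#' @param both_change Fractional change required in both human datasets
#'   (default 0.50, i.e. more than 50% change).
#' @param single_fold Fold ratio qualifying as "highly altered" in a single
#'   human dataset (default 2.0).
#' @param no_change_band Fractional band within which the other human dataset
#'   counts as unchanged for the single-dataset rule (default 0.20).
#' @param mouse_change Fractional change required in the mouse model
#'   (default 0.25).
#' @param pseudocount RPM pseudocount added to both group means before the
#'   ratio (default 0.5).
#' @return An object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(min_rpm = 5, both_change = 0.50,
                                 single_fold = 2.0, no_change_band = 0.20,
                                 mouse_change = 0.25, pseudocount = 0.5) {
  t <- list(min_rpm = min_rpm, both_change = both_change,
            single_fold = single_fold, no_change_band = no_change_band,
            mouse_change = mouse_change, pseudocount = pseudocount)
  num <- vapply(t, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) stop_mc("selection_thresholds: all thresholds must be single numbers")
  if (any(unlist(t) <= 0)) stop_mc("selection_thresholds: all thresholds must be positive")
  if (!(both_change < single_fold - 1))
    stop_mc("selection_thresholds: both_change must be < single_fold - 1")
  if (!(no_change_band < both_change))
    stop_mc("selection_thresholds: no_change_band must be < both_change")
  structure(t, class = "selection_thresholds")
}

#' Per-miRNA fold change between group means
#'
#' `fc = (mean_case + pseudocount) / (mean_control + pseudocount)`; the
#' pseudocount protects against division by zero.
#'
#' @param mean_case,mean_control Non-negative group mean RPM vectors.
#' @param pseudocount RPM pseudocount (default 0.5).
#' @param mirna_id Optional id vector for the rows.
#' @return Data frame with columns `mirna_id`, `mean_case`, `mean_control`,
#'   `fc`, `log2fc`.
#' @export
fold_change <- function(mean_case, mean_control, pseudocount = 0.5,
                        mirna_id = NULL) {
  if (any(mean_case < 0) || any(mean_control < 0))
    stop_mc("fold_change: group means must be >= 0")
  if (pseudocount < 0) stop_mc("fold_change: pseudocount must be >= 0")
  if (pseudocount == 0 && any(mean_control == 0) )
    stop_mc("fold_change: zero control mean requires a positive pseudocount")
  if (is.null(mirna_id)) {
    mirna_id <- names(mean_case)
    if (is.null(mirna_id)) mirna_id <- as.character(seq_along(mean_case))
  }
  fc <- (mean_case + pseudocount) / (mean_control + pseudocount)
  data.frame(mirna_id = mirna_id, mean_case = unname(mean_case),
             mean_control = unname(mean_control), fc = unname(fc),
             log2fc = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Fold-change table for one dataset
#'
#' Computes per-group mean RPM from an RPM matrix and a sample-to-group
#' assignment, then calls [fold_change()].
#'
#' @param rpm RPM matrix (miRNAs x samples).
#' @param groups Data frame with columns `sample_id`, `group`.
#' @param case,control Group labels treated as case and control.
#' @param pseudocount RPM pseudocount.
#' @return Data frame as from [fold_change()], one row per miRNA.
#' @export
fold_change_table <- function(rpm, groups, case = "case", control = "control",
                              pseudocount = 0.5) {
  check_table_matrix(rpm, what = "rpm")
  missing_samples <- setdiff(colnames(rpm), groups$sample_id)
  if (length(missing_samples))
    stop_mc("fold_change_table: sample(s) without group label: %s",
            paste(missing_samples, collapse = ", "))
  grp <- groups$group[match(colnames(rpm), groups$sample_id)]
  case_cols <- grp == case
  control_cols <- grp == control
  if (!any(case_cols) || !any(control_cols))
    stop_mc("fold_change_table: need >= 1 sample in each of '%s' and '%s'",
            case, control)
  fold_change(rowMeans(rpm[, case_cols, drop = FALSE]),
              rowMeans(rpm[, control_cols, drop = FALSE]),
              pseudocount = pseudocount, mirna_id = rownames(rpm))
}

#' Symmetric change-magnitude predicate
#'
#' TRUE iff `fc >= 1 + frac` or `fc <= 1/(1 + frac)` — "more than
#' frac change" read symmetrically on the log-ratio scale, boundaries
#' inclusive.
#'
#' @param fc Fold-change ratio vector (> 0).
#' @param frac Fractional change (> 0).
#' @return Logical vector.
#' @export
is_changed <- function(fc, frac) {
  if (any(fc <= 0)) stop_mc("is_changed: fc must be > 0")
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0)
    stop_mc("is_changed: frac must be a single positive number")
  fc >= 1 + frac | fc <= 1 / (1 + frac)
}

# fc tables come in as data.frames from fold_change(); pull the named ratio
# vector restricted to `ids` (order preserved).
fc_vector <- function(fc_table, ids = NULL) {
  v <- stats::setNames(fc_table$fc, fc_table$mirna_id)
  if (!is.null(ids)) v <- v[ids]
  v
}

#' Two-cohort human candidate rule
#'
#' Keeps a miRNA iff it changed in both human datasets (more than
#' `both_change`), or was highly altered (`>= single_fold` or
#' `<= 1/single_fold`) in exactly one dataset while the other stayed within
#' the no-change band.
#'
#' @param fc1,fc2 Fold-change tables (from [fold_change_table()]) for the two
#'   human datasets.
#' @param thresholds A [selection_thresholds()] object.
#' @return Character vector of kept miRNA ids.
#' @export
human_candidate_filter <- function(fc1, fc2, thresholds = selection_thresholds()) {
  ids <- intersect(fc1$mirna_id, fc2$mirna_id)
  n_dropped <- length(union(fc1$mirna_id, fc2$mirna_id)) - length(ids)
  if (length(ids) == 0L)
    stop_mc("human_candidate_filter: fold-change tables share no miRNAs")
  if (n_dropped > 0L)
    mc_msg(sprintf("human_candidate_filter: %d miRNA(s) absent from one table dropped",
                   n_dropped))
  v1 <- fc_vector(fc1, ids)
  v2 <- fc_vector(fc2, ids)
  both <- is_changed(v1, thresholds$both_change) &
    is_changed(v2, thresholds$both_change)
  big1 <- v1 >= thresholds$single_fold | v1 <= 1 / thresholds$single_fold
  big2 <- v2 >= thresholds$single_fold | v2 <= 1 / thresholds$single_fold
  quiet1 <- !is_changed(v1, thresholds$no_change_band)
  quiet2 <- !is_changed(v2, thresholds$no_change_band)
  single <- (big1 & !big2 & quiet2) | (big2 & !big1 & quiet1)
  ids[both | single]
}

#' Mouse-model concordance filter
#'
#' Keeps candidates whose mouse fold change exceeds `mouse_change`
#' (symmetric, inclusive). Candidates absent from the mouse table are dropped
#' with a warning.
#'
#' @param ids Candidate miRNA ids.
#' @param fc_mouse Mouse fold-change table.
#' @param thresholds A [selection_thresholds()] object.
#' @return Character vector of kept miRNA ids.
#' @export
mouse_filter <- function(ids, fc_mouse, thresholds = selection_thresholds()) {
  missing <- setdiff(ids, fc_mouse$mirna_id)
  if (length(missing)) {
    warning(sprintf("mouse_filter: %d candidate(s) absent from mouse table dropped: %s",
                    length(missing), paste(missing, collapse = ", ")))
    ids <- setdiff(ids, missing)
  }
  if (length(ids) == 0L) return(character())
  ids[is_changed(fc_vector(fc_mouse, ids), thresholds$mouse_change)]
}

#' Direction-consistency filter
#'
#' Keeps candidates whose log2 fold change has the same nonzero sign in both
#' human datasets and the mouse model.
#'
#' @param ids Candidate miRNA ids (must be present in all three tables).
#' @param fc1,fc2,fc_mouse Fold-change tables.
#' @return Character vector of kept miRNA ids.
#' @export
direction_filter <- function(ids, fc1, fc2, fc_mouse) {
  if (length(ids) == 0L) return(character())
  for (tab in list(fc1, fc2, fc_mouse)) {
    if (!all(ids %in% tab$mirna_id))
      stop_mc("direction_filter: candidate(s) missing from a fold-change table")
  }
  s1 <- sign(log2(fc_vector(fc1, ids)))
  s2 <- sign(log2(fc_vector(fc2, ids)))
  sm <- sign(log2(fc_vector(fc_mouse, ids)))
  ids[s1 != 0 & s1 == s2 & s1 == sm]
}

#' Paralog (seed-family) exclusion filter
#'
#' Keeps a candidate iff no other miRNA in the supplied human catalog shares
#' its seed family (identical nucleotides 2-8). A candidate without a
#' catalog sequence is an error.
#'
#' @param ids Candidate miRNA ids.
#' @param catalog A [mirna_catalog()] data frame covering the human miRNA
#'   complement.
#' @return Character vector of kept miRNA ids.
#' @export
paralog_filter <- function(ids, catalog) {
  if (length(ids) == 0L) return(character())
  missing <- setdiff(ids, catalog$mirna_id)
  if (length(missing))
    stop_mc("paralog_filter: candidate(s) without a mature sequence: %s",
            paste(missing, collapse = ", "))
  fam_size <- table(catalog$family_id)
  fam <- catalog$family_id[match(ids, catalog$mirna_id)]
  ids[fam_size[fam] == 1L]
}

#' Run the full candidate-selection cascade
#'
#' Applies, in order: the per-dataset mean-RPM expression filter, per-dataset
#' fold changes, the two-cohort human rule, the mouse concordance filter, the
#' direction-consistency filter, and the paralog exclusion. Every
#' intermediate flag is recorded per miRNA, and the funnel cardinalities are
#' reported.
#'
#' @param rpm1,rpm2,rpm_mouse RPM matrices for human dataset 1, human
#'   dataset 2 and the mouse model.
#' @param groups1,groups2,groups_mouse Matching sample-to-group tables
#'   (`sample_id`, `group` with labels `case`/`control`).
#' @param catalog A [mirna_catalog()] data frame (paralog reference).
#' @param thresholds A [selection_thresholds()] object.
#' @param case,control Group labels used in all three group tables.
#' @return An object of class `candidate_report`: list with `table` (one row
#'   per miRNA in the shared universe, all stage flags), `candidates` (final
#'   id vector), `funnel` (named stage cardinalities), `fold_changes` (the
#'   three fold-change tables) and `thresholds`.
#' @export
select_candidates <- function(rpm1, rpm2, rpm_mouse, groups1, groups2,
                              groups_mouse, catalog,
                              thresholds = selection_thresholds(),
                              case = "case", control = "control") {
  universe <- Reduce(intersect, list(rownames(rpm1), rownames(rpm2),
                                     rownames(rpm_mouse)))
  if (length(universe) == 0L)
    stop_mc("select_candidates: RPM tables share no miRNAs")

  expressed1 <- mean_rpm_filter(rpm1, thresholds$min_rpm)
  expressed2 <- mean_rpm_filter(rpm2, thresholds$min_rpm)
  expressed_m <- mean_rpm_filter(rpm_mouse, thresholds$min_rpm)
  expressed_all <- Reduce(intersect,
                          list(universe, expressed1, expressed2, expressed_m))

  fc1 <- fold_change_table(rpm1, groups1, case, control, thresholds$pseudocount)
  fc2 <- fold_change_table(rpm2, groups2, case, control, thresholds$pseudocount)
  fcm <- fold_change_table(rpm_mouse, groups_mouse, case, control,
                           thresholds$pseudocount)

  human_pass <- intersect(human_candidate_filter(fc1, fc2, thresholds),
                          expressed_all)
  mouse_pass <- mouse_filter(human_pass, fcm, thresholds)
  dir_pass <- direction_filter(mouse_pass, fc1, fc2, fcm)
  final <- paralog_filter(dir_pass, catalog)

  v1 <- fc_vector(fc1, universe)
  v2 <- fc_vector(fc2, universe)
  vm <- fc_vector(fcm, universe)
  both_rule <- is_changed(v1, thresholds$both_change) &
    is_changed(v2, thresholds$both_change)
  big1 <- v1 >= thresholds$single_fold | v1 <= 1 / thresholds$single_fold
  big2 <- v2 >= thresholds$single_fold | v2 <= 1 / thresholds$single_fold
  single_rule <- (big1 & !big2 & !is_changed(v2, thresholds$no_change_band)) |
    (big2 & !big1 & !is_changed(v1, thresholds$no_change_band))
  s1 <- sign(log2(v1)); s2 <- sign(log2(v2)); sm <- sign(log2(vm))
  in_catalog <- universe %in% catalog$mirna_id
  fam_size <- table(catalog$family_id)
  fam <- catalog$family_id[match(universe, catalog$mirna_id)]
  paralog_free <- in_catalog & fam_size[fam] == 1L

  tab <- data.frame(
    mirna_id = universe,
    expressed_ds1 = universe %in% expressed1,
    expressed_ds2 = universe %in% expressed2,
    expressed_mouse = universe %in% expressed_m,
    fc_ds1 = unname(v1), fc_ds2 = unname(v2), fc_mouse = unname(vm),
    both_rule = unname(both_rule), single_rule = unname(single_rule),
    mouse_rule = unname(is_changed(vm, thresholds$mouse_change)),
    direction_consistent = unname(s1 != 0 & s1 == s2 & s1 == sm),
    paralog_free = unname(paralog_free),
    candidate = universe %in% final,
    stringsAsFactors = FALSE)

  structure(list(
    table = tab,
    candidates = final,
    funnel = c(universe = length(universe),
               expressed = length(expressed_all),
               human = length(human_pass),
               mouse = length(mouse_pass),
               direction = length(dir_pass),
               paralog = length(final)),
    fold_changes = list(ds1 = fc1, ds2 = fc2, mouse = fcm),
    thresholds = thresholds), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate selection cascade\n")
  cat(sprintf("  %-10s %d\n", names(x$funnel), x$funnel), sep = "")
  cat("Final candidates:",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
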