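# Seeded synthetic-data generators with planted signals. Each generator is
# a pure function of the config: one global seed fans out into fixed
# per-generator substreams so modules can be regenerated independently, and
# the caller's RNG state is never disturbed.

SUBSTREAMS <- c(catalog = 1L, counts_human1 = 2L, counts_human2 = 3L,
                counts_mouse = 4L, utrs = 5L, ratios = 6L, gene_sets = 7L,
                qpcr = 8L)

#' Configuration of a simulated study
#'
#' Fully determines one synthetic study: two human case/control small
#' RNA-seq cohorts (6 vs 6 and 6 cases vs 7 controls), a paired mouse cohort
#' (3 vs 3), a mature-miRNA catalog, UTRs with planted seed sites, a
#' gene-expression-ratio table with planted down-regulated target genes, GO
#' style gene sets with one planted enriched term, and qPCR Ct tables.
#'
#' Counts are negative binomial (Gamma-Poisson) around log-normal
#' miRNA-specific base abundances with per-sample library-size factors;
#' planted miRNAs multiply their case-group mean by `2^log2fc`. Defaults
#' plant four miRNAs at |log2fc| = 1.5 in all three datasets (two up, two
#' down) with seeds kept unique in the catalog, so the full cascade can
#' recover them.
#'
#' @param seed Global integer seed.
#' @param n_mirnas Catalog size (default 300).
#' @param n_human1,n_human2,n_mouse Named `c(case=, control=)` cohort sizes.
#'   The mouse cohort is simulated as sibling pairs (case j and control j
#'   share a pair-specific biological factor), so its case and control sizes
#'   must be equal when `mouse_paired` is TRUE.
#' @param planted_mirnas Data frame with columns `mirna_id`, `log2fc_human1`,
#'   `log2fc_human2`, `log2fc_mouse` (NULL for the default 4 planted miRNAs;
#'   zero-row frame for no planting).
#' @param nb_dispersion Shared NB dispersion (variance = mu + dispersion *
#'   mu^2); 0 gives Poisson counts (default 0.1).
#' @param mouse_paired Simulate the mouse cohort as sibling pairs
#'   (default TRUE). The biological dispersion is then split between a
#'   pair-shared gamma factor and residual NB noise.
#' @param pair_dispersion_fraction Fraction of `nb_dispersion` carried by the
#'   pair-shared factor in the paired design (default 0.5).
#' @param library_size_mean,library_size_cv Mean and CV of per-sample
#'   assigned-read totals (default 5e6 reads, 20%).
#' @param base_weight_meanlog,base_weight_sdlog Log-normal parameters of the
#'   background miRNA abundance weights.
#' @param base_weight_cap Upper cap on background weights. Keeps any single
#'   miRNA's library share small so that, after RPM normalization, background
#'   proportion fold changes stay near 1 as the generator contract states
#'   (extreme compositional dominance is deliberately not emulated).
#' @param planted_weight Abundance weight given to planted miRNAs (well
#'   above the expression filter).
#' @param mirna_length Mature sequence length (default 22 nt).
#' @param n_genes Gene universe size for the expression-ratio table
#'   (default 10000).
#' @param n_targets Size of the predicted-target gene list (default 947).
#' @param n_planted_targets Target genes forced below the down-regulation
#'   cutoff (default 100).
#' @param planted_ratio_range Range of the planted down-regulated ratios.
#' @param ratio_sdlog Log-normal sd of background expression ratios
#'   (default 0.25; ~19% of background genes fall below 0.8 by chance).
#' @param n_gene_sets Number of gene sets incl. the planted term (default 50).
#' @param set_size_range Size range of the background gene sets.
#' @param planted_term_size Size of the planted term (default 150).
#' @param enrichment_strength Fraction of the planted term drawn from the
#'   planted target genes; 0 gives a fully random (null) term (default 0.6).
#' @param qpcr_n_per_group qPCR replicates per group (default 3).
#' @param qpcr_fold Planted treated/untreated RQ fold change (default 2).
#' @param qpcr_sigma Ct noise sd in cycles (default 0.05).
#' @param ct_reference_mean,delta_ct_base Reference-gene Ct level and
#'   baseline dCt of the target.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_mirnas = 300L,
                             n_human1 = c(case = 6L, control = 6L),
                             n_human2 = c(case = 6L, control = 7L),
                             n_mouse = c(case = 3L, control = 3L),
                             planted_mirnas = NULL,
                             nb_dispersion = 0.1,
                             mouse_paired = TRUE,
                             pair_dispersion_fraction = 0.5,
                             library_size_mean = 5e6,
                             library_size_cv = 0.2,
                             base_weight_meanlog = log(5),
                             base_weight_sdlog = 2,
                             base_weight_cap = 200,
                             planted_weight = 100,
                             mirna_length = 22L,
                             n_genes = 10000L,
                             n_targets = 947L,
                             n_planted_targets = 100L,
                             planted_ratio_range = c(0.3, 0.75),
                             ratio_sdlog = 0.25,
                             n_gene_sets = 50L,
                             set_size_range = c(20L, 200L),
                             planted_term_size = 150L,
                             enrichment_strength = 0.6,
                             qpcr_n_per_group = 3L,
                             qpcr_fold = 2,
                             qpcr_sigma = 0.05,
                             ct_reference_mean = 20,
                             delta_ct_base = 5) {
  if (is.null(planted_mirnas)) {
    planted_mirnas <- data.frame(
      mirna_id = paste0("syn-miR-P", 1:4),
      log2fc_human1 = c(1.5, 1.5, -1.5, -1.5),
      log2fc_human2 = c(1.5, 1.5, -1.5, -1.5),
      log2fc_mouse = c(1.5, 1.5, -1.5, -1.5),
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              n_human1 = n_human1, n_human2 = n_human2, n_mouse = n_mouse,
              planted_mirnas = planted_mirnas,
              nb_dispersion = nb_dispersion,
              mouse_paired = isTRUE(mouse_paired),
              pair_dispersion_fraction = pair_dispersion_fraction,
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              base_weight_meanlog = base_weight_meanlog,
              base_weight_sdlog = base_weight_sdlog,
              base_weight_cap = base_weight_cap,
              planted_weight = planted_weight,
              mirna_length = as.integer(mirna_length),
              n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
              n_planted_targets = as.integer(n_planted_targets),
              planted_ratio_range = planted_ratio_range,
              ratio_sdlog = ratio_sdlog,
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              planted_term_size = as.integer(planted_term_size),
              enrichment_strength = enrichment_strength,
              qpcr_n_per_group = as.integer(qpcr_n_per_group),
              qpcr_fold = qpcr_fold, qpcr_sigma = qpcr_sigma,
              ct_reference_mean = ct_reference_mean,
              delta_ct_base = delta_ct_base)
  sizes <- c(cfg$n_mirnas, cfg$n_human1, cfg$n_human2, cfg$n_mouse,
             cfg$n_genes, cfg$n_gene_sets, cfg$qpcr_n_per_group,
             cfg$mirna_length)
  if (any(sizes <= 0)) stop_mc("synthetic_config: all sizes must be positive")
  if (cfg$nb_dispersion < 0) stop_mc("synthetic_config: dispersion must be >= 0")
  if (cfg$pair_dispersion_fraction < 0 || cfg$pair_dispersion_fraction > 1)
    stop_mc("synthetic_config: pair_dispersion_fraction must be in [0, 1]")
  if (cfg$mouse_paired && cfg$n_mouse[["case"]] != cfg$n_mouse[["control"]])
    stop_mc("synthetic_config: paired mouse design needs equal case/control sizes")
  if (nrow(planted_mirnas) > cfg$n_mirnas)
    stop_mc("synthetic_config: more planted miRNAs than catalog entries")
  if (cfg$n_planted_targets > cfg$n_targets || cfg$n_targets > cfg$n_genes)
    stop_mc("synthetic_config: need n_planted_targets <= n_targets <= n_genes")
  if (cfg$enrichment_strength < 0 || cfg$enrichment_strength > 1)
    stop_mc("synthetic_config: enrichment_strength must be in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a mature-miRNA catalog
#'
#' Random mature sequences for the whole catalog; planted miRNAs are
#' resampled until their seeds are unique within the catalog (so the paralog
#' filter cannot remove them); background seed collisions are left in place,
#' as in a real miRNA complement.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of mature RNA sequences.
#' @export
simulate_mirna_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, SUBSTREAMS[["catalog"]]), {
    planted_ids <- config$planted_mirnas$mirna_id
    n_bg <- config$n_mirnas - length(planted_ids)
    ids <- c(planted_ids, sprintf("syn-miR-%03d", seq_len(n_bg)))
    seqs <- random_rna(config$n_mirnas, config$mirna_length)
    names(seqs) <- ids
    seeds <- vapply(seqs, extract_seed, character(1))
    for (id in planted_ids) {
      while (sum(seeds == seeds[[id]]) > 1L) {
        seqs[[id]] <- random_rna(1L, config$mirna_length)
        seeds[[id]] <- extract_seed(seqs[[id]])
      }
    }
    seqs
  })
}

simulate_one_dataset <- function(config, cohort, lfc, stream, prefix,
                                 paired = FALSE) {
  with_seed(substream_seed(config$seed, stream), {
    planted_ids <- config$planted_mirnas$mirna_id
    n_bg <- config$n_mirnas - length(planted_ids)
    ids <- c(planted_ids, sprintf("syn-miR-%03d", seq_len(n_bg)))
    w <- c(rep(config$planted_weight, length(planted_ids)),
           pmin(stats::rlnorm(n_bg, config$base_weight_meanlog,
                              config$base_weight_sdlog),
                config$base_weight_cap))
    names(w) <- ids
    lfc_all <- stats::setNames(rep(0, config$n_mirnas), ids)
    lfc_all[planted_ids] <- lfc
    n_case <- cohort[["case"]]; n_control <- cohort[["control"]]
    sample_ids <- c(sprintf("%s_case_%d", prefix, seq_len(n_case)),
                    sprintf("%s_control_%d", prefix, seq_len(n_control)))
    is_case <- rep(c(TRUE, FALSE), c(n_case, n_control))
    sdlog_lib <- sqrt(log(1 + config$library_size_cv^2))
    lib <- stats::rlnorm(length(sample_ids),
                         log(config$library_size_mean) - sdlog_lib^2 / 2,
                         sdlog_lib)
    counts <- matrix(0L, nrow = config$n_mirnas, ncol = length(sample_ids),
                     dimnames = list(ids, sample_ids))
    disp <- config$nb_dispersion
    d_pair <- if (paired) disp * config$pair_dispersion_fraction else 0
    d_resid <- disp - d_pair
    pair_factor <- matrix(1, nrow = config$n_mirnas, ncol = max(n_case, n_control))
    if (d_pair > 0) {
      # sibling pairs share a per-pair, per-miRNA biological abundance factor
      pair_factor[] <- stats::rgamma(length(pair_factor), shape = 1 / d_pair,
                                     scale = d_pair)
    }
    pair_of <- c(seq_len(n_case), seq_len(n_control))
    for (s in seq_along(sample_ids)) {
      eff <- w * 2^(lfc_all * is_case[s])
      mu <- lib[s] * eff / sum(eff) * pair_factor[, pair_of[s]]
      counts[, s] <- if (d_resid > 0) {
        stats::rnbinom(config$n_mirnas, mu = mu, size = 1 / d_resid)
      } else {
        stats::rpois(config$n_mirnas, mu)
      }
    }
    list(counts = counts,
         groups = data.frame(sample_id = sample_ids,
                             group = ifelse(is_case, "case", "control"),
                             stringsAsFactors = FALSE))
  })
}

#' Simulate small RNA-seq count tables for all three datasets
#'
#' @param config A [synthetic_config()].
#' @return List with elements `human1`, `human2`, `mouse` (each a list of
#'   `counts` matrix and `groups` data frame) and `truth` (the planted
#'   fold-change table).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  list(human1 = simulate_one_dataset(config, config$n_human1,
                                     config$planted_mirnas$log2fc_human1,
                                     SUBSTREAMS[["counts_human1"]], "h1"),
       human2 = simulate_one_dataset(config, config$n_human2,
                                     config$planted_mirnas$log2fc_human2,
                                     SUBSTREAMS[["counts_human2"]], "h2"),
       mouse = simulate_one_dataset(config, config$n_mouse,
                                    config$planted_mirnas$log2fc_mouse,
                                    SUBSTREAMS[["counts_mouse"]], "ms",
                                    paired = config$mouse_paired),
       truth = config$planted_mirnas)
}

#' Simulate 3'-UTRs with planted seed sites
#'
#' Uniform-random background sequences; the miRNA's 7mer-m8 seed-match motif
#' is inserted at one recorded position in each designated UTR. A manifest
#' of planted (utr_id, 0-based motif position) is returned alongside.
#'
#' @param config A [synthetic_config()].
#' @param mirna_sequence Mature miRNA (or 7-nt seed) to plant against.
#' @param n_utrs,utr_length,n_planted Number of UTRs, their length, and how
#'   many carry a planted site.
#' @return List with `utrs` (named character vector) and `manifest` (data
#'   frame `utr_id`, `position`).
#' @export
simulate_utrs <- function(config, mirna_sequence, n_utrs = 50L,
                          utr_length = 500L, n_planted = 10L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_planted > n_utrs) stop_mc("simulate_utrs: n_planted > n_utrs")
  motif <- seed_match_motif(mirna_sequence)
  with_seed(substream_seed(config$seed, SUBSTREAMS[["utrs"]]), {
    utrs <- random_rna(n_utrs, utr_length)
    names(utrs) <- sprintf("utr%03d", seq_len(n_utrs))
    planted_idx <- seq_len(n_planted)
    positions <- integer(0)
    if (n_planted > 0L) {
      positions <- sample(utr_length - nchar(motif), n_planted, replace = TRUE)
      for (j in seq_len(n_planted)) {
        substr(utrs[planted_idx[j]], positions[j] + 1L,
               positions[j] + nchar(motif)) <- motif
      }
    }
    list(utrs = utrs,
         manifest = data.frame(utr_id = names(utrs)[planted_idx],
                               position = positions,
                               stringsAsFactors = FALSE))
  })
}

#' Simulate a gene expression-ratio table with planted down-regulation
#'
#' Background treated/untreated ratios are log-normal centered at 1; the
#' planted target genes get ratios drawn below the down-regulation cutoff.
#' The predicted-target list is the planted genes plus random background
#' genes, emulating a conserved-target list.
#'
#' @param config A [synthetic_config()].
#' @return List with `ratios` (data frame `gene_id`, `ratio`), `targets`
#'   (predicted-target ids) and `planted_targets` (truly down-regulated
#'   target ids).
#' @export
simulate_expression_ratios <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, SUBSTREAMS[["ratios"]]), {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    ratio <- stats::rlnorm(config$n_genes, 0, config$ratio_sdlog)
    targets <- sample(genes, config$n_targets)
    planted <- targets[seq_len(config$n_planted_targets)]
    ratio[match(planted, genes)] <- stats::runif(
      config$n_planted_targets, config$planted_ratio_range[1],
      config$planted_ratio_range[2])
    list(ratios = data.frame(gene_id = genes, ratio = ratio,
                             stringsAsFactors = FALSE),
         targets = sort(targets), planted_targets = sort(planted))
  })
}

#' Simulate gene sets with one planted enriched term
#'
#' Background sets are uniform-random draws from the universe; the planted
#' term (`GO_SYN_PLANTED`) draws `enrichment_strength * planted_term_size`
#' members from the planted target genes and the rest at random. Strength 0
#' makes the planted term a plain random set (the null).
#'
#' @param config A [synthetic_config()].
#' @param planted_genes Genes to enrich the planted term with (from
#'   [simulate_expression_ratios()]).
#' @param universe Gene universe to draw from.
#' @return Named list of gene sets (same shape as [read_gmt()]).
#' @export
simulate_gene_sets <- function(config, planted_genes, universe) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, SUBSTREAMS[["gene_sets"]]), {
    sets <- list()
    for (i in seq_len(config$n_gene_sets - 1L)) {
      size <- sample(config$set_size_range[1]:config$set_size_range[2], 1L)
      id <- sprintf("GO_SYN_%03d", i)
      sets[[id]] <- list(term_id = id, name = sprintf("synthetic term %d", i),
                         members = sort(sample(universe, size)))
    }
    n_from_planted <- min(round(config$enrichment_strength *
                                  config$planted_term_size),
                          length(planted_genes))
    members <- character(0)
    if (n_from_planted > 0L)
      members <- sample(planted_genes, n_from_planted)
    n_rest <- config$planted_term_size - length(members)
    members <- c(members, sample(setdiff(universe, members), n_rest))
    sets[["GO_SYN_PLANTED"]] <- list(term_id = "GO_SYN_PLANTED",
                                     name = "synthetic planted term",
                                     members = sort(members))
    sets
  })
}

#' Simulate a qPCR Ct table
#'
#' `ct_reference ~ Normal(ct_reference_mean, sigma)`; `ct_target =
#' ct_reference + dCt_group + Normal(0, sigma)` with the treated group's dCt
#' shifted by `-log2(qpcr_fold)` so the planted treated/untreated RQ ratio
#' equals `qpcr_fold`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `sample_id`, `group` (treated/untreated),
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, SUBSTREAMS[["qpcr"]]), {
    n <- config$qpcr_n_per_group
    group <- rep(c("treated", "untreated"), each = n)
    dct <- config$delta_ct_base -
      log2(config$qpcr_fold) * (group == "treated")
    ct_ref <- stats::rnorm(2 * n, config$ct_reference_mean, config$qpcr_sigma)
    ct_tgt <- ct_ref + dct + stats::rnorm(2 * n, 0, config$qpcr_sigma)
    data.frame(sample_id = sprintf("%s_%d", group, rep(seq_len(n), 2)),
               group = group, ct_target = ct_tgt, ct_reference = ct_ref,
               stringsAsFactors = FALSE)
  })
}

#' Simulate the full synthetic study bundle
#'
#' Runs every generator off one global seed and optionally writes the whole
#' bundle (count and group TSVs, miRNA and UTR FASTAs, ratio TSV, target
#' list, GMT, qPCR TSV, and a JSON manifest of all planted truths) to a
#' directory ready for [run_all()].
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional output directory (created if missing).
#' @return The in-memory bundle (list), invisibly when writing.
#' @export
simulate_bundle <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  catalog_seqs <- simulate_mirna_catalog(config)
  counts <- simulate_counts(config)
  planted_ids <- config$planted_mirnas$mirna_id
  plant_against <- if (length(planted_ids)) {
    catalog_seqs[[planted_ids[1]]]
  } else {
    catalog_seqs[[1]]
  }
  utrs <- simulate_utrs(config, plant_against)
  expr <- simulate_expression_ratios(config)
  sets <- simulate_gene_sets(config, expr$planted_targets, expr$ratios$gene_id)
  qpcr <- simulate_qpcr(config)
  bundle <- list(config = config, mirna_sequences = catalog_seqs,
                 counts = counts, utrs = utrs, expression = expr,
                 gene_sets = sets, qpcr = qpcr)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    for (ds in c("human1", "human2", "mouse")) {
      write_table_tsv(counts[[ds]]$counts, p(sprintf("counts_%s.tsv", ds)))
      write_groups(counts[[ds]]$groups, p(sprintf("groups_%s.tsv", ds)))
    }
    write_fasta(catalog_seqs, p("mirna.fa"))
    write_fasta(utrs$utrs, p("utrs.fa"))
    utils::write.table(expr$ratios, p("ratios.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    writeLines(expr$targets, p("targets.txt"), sep = "\n")
    write_gmt(sets, p("gene_sets.gmt"))
    utils::write.table(qpcr, p("qpcr.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    manifest <- list(seed = config$seed,
                     planted_mirnas = config$planted_mirnas,
                     planted_targets = expr$planted_targets,
                     planted_term = "GO_SYN_PLANTED",
                     utr_manifest = utrs$manifest)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
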