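# Seed extraction, seed-match motif generation and 3'-UTR site scanning.
#
# Conventions (TargetScan site classes): the seed is miRNA nucleotides 2-8.
# In a UTR stored 5'->3' a canonical site reads
#   [m8 match][6mer core (rev. complement of miRNA nt 2-7)][A1 position]
# with the A1 position the UTR nucleotide immediately 3' of the seed-match
# heptamer, opposite miRNA nucleotide 1.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

assert_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_mc("%s must be a single character string", what)
  if (!grepl("^[ACGU]*$", x))
    stop_mc("%s must use the RNA alphabet A/C/G/U (got '%s')", what, x)
  invisible(x)
}

#' Extract the 7-nt seed of a mature miRNA
#'
#' Returns positions 2-8 (1-based, inclusive) of the mature sequence; this
#' heptamer defines the miRNA's family.
#'
#' @param sequence Mature miRNA sequence, 5'->3', RNA alphabet, length >= 8.
#' @return The 7-nt seed string.
#' @export
extract_seed <- function(sequence) {
  assert_rna(sequence, "mature miRNA sequence")
  if (nchar(sequence) < 8L)
    stop_mc("mature miRNA sequence must be >= 8 nt (got %d)", nchar(sequence))
  substr(sequence, 2L, 8L)
}

#' Reverse complement of an RNA string
#'
#' @param sequence RNA string (A/C/G/U).
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(sequence) {
  assert_rna(sequence)
  if (nchar(sequence) == 0L) return(sequence)
  paste(rev(RNA_COMPLEMENT[strsplit(sequence, "")[[1]]]), collapse = "")
}

#' Seed-match motif of a miRNA
#'
#' The 7-nt UTR motif complementary to the seed (the 7mer-m8 motif pairing
#' miRNA positions 2-8): `reverse_complement(seed)`.
#'
#' @param x Either a 7-nt seed or a full mature sequence (>= 8 nt, in which
#'   case the seed is extracted first).
#' @return 7-nt RNA motif a target UTR must contain.
#' @export
seed_match_motif <- function(x) {
  assert_rna(x, "seed or mature sequence")
  seed <- if (nchar(x) == 7L) x else extract_seed(x)
  reverse_complement(seed)
}

#' Build a mature-miRNA catalog
#'
#' Derives seed and family id (the seed string, nt 2-8) for each mature
#' sequence. Family grouping by seed is the basis of the paralog filter.
#'
#' @param sequences Named character vector of mature RNA sequences
#'   (names are miRNA ids).
#' @return Data frame with columns `mirna_id`, `sequence`, `seed`,
#'   `family_id`.
#' @export
mirna_catalog <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop_mc("mirna_catalog: sequences must be named by miRNA id")
  if (anyDuplicated(names(sequences)))
    stop_mc("mirna_catalog: duplicate miRNA ids")
  seeds <- vapply(unname(sequences), extract_seed, character(1))
  data.frame(mirna_id = names(sequences), sequence = unname(sequences),
             seed = seeds, family_id = seeds, stringsAsFactors = FALSE)
}

#' Scan a 3'-UTR for seed-match sites
#'
#' Finds all (also overlapping) occurrences of the 6mer core — the reverse
#' complement of miRNA nucleotides 2-7 — and classifies each occurrence:
#' m8 match present and an A opposite miRNA nucleotide 1 gives `8mer`; m8
#' only, `7mer-m8`; A1 only, `7mer-A1`; otherwise `6mer`. 6mer sites are
#' low-confidence and can be dropped via `min_class`. An empty result means
#' the motif is absent from the UTR.
#'
#' A DNA UTR (containing T) is transliterated T->U at this boundary, with a
#' message.
#'
#' @param utr UTR sequence 5'->3' (RNA or DNA alphabet).
#' @param mirna Mature miRNA sequence (>= 8 nt, RNA) or a 7-nt seed.
#' @param utr_id,mirna_id Identifiers carried into the output.
#' @param min_class Least site class to report: `"6mer"` (default, all
#'   sites) or `"7mer"` (7mer-A1 and better only).
#' @return Data frame with columns `utr_id`, `mirna_id`, `start` (0-based
#'   position of the type-defining match), `site_type`.
#' @export
scan_utr <- function(utr, mirna, utr_id = "utr", mirna_id = "miRNA",
                     min_class = c("6mer", "7mer")) {
  min_class <- match.arg(min_class)
  if (!is.character(utr) || length(utr) != 1L)
    stop_mc("scan_utr: utr must be a single string")
  utr <- toupper(utr)
  if (grepl("T", utr, fixed = TRUE)) {
    if (grepl("U", utr, fixed = TRUE))
      stop_mc("scan_utr: UTR mixes T and U")
    mc_msg("scan_utr: DNA UTR transliterated T->U")
    utr <- chartr("T", "U", utr)
  }
  if (!grepl("^[ACGUN]*$", utr))
    stop_mc("scan_utr: UTR has characters outside A/C/G/T/U/N")
  assert_rna(mirna, "miRNA sequence")
  seed <- if (nchar(mirna) == 7L) mirna else extract_seed(mirna)
  core <- reverse_complement(substr(seed, 1L, 6L))     # matches miRNA nt 2-7
  m8_base <- RNA_COMPLEMENT[[substr(seed, 7L, 7L)]]    # UTR base pairing nt 8

  empty <- data.frame(utr_id = character(), mirna_id = character(),
                      start = integer(), site_type = character(),
                      stringsAsFactors = FALSE)
  if (nchar(utr) < 6L) return(empty)
  # overlapping matches via zero-width lookahead
  m <- gregexpr(paste0("(?=", core, ")"), utr, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts1 <- as.integer(m)  # 1-based core starts
  site <- lapply(starts1, function(cs) {
    has_m8 <- cs > 1L && substr(utr, cs - 1L, cs - 1L) == m8_base
    a1_pos <- cs + 6L
    has_a1 <- a1_pos <= nchar(utr) && substr(utr, a1_pos, a1_pos) == "A"
    if (has_m8 && has_a1) {
      c(type = "8mer", start = cs - 2L)
    } else if (has_m8) {
      c(type = "7mer-m8", start = cs - 2L)
    } else if (has_a1) {
      c(type = "7mer-A1", start = cs - 1L)
    } else {
      c(type = "6mer", start = cs - 1L)
    }
  })
  out <- data.frame(utr_id = utr_id, mirna_id = mirna_id,
                    start = vapply(site, function(s) as.integer(s[["start"]]), integer(1)),
                    site_type = vapply(site, `[[`, character(1), "type"),
                    stringsAsFactors = FALSE)
  if (min_class == "7mer")
    out <- out[out$site_type != "6mer", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many UTRs against many miRNAs
#'
#' @param utrs Named character vector of UTR sequences.
#' @param catalog A [mirna_catalog()] data frame (or named vector of mature
#'   sequences).
#' @param min_class Passed to [scan_utr()].
#' @return Combined site data frame over all (UTR, miRNA) pairs.
#' @export
scan_utrs <- function(utrs, catalog, min_class = "6mer") {
  if (is.character(catalog)) catalog <- mirna_catalog(catalog)
  res <- list()
  for (j in seq_len(nrow(catalog))) {
    for (i in seq_along(utrs)) {
      res[[length(res) + 1L]] <- scan_utr(
        utrs[[i]], catalog$sequence[j], utr_id = names(utrs)[i],
        mirna_id = catalog$mirna_id[j], min_class = min_class)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- scan_utr("", "AAAAAAA")[0, ]
  rownames(out) <- NULL
  out
}
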