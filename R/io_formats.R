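# Minimal, dialect-explicit readers/writers for the external formats the
# pipeline touches. Genomic intervals are 0-based half-open everywhere
# internally: BED is native, SAM is converted at this boundary. TSV is the
# only table dialect and always carries a header row.

#' Read a BED6 file of miRNA loci
#'
#' Parses a 6-column BED file into a data frame of miRNA loci. BED start/end
#' are already 0-based half-open and are mapped verbatim; column 4 becomes
#' `mirna_id`, column 6 the strand. Strand must be `+` or `-`; locus ids must
#' be unique.
#'
#' @param path Path to a BED file with at least 6 tab-separated columns.
#' @return A data frame with columns `mirna_id`, `chrom`, `start`, `end`,
#'   `strand`. Empty file gives a zero-row frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_mc("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  loci <- empty_loci()
  if (length(lines) == 0L) return(loci)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L)
      stop_mc("BED parse error at line %d: expected >= 6 tab-separated columns, got %d",
              lineno[i], length(f))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end))
      stop_mc("BED parse error at line %d: non-integer coordinates", lineno[i])
    if (!(f[6] %in% c("+", "-")))
      stop_mc("BED parse error at line %d: strand must be '+' or '-' (got '%s')",
              lineno[i], f[6])
    if (start >= end)
      stop_mc("BED parse error at line %d: start must be < end", lineno[i])
    rows[[i]] <- data.frame(mirna_id = f[4], chrom = f[1], start = start,
                            end = end, strand = f[6], stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, rows)
  dup <- loci$mirna_id[duplicated(loci$mirna_id)]
  if (length(dup))
    stop_mc("BED validation error: duplicate mirna_id(s): %s",
            paste(unique(dup), collapse = ", "))
  loci
}

empty_loci <- function() {
  data.frame(mirna_id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), stringsAsFactors = FALSE)
}

#' Write miRNA loci as BED6
#'
#' @param loci Data frame as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", loci$chrom, as.integer(loci$start),
                   as.integer(loci$end), loci$mirna_id, loci$strand)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# Reference span consumed by a CIGAR string (ops M/D/N/=/X), or NA if the
# CIGAR is unparseable.
cigar_reference_span <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Read a minimal SAM subset into alignment records
#'
#' Consumes SAM text (header lines starting with `@` are skipped) and keeps
#' only the fields the quantification step needs: FLAG, RNAME, POS, CIGAR and
#' the optional `NM:i` edit-distance tag. The 1-based POS is converted to a
#' 0-based start; `end = start +` reference span of the CIGAR (M/D/N/=/X
#' consume reference). FLAG bit 0x10 gives strand `-`; FLAG bit 0x4 marks the
#' record unmapped (coordinates/strand are then `NA`). A missing NM tag is
#' treated as edit distance 0 with a warning; an unparseable CIGAR skips the
#' record with a warning.
#'
#' @param path Path to a SAM text file.
#' @return Data frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `edit_distance`, `mapped`. The number of skipped records is
#'   attached as attribute `n_skipped`.
#' @export
read_sam_minimal <- function(path) {
  if (!file.exists(path)) stop_mc("SAM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  n <- length(lines)
  out <- data.frame(read_id = character(n), chrom = character(n),
                    start = rep(NA_real_, n), end = rep(NA_real_, n),
                    strand = rep(NA_character_, n),
                    edit_distance = rep(NA_integer_, n),
                    mapped = logical(n), stringsAsFactors = FALSE)
  skipped <- 0L
  missing_nm <- 0L
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      skipped <- skipped + 1L
      keep[i] <- FALSE
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) {
      skipped <- skipped + 1L
      keep[i] <- FALSE
      next
    }
    out$read_id[i] <- f[1]
    if (bitwAnd(flag, 4L) != 0L) {
      out$mapped[i] <- FALSE
      next
    }
    span <- cigar_reference_span(f[6])
    if (is.na(span)) {
      skipped <- skipped + 1L
      keep[i] <- FALSE
      next
    }
    nm_field <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(f) <= 11L) nm_field <- character()
    if (length(nm_field) == 0L) {
      nm <- 0L
      missing_nm <- missing_nm + 1L
    } else {
      nm <- as.integer(sub("^NM:i:", "", nm_field[1]))
    }
    start <- suppressWarnings(as.numeric(f[4])) - 1
    out$chrom[i] <- f[3]
    out$start[i] <- start
    out$end[i] <- start + span
    out$strand[i] <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    out$edit_distance[i] <- nm
    out$mapped[i] <- TRUE
  }
  if (skipped > 0L)
    warning(sprintf("read_sam_minimal: skipped %d unparseable record(s)", skipped))
  if (missing_nm > 0L)
    warning(sprintf("read_sam_minimal: %d mapped record(s) lack NM tag; edit distance assumed 0",
                    missing_nm))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Read a FASTA file into a named character vector
#'
#' Wraps `Biostrings::readBStringSet` and enforces the pipeline's contract:
#' ids are the header token before the first whitespace and must be unique,
#' sequences are uppercased and must be non-empty, and the alphabet (RNA if
#' the file uses U, DNA if it uses T) is recorded as attribute `alphabet`
#' rather than silently converted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences with attribute
#'   `alphabet` in `"RNA"`, `"DNA"` or `"ambiguous"` (no T/U observed).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_mc("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_mc("FASTA error: duplicate id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop_mc("FASTA error: empty sequence for id(s): %s",
            paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop_mc("FASTA error: unexpected characters in sequence(s): %s",
            paste(ids[bad], collapse = ", "))
  has_u <- any(grepl("U", seqs, fixed = TRUE))
  has_t <- any(grepl("T", seqs, fixed = TRUE))
  alphabet <- if (has_u && has_t) {
    stop_mc("FASTA error: file mixes T and U")
  } else if (has_u) "RNA" else if (has_t) "DNA" else "ambiguous"
  names(seqs) <- ids
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), unname(seqs[i])), con, sep = "\n")
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Member
#' lists are deduplicated preserving order; lines with fewer than 3 columns
#' or no non-empty members are rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets, each a list with `term_id`, `name`
#'   (the description column) and `members` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_mc("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_mc("GMT parse error at line %d: expected >= 3 columns", lineno[i])
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop_mc("GMT parse error at line %d: gene set '%s' is empty", lineno[i], f[1])
    sets[[f[1]]] <- list(term_id = f[1], name = f[2], members = members)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$term_id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a miRNA-by-sample table from TSV
#'
#' First column holds miRNA ids, remaining columns one sample each; header
#' row mandatory (TSV is the only table dialect).
#'
#' @param path Path to a TSV file.
#' @param integral Require integral values (count tables).
#' @return Numeric matrix with miRNA row names and sample column names.
#' @export
read_table_tsv <- function(path, integral = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_mc("table %s needs an id column plus >= 1 sample column", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  check_table_matrix(m, what = basename(path), integral = integral)
  m
}

#' Write a miRNA-by-sample table to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the id column (first column header).
#' @export
write_table_tsv <- function(m, path, id_col = "mirna_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' TSV with header columns `sample_id` and `group`.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `sample_id` and `group`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop_mc("group table %s must have columns 'sample_id' and 'group'", path)
  if (anyDuplicated(df$sample_id))
    stop_mc("group table %s has duplicated sample ids", path)
  df[, c("sample_id", "group")]
}

#' Write a sample-to-group table
#' @param groups Data frame with `sample_id` and `group` columns.
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
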