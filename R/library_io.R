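# Strength libraries: the training substrate. A library joins named
# equal-length sequences with measured relative strengths (wild type == 1),
# read/written as FASTA + TSV.

#' Construct a strength library
#'
#' @param ids character vector of unique record ids.
#' @param sequences character vector of equal-length A/C/G/T sequences.
#' @param strengths numeric vector of relative strengths (dimensionless,
#'   wild type = 1); `NA` marks unmeasured designs.
#' @param wild_type_id id of the wild-type record; its strength, when
#'   present, must equal 1 (tolerance 1e-9).
#' @return object of class `strength_library` with fields `id`, `sequence`,
#'   `relative_strength`, `wild_type_id`, `sequence_length`.
#' @export
strength_library <- function(ids, sequences, strengths = NULL, wild_type_id = NULL) {
  if (length(ids) == 0L) fail("a strength library needs at least one record")
  if (length(ids) != length(sequences))
    fail("ids (%d) and sequences (%d) differ in length", length(ids), length(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    fail("duplicate record id '%s'", ids[duplicated(ids)][1L])
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1L]]
    fail("all sequences must share one length; offending record(s): %s",
         paste(off, collapse = ", "))
  }
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) fail("record '%s' contains non-ACGT characters", ids[bad][1L])
  if (is.null(strengths)) strengths <- rep(NA_real_, length(ids))
  if (length(strengths) != length(ids))
    fail("strengths length (%d) does not match record count (%d)",
         length(strengths), length(ids))
  strengths <- as.numeric(strengths)
  if (any(!is.na(strengths) & strengths < 0))
    fail("relative strengths must be non-negative")
  if (!is.null(wild_type_id)) {
    wix <- match(wild_type_id, ids)
    if (is.na(wix)) fail("wild_type_id '%s' not found among record ids", wild_type_id)
    if (!is.na(strengths[wix]) && abs(strengths[wix] - 1) > 1e-9)
      fail("wild-type record '%s' has strength %.6g, expected 1", wild_type_id,
           strengths[wix])
  }
  structure(
    list(id = ids, sequence = sequences, relative_strength = strengths,
         wild_type_id = wild_type_id, sequence_length = lens[1L]),
    class = "strength_library")
}

#' @export
print.strength_library <- function(x, ...) {
  meas <- sum(!is.na(x$relative_strength))
  cat(sprintf("strength_library: %d records, %d nt, %d with measured strength\n",
              length(x$id), x$sequence_length, meas))
  if (meas > 0) {
    rng <- range(x$relative_strength, na.rm = TRUE)
    cat(sprintf("  strength range [%.3f, %.3f]; %d records > 1\n",
                rng[1], rng[2], sum(x$relative_strength > 1, na.rm = TRUE)))
  }
  if (!is.null(x$wild_type_id)) cat(sprintf("  wild type: %s\n", x$wild_type_id))
  invisible(x)
}

#' @export
length.strength_library <- function(x) length(x$id)

#' Subset a strength library by index or id
#'
#' @param x a [strength_library].
#' @param i integer, logical or character index over records.
#' @param ... unused.
#' @return a `strength_library` containing the selected records. The wild-type
#'   id is kept only if the wild type survives the subset.
#' @export
`[.strength_library` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  ids <- x$id[i]
  if (anyNA(ids)) fail("subset index out of range")
  wt <- if (!is.null(x$wild_type_id) && x$wild_type_id %in% ids) x$wild_type_id
  strength_library(ids, x$sequence[i], x$relative_strength[i], wt)
}

#' Read a strength library from FASTA + TSV
#'
#' Sequences come from a FASTA file (single-line or wrapped); strengths from a
#' tab-separated table with header `id<TAB>relative_strength`. Table ids must
#' match FASTA headers (first whitespace-delimited token). FASTA records
#' absent from the table carry `NA` strength; record order follows the FASTA.
#'
#' @param fasta_path path to the FASTA file.
#' @param strengths_path path to the TSV strength table, or `NULL` for a
#'   sequences-only library.
#' @param wild_type_id optional wild-type id; defaults to the id of a record
#'   whose strength equals 1 exactly, if there is exactly one such record.
#' @return a [strength_library].
#' @export
read_library <- function(fasta_path, strengths_path = NULL, wild_type_id = NULL) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) == 0L) fail("no sequences in '%s'", fasta_path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    fail("duplicate FASTA header '%s' in '%s'", ids[duplicated(ids)][1L], fasta_path)
  seqs <- as.character(set)
  strengths <- rep(NA_real_, length(ids))
  if (!is.null(strengths_path)) {
    tab <- read.table(strengths_path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric"))
    if (!identical(colnames(tab)[1:2], c("id", "relative_strength")))
      fail("strength table must have header 'id<TAB>relative_strength'")
    if (anyDuplicated(tab$id)) fail("duplicate id '%s' in strength table",
                                    tab$id[duplicated(tab$id)][1L])
    miss <- setdiff(tab$id, ids)
    if (length(miss) > 0L)
      fail("strength table id(s) with no FASTA match: %s",
           paste(miss, collapse = ", "))
    strengths[match(tab$id, ids)] <- tab$relative_strength
  }
  if (is.null(wild_type_id)) {
    at1 <- which(!is.na(strengths) & strengths == 1)
    if (length(at1) == 1L) wild_type_id <- ids[at1]
  }
  strength_library(ids, seqs, strengths, wild_type_id)
}

#' Write a strength library to FASTA + TSV
#'
#' Strengths are serialized with enough digits (15 significant) that
#' [read_library()] of the written pair reproduces the library exactly at
#' double precision. Records without a measured strength are omitted from the
#' table.
#'
#' @param lib a [strength_library].
#' @param fasta_path output FASTA path.
#' @param strengths_path output TSV path.
#' @return invisibly, the library.
#' @export
write_library <- function(lib, fasta_path, strengths_path) {
  stopifnot(inherits(lib, "strength_library"))
  if (length(lib$id) == 0L) fail("refusing to write an empty library")
  set <- Biostrings::DNAStringSet(setNames(lib$sequence, lib$id))
  Biostrings::writeXStringSet(set, fasta_path)
  keep <- !is.na(lib$relative_strength)
  tab <- data.frame(id = lib$id[keep],
                    relative_strength = sprintf("%.15g", lib$relative_strength[keep]))
  names(tab)[2] <- "relative_strength"
  write.table(tab, strengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' Relative strength from raw fluorescence readings
#'
#' The strength of a mutant relative to the wild type is the blank-subtracted
#' ratio `(F - F_blank) / (F_ref - F_blank)`: 1 for the wild-type reading, 0
#' for the blank. For flow-cytometry quantification, pass geometric means of
#' the per-event signal (see [geometric_mean()]) as the readings. Readings
#' below blank (measurement noise) clamp to 0 with a warning.
#'
#' @param F fluorescence reading(s) of the mutant.
#' @param F_blank blank-control reading.
#' @param F_ref wild-type reference reading; must exceed `F_blank`.
#' @return dimensionless relative strength(s), >= 0.
#' @export
#' @examples
#' relative_strength(60, F_blank = 10, F_ref = 110)  # 0.5
relative_strength <- function(F, F_blank, F_ref) {
  if (!is_scalar_num(F_blank) || !is_scalar_num(F_ref))
    fail("F_blank and F_ref must be finite scalars")
  if (F_ref <= F_blank)
    fail("degenerate reference: F_ref (%.6g) must exceed F_blank (%.6g)",
         F_ref, F_blank)
  s <- (F - F_blank) / (F_ref - F_blank)
  if (any(s < 0)) {
    warning("reading(s) below blank control; clamping relative strength to 0")
    s[s < 0] <- 0
  }
  s
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` of strictly positive values; the standard summary of
#' log-normal per-cell fluorescence from flow cytometry.
#'
#' @param x non-empty vector of positive values.
#' @return positive scalar.
#' @export
#' @examples
#' geometric_mean(c(4, 9))  # 6
geometric_mean <- function(x) {
  if (length(x) == 0L) fail("geometric mean of an empty vector is undefined")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    fail("geometric mean requires strictly positive finite values")
  exp(mean(log(x)))
}
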