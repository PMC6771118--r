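# Cohort and per-variant energy table I/O.
#
# Tables are plain delimited text with a header row.  Numeric cells may use
# either the decimal point or the decimal comma (the source tables mix
# locales); "NA", "" and "-" are read as missing.  Missing values are always
# written back as "NA".

.NA_STRINGS <- c("NA", "", "-")

.parse_numeric <- function(x, dec = ".", column = "", rows = seq_along(x)) {
  x <- as.character(x)
  x[x %in% .NA_STRINGS] <- NA_character_
  if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("unparseable value '%s' in column '%s' at data row %d",
                 x[bad[1]], column, rows[bad[1]]), call. = FALSE)
  out
}

.read_delim_chr <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    na.strings = NULL, quote = "\"", comment.char = "")
}

#' Read a proband cohort table
#'
#' Reads a delimited proband table (one row per clinically evaluated
#' individual) and validates it. Mandatory columns: \code{proband_id},
#' \code{age_years}, \code{protein_change}, \code{bcva_le}, \code{bcva_re}.
#' Optional columns (\code{sex}, \code{exon}, \code{nucleotide_change},
#' \code{allele_state}, \code{stage_le}, \code{stage_re}, ...) are carried
#' through. Best-corrected visual acuity (BCVA) is per-eye logMAR in
#' [0, 2.6]; disease stage is an integer 0-5. A record missing BCVA for
#' either eye is flagged BCVA-incomplete and is excluded from severity
#' averaging downstream, never zero-imputed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dec Decimal mark for numeric cells, \code{"."} or \code{","}.
#' @param sep Field separator.
#' @return A data frame of class \code{bv_cohort} with parsed numeric
#'   columns, a canonical \code{variant} column, a \code{truncating} flag
#'   and a logical \code{bcva_complete} column. A validation report (see
#'   \code{\link{validate_cohort}}) is attached as attribute
#'   \code{"validation"}.
#' @examples
#' coh <- read_cohort(bestqspr_example("probands.csv"))
#' nrow(coh); sum(coh$bcva_complete)
#' @export
read_cohort <- function(path, dec = ".", sep = ",") {
  dec <- match.arg(dec, c(".", ","))
  raw <- .read_delim_chr(path, sep = sep)
  mandatory <- c("proband_id", "age_years", "protein_change",
                 "bcva_le", "bcva_re")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("cohort table has a header but no data rows", call. = FALSE)
  }
  df <- raw
  chr_na <- function(x) { x[x %in% .NA_STRINGS] <- NA_character_; x }
  for (col in names(df)) df[[col]] <- chr_na(df[[col]])

  df$age_years <- .parse_numeric(raw$age_years, dec, "age_years")
  df$bcva_le <- .parse_numeric(raw$bcva_le, dec, "bcva_le")
  df$bcva_re <- .parse_numeric(raw$bcva_re, dec, "bcva_re")
  for (col in c("stage_le", "stage_re")) {
    if (col %in% names(raw)) {
      v <- .parse_numeric(raw[[col]], dec, col)
      bad <- which(!is.na(v) & (v %% 1 != 0 | v < 0 | v > 5))
      if (length(bad))
        stop(sprintf("stage out of range 0-5 in column '%s' at data row %d",
                     col, bad[1]), call. = FALSE)
      df[[col]] <- as.integer(v)
    }
  }
  bad_age <- which(is.na(df$age_years) | df$age_years <= 0)
  if (length(bad_age))
    stop(sprintf("missing or non-positive age_years at data row %d",
                 bad_age[1]), call. = FALSE)
  for (col in c("bcva_le", "bcva_re")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 2.6))
    if (length(bad))
      stop(sprintf("BCVA outside [0, 2.6] in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
  }
  if ("allele_state" %in% names(df)) {
    st <- toupper(df$allele_state)
    map <- c(HET = "heterozygous", HOM = "homozygous",
             HETEROZYGOUS = "heterozygous", HOMOZYGOUS = "homozygous")
    unknown <- which(!is.na(st) & !st %in% names(map))
    if (length(unknown))
      stop(sprintf("unknown allele_state '%s' at data row %d",
                   df$allele_state[unknown[1]], unknown[1]), call. = FALSE)
    df$allele_state <- unname(map[st])
  }
  df$variant <- canonical_variant(df$protein_change)
  df$truncating <- vapply(df$variant, function(v) {
    if (is.na(v)) NA else parse_protein_variant(v)$truncating
  }, logical(1), USE.NAMES = FALSE)
  one_eye <- xor(is.na(df$bcva_le), is.na(df$bcva_re))
  df$bcva_complete <- !is.na(df$bcva_le) & !is.na(df$bcva_re)

  report <- list(
    n_records = nrow(df),
    n_bcva_complete = sum(df$bcva_complete),
    bcva_missing_ids = df$proband_id[!df$bcva_complete],
    partially_missing_ids = df$proband_id[one_eye])
  attr(df, "validation") <- report
  class(df) <- c("bv_cohort", "data.frame")
  df
}

#' Print the cohort validation report
#'
#' @param cohort A \code{bv_cohort} data frame from \code{\link{read_cohort}}.
#' @return Invisibly, the validation report list (\code{n_records},
#'   \code{n_bcva_complete}, \code{bcva_missing_ids},
#'   \code{partially_missing_ids}).
#' @export
validate_cohort <- function(cohort) {
  rep <- attr(cohort, "validation")
  if (is.null(rep)) {
    rep <- list(
      n_records = nrow(cohort),
      n_bcva_complete = sum(!is.na(cohort$bcva_le) & !is.na(cohort$bcva_re)),
      bcva_missing_ids = cohort$proband_id[
        is.na(cohort$bcva_le) | is.na(cohort$bcva_re)],
      partially_missing_ids = cohort$proband_id[
        xor(is.na(cohort$bcva_le), is.na(cohort$bcva_re))])
  }
  cat(sprintf("cohort: %d records, %d with BCVA for both eyes\n",
              rep$n_records, rep$n_bcva_complete))
  if (length(rep$bcva_missing_ids))
    cat("BCVA missing:", paste(rep$bcva_missing_ids, collapse = ", "), "\n")
  if (length(rep$partially_missing_ids))
    cat("single-eye BCVA (flagged partially missing):",
        paste(rep$partially_missing_ids, collapse = ", "), "\n")
  invisible(rep)
}

#' Write a cohort table
#'
#' Missing values are encoded as \code{"NA"}; numeric columns use the
#' decimal point. A write-then-read round trip is the identity on all
#' non-missing fields.
#'
#' @param cohort A \code{bv_cohort} data frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  drop <- intersect(c("variant", "truncating", "bcva_complete"),
                    names(cohort))
  out <- as.data.frame(cohort)[, setdiff(names(cohort), drop), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Group proband records by protein variant
#'
#' The grouping key is the canonical (reference, position, alternate)
#' triple, not the nucleotide change, so nucleotide-distinct variants
#' producing the same amino-acid replacement share a group.
#'
#' @param records A \code{bv_cohort} data frame.
#' @return A named list of data frames, one per canonical variant; the
#'   groups partition the records.
#' @examples
#' groups <- group_by_variant(read_cohort(bestqspr_example("probands.csv")))
#' groups[["p.(Asn296Lys)"]]$proband_id
#' @export
group_by_variant <- function(records) {
  if (any(is.na(records$variant)))
    stop("records with missing variant cannot be grouped", call. = FALSE)
  split(as.data.frame(records), records$variant)
}

#' Read a per-variant energy table
#'
#' Reads a delimited table of protein variants with their relative
#' dimerization energy (\code{dde_dim}) and relative calcium-binding energy
#' (\code{dde_cabin}), both in kcal/mol, an optional observed mean severity
#' index (\code{mean_bdsi}, percent) and optional semicolon-separated
#' residue-location labels. Truncating variants may carry missing energies.
#'
#' @inheritParams read_cohort
#' @return A data frame of class \code{bv_energy_table} with columns
#'   \code{group_id} (if present), \code{variant} (canonical),
#'   \code{truncating}, \code{dde_dim}, \code{dde_cabin}, \code{mean_bdsi}
#'   and \code{location} (a list column of label vectors).
#' @export
read_variant_energies <- function(path, dec = ".", sep = ",") {
  dec <- match.arg(dec, c(".", ","))
  raw <- .read_delim_chr(path, sep = sep)
  mandatory <- c("variant", "dde_dim", "dde_cabin")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- raw
  df$variant <- canonical_variant(raw$variant)
  df$truncating <- vapply(df$variant, function(v)
    parse_protein_variant(v)$truncating, logical(1), USE.NAMES = FALSE)
  df$dde_dim <- .parse_numeric(raw$dde_dim, dec, "dde_dim")
  df$dde_cabin <- .parse_numeric(raw$dde_cabin, dec, "dde_cabin")
  if ("mean_bdsi" %in% names(raw)) {
    df$mean_bdsi <- .parse_numeric(raw$mean_bdsi, dec, "mean_bdsi")
    bad <- which(!is.na(df$mean_bdsi) &
                   (df$mean_bdsi < 0 | df$mean_bdsi > 100))
    if (length(bad))
      stop(sprintf("mean_bdsi outside [0, 100] at data row %d", bad[1]),
           call. = FALSE)
  } else {
    df$mean_bdsi <- NA_real_
  }
  if ("pmva" %in% names(raw)) df$pmva <- .parse_numeric(raw$pmva, dec, "pmva")
  bad_e <- which(!df$truncating & (is.na(df$dde_dim) | is.na(df$dde_cabin)))
  if (length(bad_e))
    stop(sprintf("non-truncating variant with missing energies at data row %d",
                 bad_e[1]), call. = FALSE)
  if ("location" %in% names(raw)) {
    loc <- raw$location
    loc[loc %in% .NA_STRINGS] <- NA_character_
    df$location <- lapply(loc, function(s)
      if (is.na(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]])
  } else {
    df$location <- rep(list(character(0)), nrow(df))
  }
  class(df) <- c("bv_energy_table", "data.frame")
  df
}

#' Path to a packaged example data file
#'
#' The package ships the source study's proband cohort
#' (\code{"probands.csv"}, 36 probands), the per-variant energy table
#' (\code{"variant_energies.csv"}, 25 variants with relative dimerization
#' and calcium-binding energies) and a derived per-sex carrier-count table
#' (\code{"carrier_counts_derived.csv"}; the per-sex integer decomposition
#' is reconstructed from the published percentages, not itself published).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
bestqspr_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "bestqspr")))
  path <- system.file("extdata", file, package = "bestqspr")
  if (!nzchar(path)) stop("no packaged file named '", file, "'",
                          call. = FALSE)
  path
}

#' Export parsed proband records as JSON
#'
#' @param cohort A \code{bv_cohort} data frame.
#' @param path Output path for a JSON array of record objects.
#' @return Invisibly, \code{path}.
#' @export
export_cohort_json <- function(cohort, path) {
  jsonlite::write_json(as.data.frame(cohort), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
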