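#' @keywords internal
.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

.normalize_aa3 <- function(code) {
  paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, nchar(code))))
}

#' Parse a protein-level variant in p.(RefPosAlt) notation
#'
#' Parses a protein sequence variant written with three-letter amino-acid
#' codes, e.g. \code{"p.(Thr2Ile)"}, into its (reference residue, position,
#' alternate residue) triple. Stop gains written with \code{"*"} or
#' \code{"Ter"} are flagged as truncating; truncating variants carry no
#' dimerization energies and are excluded from energy-based prediction
#' downstream. The surrounding parentheses are optional on input but are
#' always present in the canonical form.
#'
#' @param text A single non-empty variant string.
#' @return An object of class \code{protein_variant}: a list with elements
#'   \code{ref}, \code{position}, \code{alt} (three-letter codes, \code{"*"}
#'   for a stop), \code{truncating} and \code{raw} (the original string).
#'   \code{format()} and \code{as.character()} return the canonical
#'   \code{"p.(RefPosAlt)"} form.
#' @examples
#' parse_protein_variant("p.(Thr2Ile)")
#' parse_protein_variant("p.(Arg200*)")$truncating
#' @export
parse_protein_variant <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("variant notation must be a single non-empty string", call. = FALSE)
  s <- trimws(text)
  m <- regmatches(s, regexec(
    "^p\\.(\\()?([A-Za-z]{3})([0-9]+)((?:[A-Za-z]{3})|\\*)(\\))?$", s))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed protein variant notation: '%s'", s),
         call. = FALSE)
  open <- nzchar(m[2]); close <- nzchar(m[6])
  if (open != close)
    stop(sprintf("unbalanced parentheses in variant notation: '%s'", s),
         call. = FALSE)
  ref <- .normalize_aa3(m[3])
  pos <- as.integer(m[4])
  alt_raw <- m[5]
  if (!ref %in% .AA3)
    stop(sprintf("unknown residue code '%s' in '%s'", m[3], s),
         call. = FALSE)
  if (pos < 1L)
    stop(sprintf("residue position must be >= 1, got %d in '%s'", pos, s),
         call. = FALSE)
  if (alt_raw == "*") {
    alt <- "*"
  } else {
    alt <- .normalize_aa3(alt_raw)
    if (identical(alt, "Ter")) {
      alt <- "*"
    } else if (!alt %in% .AA3) {
      stop(sprintf("unknown residue code '%s' in '%s'", alt_raw, s),
           call. = FALSE)
    }
  }
  structure(
    list(ref = ref, position = pos, alt = alt,
         truncating = identical(alt, "*"), raw = text),
    class = "protein_variant")
}

#' @export
format.protein_variant <- function(x, ...) {
  sprintf("p.(%s%d%s)", x$ref, x$position, x$alt)
}

#' @export
as.character.protein_variant <- function(x, ...) format(x)

#' @export
print.protein_variant <- function(x, ...) {
  cat(format(x),
      if (x$truncating) " [truncating]" else "", "\n", sep = "")
  invisible(x)
}

#' Canonicalize protein-variant strings
#'
#' Vectorized canonical form used as the grouping key: nucleotide-distinct
#' changes yielding the same amino-acid replacement map to the same string.
#'
#' @param text Character vector of variant strings; \code{NA} passes through.
#' @return Character vector of canonical \code{"p.(RefPosAlt)"} strings.
#' @export
canonical_variant <- function(text) {
  vapply(text, function(s) {
    if (is.na(s)) return(NA_character_)
    format(parse_protein_variant(s))
  }, character(1), USE.NAMES = FALSE)
}
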