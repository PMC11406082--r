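#' Canonical essential amino acid keys
#'
#' The ten scored entities, in the fixed canonical order used for all
#' serialization, reporting, and tie-breaking. Phenylalanine and tyrosine are
#' combined (`PHE_TYR`) because reference patterns give no individual
#' recommendation for either; cysteine is tracked separately from methionine
#' so that the unidirectional Met-to-Cys top-up (see [met_cys_topup()]) can be
#' applied.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' eaa_keys()
eaa_keys <- function() {
  c("HIS", "ILE", "LEU", "LYS", "MET", "CYS", "PHE_TYR", "THR", "TRP", "VAL")
}

# lower-case column names used in the external CSV/JSON schema, same order
eaa_cols <- function() tolower(eaa_keys())

#' Construct an amino acid vector
#'
#' A named non-negative numeric vector over the canonical EAA set. Entries not
#' supplied are zero, never missing. Units depend on context: mg per g protein
#' in food tables and reference patterns, absolute mg in intakes and
#' requirements.
#'
#' @param ... Named values, names from [eaa_keys()] (case-insensitive), or a
#'   single named numeric vector/list.
#' @return Named numeric vector of length 10 in canonical order.
#' @export
#' @examples
#' aa_vector(LYS = 45, MET = 16)
aa_vector <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  out <- stats::setNames(numeric(10L), eaa_keys())
  if (length(args)) {
    nm <- toupper(names(args))
    bad <- setdiff(nm, eaa_keys())
    if (length(bad)) {
      stop("unknown amino acid key(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(eaa_keys(), collapse = ", "), call. = FALSE)
    }
    vals <- vapply(args, function(x) as.numeric(x)[1], numeric(1))
    if (anyNA(vals)) stop("amino acid values must be numeric and non-missing", call. = FALSE)
    out[nm] <- vals
  }
  if (any(out < 0)) stop("amino acid values must be non-negative", call. = FALSE)
  out
}

# coerce a candidate to a full canonical vector, zero-filling absences
as_aa_vector <- function(x) {
  if (is.numeric(x) && !is.null(names(x)) &&
      identical(names(x), eaa_keys())) {
    return(x)
  }
  aa_vector(x)
}

#' FAO/WHO adult amino acid reference pattern
#'
#' The built-in reference pattern (mg of each EAA per g of dietary protein)
#' for individuals older than 3 years. Multiplying by a protein target in
#' g/kg body weight yields per-kilogram EAA requirements: at the 0.3 g/kg
#' per-meal target the pattern gives His 4.5, Ile 9, Leu 17.7, Lys 13.5,
#' Met 4.8, Cys 1.8, Phe+Tyr 11.4, Thr 6.9, Trp 1.8, Val 11.7 mg/kg.
#' The constructor verifies that product to one decimal and refuses to return
#' a pattern that fails it.
#'
#' @return Named numeric vector (mg/g protein) over [eaa_keys()].
#' @export
#' @examples
#' reference_pattern() * 0.3  # per-meal mg/kg body weight
reference_pattern <- function() {
  pat <- aa_vector(
    HIS = 15, ILE = 30, LEU = 59, LYS = 45, MET = 16,
    CYS = 6, PHE_TYR = 38, THR = 23, TRP = 6, VAL = 39
  )
  check <- c(4.5, 9, 17.7, 13.5, 4.8, 1.8, 11.4, 6.9, 1.8, 11.7)
  if (any(abs(round(pat * 0.3, 1) - check) > 0)) {
    stop("internal reference pattern failed its self-check", call. = FALSE)
  }
  pat
}

# validate a user-supplied pattern override
validate_pattern <- function(pattern) {
  pattern <- as_aa_vector(pattern)
  if (any(pattern <= 0)) {
    stop("reference pattern entries must all be positive", call. = FALSE)
  }
  pattern
}

# half-up rounding for published-style integer percentages; round() in R is
# round-half-even, which does not match printed nutrition tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
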