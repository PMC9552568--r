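#' Diagnosis-code sets used for SCD case finding
#'
#' The surveillance code set covers the ICD-9-CM 282.4x/282.6x sickle cell
#' disease family plus the trait code 282.5, and the ICD-10-CM D57 family with
#' its trait subfamily D57.3x. The set ships as a versioned plain-text table so
#' that a state program can extend it through configuration rather than code.
#'
#' @param path Optional path to an alternative code table (TSV with columns
#'   `system`, `code`, `category`, `wildcard`, `label`).
#' @return A tibble with one row per code or code prefix.
#' @examples
#' icd_code_table()
#' @export
icd_code_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "icd_scd_codes.tsv",
                                package = "scdlink", mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    system = readr::col_character(),
    code = readr::col_character(),
    category = readr::col_character(),
    wildcard = readr::col_logical(),
    label = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(tab$system), c("ICD9", "ICD10"))
  if (length(bad)) {
    scdlink_abort(sprintf("unknown code system in code table: %s",
                          paste(bad, collapse = ", ")),
                  class = "scdlink_code_error")
  }
  tab
}

#' Normalize raw diagnosis code strings
#'
#' Claims extracts frequently carry codes without the decimal point
#' (`"2826"`, `"D5701"`). This inserts the point at the position the coding
#' system defines (ICD-9-CM: after three digits; ICD-10-CM: after three
#' characters), upper-cases and trims. Codes already carrying a point pass
#' through unchanged.
#'
#' @param system `"ICD9"` or `"ICD10"` (vector, recycled).
#' @param code Character vector of raw code strings.
#' @return Normalized code strings.
#' @examples
#' normalize_icd("ICD9", "28260")   # "282.60"
#' normalize_icd("ICD10", "D5701")  # "D57.01"
#' @export
normalize_icd <- function(system, code) {
  n <- max(length(system), length(code))
  system <- rep_len(as.character(system), n)
  code <- toupper(trimws(rep_len(as.character(code), n)))
  plain <- !is.na(code) & !grepl(".", code, fixed = TRUE) & nchar(code) > 3L
  code[plain] <- paste0(substr(code[plain], 1, 3), ".", substring(code[plain], 4))
  code
}

#' @noRd
icd_syntax_ok <- function(system, code) {
  ifelse(system == "ICD9",
         grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", code),
         grepl("^[A-Z][0-9]{2}(\\.[A-Z0-9]{1,4})?$", code))
}

#' Classify a diagnosis code as SCD, trait, or other
#'
#' Pure classification of normalized codes into the three surveillance
#' categories. ICD-10-CM family rows marked as wildcards match any suffix
#' (so `D57.819` falls under the `D57.8` family); the trait family `D57.3x`
#' takes precedence over the bare `D57` row, which otherwise classifies as
#' SCD on its own. Unknown code systems and syntactically invalid codes are
#' rejected loudly rather than treated as `OTHER`, so schema drift in an
#' upstream extract surfaces immediately.
#'
#' @param system `"ICD9"` or `"ICD10"` (vector, recycled against `code`).
#' @param code Character vector of normalized codes (see [normalize_icd()]).
#' @param table Code table from [icd_code_table()].
#' @return Character vector with values `"SCD"`, `"TRAIT"` or `"OTHER"`.
#' @examples
#' classify_icd("ICD9", "282.5")    # TRAIT
#' classify_icd("ICD10", "D57.819") # SCD (D57.8 family)
#' classify_icd("ICD10", "D57.31")  # TRAIT (D57.3 family)
#' @export
classify_icd <- function(system, code, table = icd_code_table()) {
  n <- max(length(system), length(code))
  system <- rep_len(as.character(system), n)
  code <- rep_len(as.character(code), n)
  bad_sys <- !system %in% c("ICD9", "ICD10")
  if (any(bad_sys)) {
    scdlink_abort(sprintf("unknown code system: %s",
                          paste(unique(system[bad_sys]), collapse = ", ")),
                  class = "scdlink_code_error")
  }
  bad_code <- is.na(code) | !icd_syntax_ok(system, code)
  if (any(bad_code)) {
    scdlink_abort(sprintf("malformed %s code: %s",
                          system[bad_code][1], code[bad_code][1]),
                  class = "scdlink_code_error")
  }

  out <- rep("OTHER", n)
  exact <- table[!table$wildcard, ]
  wild <- table[table$wildcard, ]
  # wildcard families, trait last so the D57.3x family overrides bare-D57/SCD
  wild <- wild[order(wild$category == "TRAIT"), ]
  key <- paste(system, code)
  hit <- match(key, paste(exact$system, exact$code))
  out[!is.na(hit)] <- exact$category[hit[!is.na(hit)]]
  for (k in seq_len(nrow(wild))) {
    sel <- system == wild$system[k] & startsWith(code, wild$code[k])
    out[sel] <- wild$category[k]
  }
  out
}
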