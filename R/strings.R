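#' American Soundex code
#'
#' Classic four-character Soundex used as a phonetic blocking key: surname
#' variants that sound alike ("Smith"/"Smyth") share a key, so candidate pairs
#' survive common spelling noise. Letters separated by H or W are treated as
#' adjacent, per the standard (census) algorithm.
#'
#' @param x Character vector of names.
#' @return Character vector of codes such as `"S530"`; `NA` for inputs with no
#'   leading letter.
#' @examples
#' soundex(c("Robert", "Rupert", "Ashcraft", "Tymczak"))
#' @export
soundex <- function(x) {
  digits <- c(
    B = "1", F = "1", P = "1", V = "1",
    C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2", Z = "2",
    D = "3", T = "3",
    L = "4",
    M = "5", N = "5",
    R = "6"
  )
  vapply(x, function(s) {
    s <- toupper(gsub("[^A-Za-z]", "", s %||% ""))
    if (is.na(s) || nchar(s) == 0L) return(NA_character_)
    chars <- strsplit(s, "")[[1]]
    codes <- unname(digits[chars]) # NA for vowels + H W Y
    out <- substr(s, 1, 1)
    prev <- codes[1] # code of the first letter, for the duplicate rule
    for (i in seq_along(chars)[-1]) {
      ch <- chars[i]
      code <- codes[i]
      if (ch %in% c("H", "W")) next # transparent: do not reset `prev`
      if (!is.na(code)) {
        if (is.na(prev) || code != prev) out <- paste0(out, code)
      }
      prev <- code
    }
    substr(paste0(out, "000"), 1, 4)
  }, character(1), USE.NAMES = FALSE)
}

#' Jaro-Winkler string similarity
#'
#' Edit similarity in `[0, 1]` used for name comparison in record linkage:
#' the Jaro similarity (matches within a sliding window, penalised for
#' transpositions) boosted for a shared prefix of up to four characters with
#' the usual scaling factor 0.1.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Numeric vector of similarities; `NA` where either input is `NA`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA") # 0.961
#' jaro_winkler("SMITH", "SMYTH")
#' @export
jaro_winkler <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  # cache distinct pairs: linkage compares many repeated name pairs
  key <- paste(a, b, sep = "\r")
  uniq <- !duplicated(key)
  vals <- vapply(which(uniq), function(i) jw_one(a[i], b[i]), numeric(1))
  names(vals) <- key[uniq]
  out <- unname(vals[key])
  out[is.na(a) | is.na(b)] <- NA_real_
  out
}

#' @noRd
jw_one <- function(s1, s2) {
  if (is.na(s1) || is.na(s2)) return(NA_real_)
  if (s1 == s2) return(1)
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 == 0L || l2 == 0L) return(0)
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  window <- max(floor(max(l1, l2) / 2) - 1, 0)
  used2 <- logical(l2)
  m1 <- integer(0) # indices into c1 of matched chars, in order
  m2 <- integer(0)
  for (i in seq_len(l1)) {
    lo <- max(1L, i - window); hi <- min(l2, i + window)
    for (j in seq(lo, length.out = max(hi - lo + 1L, 0L))) {
      if (!used2[j] && c1[i] == c2[j]) {
        used2[j] <- TRUE
        m1 <- c(m1, i); m2 <- c(m2, j)
        break
      }
    }
  }
  m <- length(m1)
  if (m == 0L) return(0)
  # transpositions: matched characters out of relative order, halved
  t <- sum(c1[m1] != c2[sort(m2)]) / 2
  jaro <- (m / l1 + m / l2 + (m - t) / m) / 3
  prefix <- 0L
  for (k in seq_len(min(4L, l1, l2))) {
    if (c1[k] == c2[k]) prefix <- k else break
  }
  jaro + prefix * 0.1 * (1 - jaro)
}

# Canonical form for identifier strings before comparison: case-fold,
# strip internal whitespace, and turn empty strings into NA.
#' @noRd
normalize_name <- function(x) {
  x <- toupper(gsub("\\s+", "", as.character(x)))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}
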