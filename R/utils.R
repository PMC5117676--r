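#' @keywords internal
"_PACKAGE"

## Half-up rounding is used everywhere a percentage is reported, because the
## survey tables this package reproduces round that way (R's round() is
## round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## percentage of n out of d, 2 dp half-up
pct2 <- function(n, d, digits = 2) round_half_up(100 * n / d, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a plain character DNA string
#'
#' Vectorised over `x`.  Any base outside `A/C/G/T` must already be `N`.
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Normalise a base string: uppercase, anything outside ACGT becomes N.
normalize_bases <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

## all cyclic rotations of a short string
rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  dbl <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(dbl, i, i + k - 1L), character(1))
}

## smallest period of a short string (== nchar(m) iff primitive)
smallest_period <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        m == strrep(substr(m, 1L, d), k %/% d)) {
      return(d)
    }
  }
  k
}

is_primitive_motif <- function(m) smallest_period(m) == nchar(m)

stop_contract <- function(...) stop(..., call. = FALSE)
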