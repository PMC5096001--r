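#' Natural isotope abundance table
#'
#' Per-element vectors of natural isotope abundances indexed by mass shift
#' (position 1 = lightest isotope, position 2 = +1 mass shift, ...). The
#' defaults are the IUPAC representative natural abundances for the elements
#' that occur in TBDMS-derivatized amino-acid fragments: C, H, N, O, Si, S.
#'
#' @param overrides named list of numeric vectors replacing the default
#'   abundance vector of an element, e.g. `list(C = c(0.99, 0.01))`.
#' @return object of class `isotope_table`: named list of abundance vectors,
#'   each summing to 1.
#' @export
isotope_table <- function(overrides = NULL) {
  tab <- list(
    C  = c(1 - 0.0107, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.0467 - 0.0310, 0.0467, 0.0310),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
  )
  if (!is.null(overrides)) {
    for (el in names(overrides)) {
      v <- as.numeric(overrides[[el]])
      if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
        stop("isotope abundances for ", el, " must be non-negative and sum to 1")
      tab[[el]] <- v
    }
  }
  structure(tab, class = "isotope_table")
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("<isotope_table>\n")
  for (el in names(x))
    cat(sprintf("  %-2s: %s\n", el, paste(signif(x[[el]], 6), collapse = " ")))
  invisible(x)
}

#' Convolve two mass isotopomer distributions
#'
#' Discrete convolution, i.e. the MID of the combined molecule formed from two
#' independently labeled parts. Length of the result is
#' `length(a) + length(b) - 1`.
#'
#' @param a,b numeric MID vectors (non-negative, summing to 1).
#' @return numeric MID vector.
#' @export
convolve_mid <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Natural-abundance MID of a carbon backbone
#'
#' Binomial distribution of the number of naturally occurring 13C atoms among
#' `n_carbons` carbon positions (heavier carbon isotopes are ignored).
#'
#' @param n_carbons number of carbon atoms (>= 0).
#' @param table an [isotope_table()].
#' @return numeric vector of length `n_carbons + 1`.
#' @export
natural_mid <- function(n_carbons, table = isotope_table()) {
  if (n_carbons < 0) stop("n_carbons must be non-negative")
  p13 <- table$C[2]
  stats::dbinom(0:n_carbons, n_carbons, p13)
}

# n-fold self-convolution of a per-atom isotope distribution: mass-shift
# distribution of n atoms of one element (multinomial collapsed to shifts).
element_shift_dist <- function(abund, n) {
  out <- 1
  if (n > 0) for (i in seq_len(n)) out <- convolve_mid(out, abund)
  out
}

# Validate an MID vector; returns normalized copy.
check_mid <- function(x, tol = 1e-6) {
  if (any(x < -tol)) stop("MID has negative fractions")
  s <- sum(x)
  if (abs(s - 1) > tol) stop("MID does not sum to 1 (sum = ", s, ")")
  pmax(x, 0) / sum(pmax(x, 0))
}
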