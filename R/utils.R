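# Physical constants (CODATA 2018, unified atomic mass units)
.PROTON_MASS <- 1.007276466621
.ELECTRON_MASS <- 0.000548579909065

#' Monoisotopic mass of the hydrogen atom
#'
#' Mass of one neutral hydrogen atom (proton + electron, electron binding
#' energy negligible at this precision), truncated to a fixed number of
#' decimals. This is the neutralization mass used when converting between
#' `[M+H]+` / `[M-H]-` ion m/z and the neutral monoisotopic mass M during
#' cross-polarity merging.
#'
#' @param digits number of decimal places to truncate to (default 5, the
#'   precision at which merge tolerances are stated).
#' @return numeric scalar, Da.
#' @examples
#' hydrogen_mass() # 1.00782
#' @export
hydrogen_mass <- function(digits = 5) {
  m <- .PROTON_MASS + .ELECTRON_MASS
  trunc(m * 10^digits) / 10^digits
}

#' Relative mass error in parts per million
#'
#' @param a,b masses in Da. The error is relative to the midpoint, so the
#'   function is symmetric in its arguments.
#' @return numeric, ppm.
#' @export
ppm_error <- function(a, b) {
  abs(a - b) / ((a + b) / 2) * 1e6
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook step-up procedure: order p-values, compute `p * n / rank`, and
#' enforce monotonicity from the largest p downward. Equivalent to
#' `stats::p.adjust(p, "BH")` (used as an independent oracle in the test
#' suite, never as the implementation).
#'
#' @param p numeric vector of p-values in `[0, 1]`; NA allowed and propagated.
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  if (n == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  q
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Monoisotopic masses of the elements handled in formula parsing.
.ELEMENT_MASS <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, Cl = 34.96885268,
  F = 18.99840322, Br = 78.9183371, Si = 27.9769265325, K = 38.96370668
)

#' Monoisotopic mass of an elemental formula
#'
#' @param formula string such as `"C6H12O6"`. Supported elements: C, H, N, O,
#'   P, S, Na, Cl, F, Br, Si, K.
#' @return neutral monoisotopic mass in Da, or NA for an empty/NA formula.
#' @export
formula_mass <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  total <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]+", "", tk)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!el %in% names(.ELEMENT_MASS))
      stop("unsupported element in formula: ", el, call. = FALSE)
    total <- total + .ELEMENT_MASS[[el]] * cnt
  }
  total
}

# row-wise variance of a numeric matrix, NA-tolerant
row_vars <- function(x, na.rm = FALSE) {
  m <- rowMeans(x, na.rm = na.rm)
  n <- if (na.rm) rowSums(!is.na(x)) else ncol(x)
  rowSums((x - m)^2, na.rm = na.rm) / (n - 1)
}
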