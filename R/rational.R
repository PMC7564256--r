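# Internal exact rational arithmetic.
#
# Stoichiometric coefficients are kept as reduced integer fractions
# (numerator/denominator pairs stored in doubles, which are exact for the
# magnitudes arising here). Decimal coefficients such as 3.75 are parsed to
# 15/4 so that composed reactions reproduce printed coefficients bit-exactly.

.gcd1 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    t <- a %% b
    a <- b
    b <- t
  }
  if (a < 0.5) 1 else a
}

.gcd <- function(a, b) mapply(.gcd1, a, b)

# reduce n/d to canonical form: gcd 1, d > 0
.ratReduce <- function(n, d) {
  if (any(d == 0)) stop("zero denominator in rational coefficient")
  s <- ifelse(d < 0, -1, 1)
  n <- n * s
  d <- d * s
  g <- .gcd(n, d)
  list(n = n / g, d = d / g)
}

.ratAdd <- function(n1, d1, n2, d2) .ratReduce(n1 * d2 + n2 * d1, d1 * d2)

.ratMul <- function(n1, d1, n2, d2) .ratReduce(n1 * n2, d1 * d2)

.ratEq <- function(n1, d1, n2, d2) (n1 == n2) & (d1 == d2)

# parse "9", "-1", "3.75", "15/4" into a reduced rational
.parseRational <- function(text) {
  text <- trimws(text)
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("empty coefficient")
  if (grepl("^[+-]?[0-9]+$", text)) {
    return(.ratReduce(as.numeric(text), 1))
  }
  if (grepl("^[+-]?[0-9]*\\.[0-9]+$", text)) {
    frac <- sub("^[+-]?[0-9]*\\.", "", text)
    k <- nchar(frac)
    return(.ratReduce(as.numeric(text) * 10^k, 10^k))
  }
  if (grepl("^[+-]?[0-9]+/[0-9]+$", text)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1]]
    return(.ratReduce(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  stop(sprintf("cannot parse coefficient '%s'", text))
}

# snap a double to the simplest nearby fraction (continued-fraction
# expansion); doubles arising from expressions like 1/3 or 0.25 recover
# their exact rational value
.ratFromNumeric <- function(x, tol = 1e-9, maxDen = 1e6) {
  if (length(x) != 1L || is.na(x)) stop("need a single finite number")
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > maxDen) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h1 / k1) < tol * max(1, x)) break
    if (b == a) break
    b <- 1 / (b - a)
  }
  .ratReduce(sign * h1, k1)
}

# render a reduced rational the way the source tables print it:
# integers bare, finite decimals as decimals, everything else as n/d
.formatRational <- function(n, d) {
  out <- character(length(n))
  for (i in seq_along(n)) {
    if (d[i] == 1) {
      out[i] <- format(n[i])
    } else {
      dec <- n[i] / d[i]
      # denominators 2^a * 5^b have exact finite decimal expansions
      dd <- d[i]
      while (dd %% 2 == 0) dd <- dd / 2
      while (dd %% 5 == 0) dd <- dd / 5
      if (dd == 1) {
        out[i] <- format(dec, drop0trailing = TRUE)
      } else {
        out[i] <- sprintf("%d/%d", n[i], d[i])
      }
    }
  }
  out
}
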