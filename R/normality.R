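#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe-Glynn (1983) transformed kurtosis statistic into the omnibus
#' K-squared statistic, referred to a chi-squared distribution with two
#' degrees of freedom (D'Agostino, Belanger & D'Agostino 1990). Moment
#' statistics use the biased (population, n-denominator) sample moments.
#' Requires at least 8 observations for the kurtosis transform to be
#' defined.
#'
#' @param x Numeric vector; `NA` removed.
#' @return A list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson test requires at least 8 observations",
         call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    return(list(statistic = NA_real_, p_value = 1, z_skew = 0, z_kurt = 0,
                n = n))
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino (1970) Johnson SU transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn (1983) cube-root transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  term <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}
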