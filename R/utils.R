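#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return object of the same shape with every value wrapped to (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # modulo puts exact multiples of 2*pi at -pi; convention is (-pi, pi]
  w[!is.na(w) & w <= -pi] <- pi
  w
}

#' Circular mean and resultant length
#'
#' Mean direction is the argument of the complex mean resultant; the phase
#' locking value (PLV) is its modulus. `NA` angles (masked samples) are
#' excluded.
#'
#' @param theta angles in radians.
#' @return list with `mean` (radians in (-pi, pi]), `plv` in \[0, 1\] and `n`,
#'   the number of non-missing angles used.
#' @export
circular_stats <- function(theta) {
  theta <- theta[!is.na(theta)]
  n <- length(theta)
  if (n == 0L) {
    return(list(mean = NA_real_, plv = NA_real_, n = 0L))
  }
  z <- complex(real = mean(cos(theta)), imaginary = mean(sin(theta)))
  list(mean = Arg(z), plv = Mod(z), n = n)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative, using the mean resultant length and
#' the standard small-sample correction of the p-value.
#'
#' @param angles angles in radians; at least 10 non-missing values.
#' @return list with `r_bar` (mean resultant length), `statistic`
#'   (Z = n * r_bar^2), `p.value` and `n`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 10L) {
    stop("rayleigh_test() requires at least 10 angles, got ", n)
  }
  cs <- circular_stats(angles)
  r_bar <- cs$plv
  bigR <- n * r_bar
  z <- n * r_bar^2
  # Zar's approximation; accurate for n >= 10
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - bigR^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  list(r_bar = r_bar, statistic = z, p.value = p, n = n)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

# deterministic sub-stream seeds: one session seed is split per component so
# that adding noise to one component does not perturb the draws of another
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + as.numeric(k) * 12345 + 17) %%
               2147483647)
}

# random permutation of 1..n with no fixed points (n >= 2)
derangement <- function(n) {
  if (n < 2L) stop("derangement requires n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
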