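#' Photoreceptor quantum catch
#'
#' Integral of sensitivity times radiance over wavelength. For an
#' `lc_cone` the `net` sensitivity is used, which already includes the
#' oil-droplet and ocular-media factors, so no media spectrum may be
#' applied again; for a plain sensitivity [lc_spectrum] the caller
#' supplies exactly the factors to be integrated via `media`.
#'
#' @param sens An `lc_cone` or a sensitivity [lc_spectrum].
#' @param radiance A radiance (or any) [lc_spectrum] on the same grid.
#' @param media Optional extra transmittance [lc_spectrum]; forbidden for
#'   `lc_cone` input (it is already folded into `net`).
#' @return Scalar quantum catch (arbitrary units).
#' @export
quantum_catch <- function(sens, radiance, media = NULL) {
  if (inherits(sens, "lc_cone")) {
    if (!is.null(media))
      stop("cone `net` sensitivity already includes the ocular media; ",
           "passing `media` would double-apply it", call. = FALSE)
    sens <- sens$net
  }
  stopifnot(is_spectrum(sens), is_spectrum(radiance))
  if (is.null(media)) integrate_product(sens, radiance)
  else integrate_product(sens, media, radiance)
}

#' Michelson contrast between two quantum catches
#'
#' `(Q_u - Q_l) / (Q_u + Q_l)`, signed: positive when the upper surface
#' is the brighter one.
#'
#' @param Q_u,Q_l Non-negative quantum catches; their sum must be
#'   positive.
#' @return Scalar in \[-1, 1\].
#' @export
michelson <- function(Q_u, Q_l) {
  if (Q_u + Q_l <= 0)
    stop("Michelson contrast undefined: both quantum catches are zero",
         call. = FALSE)
  (Q_u - Q_l) / (Q_u + Q_l)
}

#' Relative contrast performance of the V-cone over the U-cone
#'
#' `R = C_V - C_U`; positive values mean the V (violet) cone sees the
#' higher leaf-contrast, negative the U (ultraviolet) cone.
#'
#' @param C_V,C_U Michelson contrasts in \[-1, 1\].
#' @return Scalar difference.
#' @export
relative_performance <- function(C_V, C_U) {
  stopifnot(abs(C_V) <= 1 + 1e-12, abs(C_U) <= 1 + 1e-12)
  C_V - C_U
}

#' Receptor-noise-limited color distance (JND)
#'
#' Chromatic distance between two stimuli in the receptor-noise-limited
#' model with log-transformed quantum catches: the per-channel signals
#' are `df_i = ln(Q_u_i / Q_l_i)` and the distance for n channels with
#' noise `e_i` (the Weber fractions) is
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \ne i,j} e_k^2)
#'   (df_i - df_j)^2}{\sum_i \prod_{k \ne i} e_k^2}}
#' which reduces to the familiar closed forms for di-, tri- and
#' tetrachromats. One unit is approximately one just noticeable
#' difference.
#'
#' @param Q_u,Q_l Named (or positionally matched) positive quantum-catch
#'   vectors for the two stimuli; at least two channels.
#' @param weber Per-channel Weber fractions (noise), positive.
#' @return Scalar distance in JND units.
#' @examples
#' rnl_color_distance(c(1.2, 1), c(1, 1), weber = c(0.069, 0.069))
#' @export
rnl_color_distance <- function(Q_u, Q_l, weber) {
  n <- length(Q_u)
  if (n < 2)
    stop("need at least two receptor channels (use michelson() for ",
         "achromatic contrast)", call. = FALSE)
  if (length(Q_l) != n || length(weber) != n)
    stop("Q_u, Q_l and weber must have the same length", call. = FALSE)
  if (!is.null(names(Q_u)) && !is.null(names(Q_l)))
    Q_l <- Q_l[names(Q_u)]
  if (any(Q_u <= 0) || any(Q_l <= 0))
    stop("quantum catches must be positive for the log transform",
         call. = FALSE)
  if (any(weber <= 0)) stop("Weber fractions must be positive", call. = FALSE)
  df <- log(Q_u / Q_l)
  e2 <- weber^2
  prod_e2 <- prod(e2)
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      num <- num + prod_e2 / (e2[i] * e2[j]) * (df[i] - df[j])^2
    }
  }
  den <- sum(prod_e2 / e2)
  sqrt(num / den)
}

#' Paired sign test
#'
#' Counts the positive differences among the non-zero ones and computes
#' the exact two-sided binomial probability under the null that positive
#' and negative differences are equally likely:
#' `p = min(1, 2 min(P(X <= s), P(X >= s)))` with `X ~ Binomial(n, 1/2)`.
#' Zero differences are dropped.
#'
#' @param diffs Numeric vector of signed paired differences; at least one
#'   must be non-zero.
#' @return List of class `lc_sign_test` with `statistic` (count of
#'   positive differences), `n` (count of non-zero differences) and `p`.
#' @examples
#' sign_test(c(2, 1, 3, 0.5, 0.1))
#' @export
sign_test <- function(diffs) {
  stopifnot(length(diffs) >= 1)
  diffs <- diffs[diffs != 0]
  if (!length(diffs))
    stop("all paired differences are zero: sign test is degenerate",
         call. = FALSE)
  s <- sum(diffs > 0)
  n <- length(diffs)
  p <- min(1, 2 * min(stats::pbinom(s, n, 0.5),
                      stats::pbinom(s - 1, n, 0.5, lower.tail = FALSE)))
  structure(list(statistic = s, n = n, p = p), class = "lc_sign_test")
}

#' @export
print.lc_sign_test <- function(x, ...) {
  cat(sprintf("Paired sign test: %d of %d differences > 0, two-sided p = %.4g\n",
              x$statistic, x$n, x$p))
  invisible(x)
}
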