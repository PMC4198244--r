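#' Per-channel receptor noise from cone proportions
#'
#' Channel noise for the receptor-noise-limited model, anchored so the most
#' abundant cone type has exactly the receiver's Weber fraction:
#' `e_i = omega * sqrt(eta_max / eta_i)`, with `eta_i` the relative cone
#' proportions. The double cone carries `e = omega`.
#'
#' @param receiver a `receiver_model`.
#' @return A `noise_vector`: named positive numeric (uv, sw, mw, lw, dbl).
#' @export
channel_noise <- function(receiver) {
  eta <- receiver$cone_proportions
  if (any(eta <= 0)) stop("cone proportions must be positive", call. = FALSE)
  omega <- receiver$weber_fraction
  e <- omega * sqrt(max(eta) / eta)
  out <- c(uv = e[["uv"]], sw = e[["sw"]], mw = e[["mw"]], lw = e[["lw"]],
           dbl = omega)
  structure(out, class = "noise_vector")
}

#' Chromatic just-noticeable difference (receptor-noise-limited model)
#'
#' Perceptual colour distance between two stimuli in just-noticeable
#' differences, using the log form of the receptor-noise-limited model for
#' a tetrachromat. Channel signals are `f_i = ln(q_i)`; the distance
#' weights the pairwise opponent differences by the noise of the remaining
#' channels:
#' \deqn{\Delta S^2 = \frac{\sum_{j<k} (e_l e_m)^2 (\Delta f_j - \Delta f_k)^2}
#'                        {\sum_{\mathrm{triples}} (e_a e_b e_c)^2}}
#' where for each cone pair (j, k), l and m are the other two cones. A pure
#' intensity change (all catches scaled equally) scores 0.
#'
#' @param qA,qB `quantum_catch_set`s with strictly positive chromatic
#'   catches.
#' @param noise a `noise_vector` (see [channel_noise()]).
#' @param channels chromatic channels used (default all four).
#' @return Nonnegative JND value.
#' @export
chromatic_jnd <- function(qA, qB, noise, channels = c("uv", "sw", "mw", "lw")) {
  a <- unclass(qA)[channels]; b <- unclass(qB)[channels]
  bad <- !(a > 0) | !(b > 0)
  if (any(bad))
    stop(sprintf("log-domain error: nonpositive catch in channel(s) %s",
                 paste(channels[bad], collapse = ", ")), call. = FALSE)
  e <- unclass(noise)[channels]
  df <- log(a) - log(b)
  n <- length(channels)
  num <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    others <- setdiff(seq_len(n), c(j, k))
    num <- num + prod(e[others])^2 * (df[j] - df[k])^2
  }
  den <- 0
  triples <- utils::combn(n, n - 1)
  for (t in seq_len(ncol(triples)))
    den <- den + prod(e[triples[, t]])^2
  unname(sqrt(num / den))
}

#' Achromatic (luminance) just-noticeable difference
#'
#' Double-cone luminance discrimination in the same log form:
#' `|ln(qA / qB)| / omega`.
#'
#' @param qA_dbl,qB_dbl positive double-cone catches.
#' @param omega Weber fraction of the achromatic channel.
#' @export
achromatic_jnd <- function(qA_dbl, qB_dbl, omega) {
  if (!(qA_dbl > 0) || !(qB_dbl > 0))
    stop("log-domain error: nonpositive double-cone catch", call. = FALSE)
  abs(log(qA_dbl / qB_dbl)) / omega
}

#' Classify a JND value
#'
#' Below 1 JND two stimuli are indistinguishable; 1--3 (inclusive) is a
#' marginal difference unlikely to be discriminated; above 3 differences
#' are increasingly likely to be discriminable.
#'
#' @param jnd nonnegative JND value(s).
#' @return Factor with levels indistinguishable, marginal, distinguishable.
#' @export
discriminability_class <- function(jnd) {
  if (any(jnd < 0)) stop("jnd must be nonnegative", call. = FALSE)
  cls <- cut(jnd, breaks = c(-Inf, 1, 3, Inf), right = FALSE,
             labels = c("indistinguishable", "marginal", "distinguishable"))
  # the 1--3 band is read as inclusive: exactly 3 is still marginal
  cls[jnd == 3] <- "marginal"
  cls
}

#' Background match of a fish in JNDs
#'
#' The chromatic and achromatic just-noticeable differences between a
#' fish's mean catches and its background's: the modelled conspicuousness
#' of the fish to the receiver.
#'
#' @param fish,background `quantum_catch_set`s.
#' @param receiver a `receiver_model`.
#' @return Named numeric: `chromatic_jnd`, `achromatic_jnd`.
#' @export
background_match <- function(fish, background, receiver) {
  noise <- channel_noise(receiver)
  c(chromatic_jnd = chromatic_jnd(fish, background, noise),
    achromatic_jnd = achromatic_jnd(unclass(fish)[["dbl"]],
                                    unclass(background)[["dbl"]],
                                    receiver$weber_fraction))
}
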