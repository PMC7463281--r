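# Gametic-phase LD decay under recombination alone.

#' Gametic linkage disequilibrium decay
#'
#' Under recombination alone, two-locus gametic disequilibrium erodes
#' geometrically: `D_t = (1 - c)^t * D0`.
#'
#' @param D0 Initial disequilibrium `D(AB)`.
#' @param c Recombination fraction per generation, in `[0, 0.5]`.
#' @param t Generations (non-negative; may be a vector, and may be
#'   real-valued for interpolation).
#' @return `D_t`, same length as `t`.
#' @export
#' @examples
#' gametic_decay(0.116, 0.0012, 577) # ~ half the initial value
gametic_decay <- function(D0, c, t) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 0.5) {
    abort("`c` must be a single recombination fraction in [0, 0.5].")
  }
  if (any(t < 0)) abort("`t` must be non-negative.")
  D0 * (1 - c)^t
}

#' Half-life of gametic LD under recombination
#'
#' Solves `(1 - c)^t = 1/2` for `t`: the number of generations for
#' disequilibrium to fall to half its initial value under recombination
#' alone.
#'
#' @param c Recombination fraction per generation, in `(0, 0.5]`.
#' @return A list with `half_life` (real-valued) and `rounded` (nearest
#'   integer generation).
#' @export
#' @examples
#' half_life(0.0012) # 577.26, rounded 577
#' half_life(0.5) # 1
half_life <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > 0.5) {
    abort("`c` must be a single recombination fraction in (0, 0.5].")
  }
  t <- log(0.5) / log(1 - c)
  list(half_life = t, rounded = round(t))
}
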