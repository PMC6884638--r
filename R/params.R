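#' Kinetic parameter set for the two-stage adsorption model
#'
#' Bundles the rate constants of the two-stage scheme. Chains with fewer than
#' \code{s} incorporated units propagate as coils at second-order rate
#' \code{k1}; chains with \code{s} or more units are helical and propagate by
#' reversible monomer adsorption (\code{kon}/\code{koff}) followed by
#' ring opening within the complex (\code{kr}).
#'
#' @param k1 coil-stage propagation rate constant, 1/(M s).
#' @param kon adsorption rate constant of monomer onto the helical
#'   N terminus, 1/(M s).
#' @param koff desorption rate constant of the helix-monomer complex, 1/s.
#' @param kr in-complex ring-opening rate constant, 1/s.
#' @param s critical chain length (degree of polymerization) at which the
#'   coil-to-helix transition occurs; integer, at least 2.
#' @return An object of class \code{rate_params}.
#' @examples
#' rate_params(k1 = 0.02, kon = 10, koff = 2, kr = 0.2, s = 10)
#' @export
rate_params <- function(k1, kon, koff, kr, s) {
  vals <- c(k1 = k1, kon = kon, koff = koff, kr = kr)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants must be finite and >= 0")
  }
  if (!is.finite(s) || s < 2 || s != round(s)) {
    stop("'s' must be an integer >= 2")
  }
  structure(
    list(k1 = k1, kon = kon, koff = koff, kr = kr, s = as.integer(s)),
    class = "rate_params"
  )
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Two-stage kinetic parameters:\n")
  cat(sprintf("  k1   = %g 1/(M s)   (coil propagation)\n", x$k1))
  cat(sprintf("  kon  = %g 1/(M s)   (adsorption)\n", x$kon))
  cat(sprintf("  koff = %g 1/s       (desorption)\n", x$koff))
  cat(sprintf("  kr   = %g 1/s       (in-complex ring opening)\n", x$kr))
  cat(sprintf("  s    = %d           (critical helix length, DP)\n", x$s))
  if (x$koff > 0) {
    cat(sprintf("  K = kon/koff = %g 1/M\n", x$kon / x$koff))
  }
  invisible(x)
}

#' Initial conditions of a polymerization run
#'
#' @param M0 initial monomer concentration, mol/L.
#' @param ratio monomer-to-initiator ratio \code{[M]0/[I]0} (sets the design
#'   degree of polymerization). Give either \code{ratio} or \code{I0}.
#' @param I0 initial initiator concentration, mol/L.
#' @return An object of class \code{initial_conditions} with fields
#'   \code{M0}, \code{I0} and \code{ratio}.
#' @examples
#' initial_conditions(M0 = 0.4, ratio = 100)
#' @export
initial_conditions <- function(M0, ratio = NULL, I0 = NULL) {
  if (!is.finite(M0) || M0 <= 0) stop("'M0' must be > 0")
  if (is.null(I0) && is.null(ratio)) stop("give one of 'ratio' or 'I0'")
  if (is.null(I0)) I0 <- M0 / ratio
  if (is.null(ratio)) ratio <- M0 / I0
  if (!is.finite(I0) || I0 <= 0) stop("'I0' must be > 0")
  if (abs(ratio - M0 / I0) > 1e-9 * ratio) {
    stop("'ratio' inconsistent with M0/I0")
  }
  structure(list(M0 = M0, I0 = I0, ratio = ratio),
            class = "initial_conditions")
}

#' @export
print.initial_conditions <- function(x, ...) {
  cat(sprintf("[M]0 = %g M, [I]0 = %g M ([M]0/[I]0 = %g)\n",
              x$M0, x$I0, x$ratio))
  invisible(x)
}
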