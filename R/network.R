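#' Assemble the truncated reaction network
#'
#' Builds the finite population-balance system for the two-stage scheme:
#' for \code{i < s}, \code{P_i + M -> P_{i+1}} at rate \code{k1*M*P_i};
#' for \code{i >= s}, \code{P_i + M <-> C_i} at rates \code{kon*M*P_i} /
#' \code{koff*C_i}, and \code{C_i -> P_{i+1}} at rate \code{kr*C_i}. The
#' initial state is \code{P_0 = I0}, \code{M = M0}, everything else zero
#' (the free initiator is treated as a chain of length zero and initiation
#' proceeds with the coil-stage constant \code{k1}).
#'
#' The infinite chain-length ladder is truncated at \code{Nmax}
#' (default \code{ceiling(4 * ratio)}, leaving ample headroom above the
#' design DP). So that chain count and monomer-unit count are conserved
#' exactly on the finite system, propagation and binding are switched off at
#' the top rung \code{i = Nmax}; simulations verify afterwards that the top
#' of the ladder is essentially unoccupied (see [simulate_kinetics()]).
#' Choosing \code{s > Nmax} is allowed and yields the degenerate
#' single-stage (pure coil growth) model.
#'
#' @param params a [rate_params()] object.
#' @param ic an [initial_conditions()] object.
#' @param Nmax truncation chain length, or \code{"auto"}.
#' @return An object of class \code{reaction_network}.
#' @examples
#' net <- build_network(rate_params(0.02, 10, 2, 0.2, 10),
#'                      initial_conditions(0.4, ratio = 100))
#' net$Nmax  # 400
#' @export
build_network <- function(params, ic, Nmax = "auto") {
  stopifnot(inherits(params, "rate_params"), inherits(ic, "initial_conditions"))
  if (identical(Nmax, "auto")) Nmax <- ceiling(4 * ic$ratio)
  if (!is.finite(Nmax) || Nmax < 2 || Nmax != round(Nmax)) {
    stop("'Nmax' must be an integer >= 2 or \"auto\"")
  }
  if (Nmax < 2 * ic$ratio && params$s <= Nmax) {
    warning("Nmax < 2 * ratio: the chain-length ladder may be too short")
  }
  structure(list(params = params, ic = ic, Nmax = as.integer(Nmax)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Two-stage adsorption reaction network\n")
  print(x$params)
  print(x$ic)
  cat(sprintf("  ladder truncated at Nmax = %d%s\n", x$Nmax,
              if (x$params$s > x$Nmax) " (single-stage limit: s > Nmax)" else ""))
  invisible(x)
}

# state vector layout of the full model:
#   y[1] = M; y[2..(Nmax+2)] = P_0..P_Nmax; then C_s..C_{Nmax-1}
state_dim <- function(network) {
  nC <- max(0L, network$Nmax - network$params$s)
  2L + network$Nmax + nC
}

initial_state_vector <- function(network) {
  y <- numeric(state_dim(network))
  nm <- c("M", paste0("P", 0:network$Nmax))
  if (network$Nmax > network$params$s) {
    nm <- c(nm, paste0("C", network$params$s:(network$Nmax - 1L)))
  }
  names(y) <- nm
  y["M"] <- network$ic$M0
  y["P0"] <- network$ic$I0
  y
}

#' Interpret a raw state vector as a chain state
#'
#' @param y numeric state vector in the full-ladder layout.
#' @param network the [build_network()] object that defines the layout.
#' @param t time stamp in seconds.
#' @param clamp clamp tiny negative integrator undershoot
#'   (values in \code{[-1e-12, 0)}) to zero.
#' @return An object of class \code{chain_state}: a list with time \code{t},
#'   free monomer \code{M}, propagating chains \code{P} (named by DP,
#'   starting at 0) and complexes \code{C} (named by chain DP).
#' @export
chain_state <- function(y, network, t = 0, clamp = TRUE) {
  s <- network$params$s; Nmax <- network$Nmax
  nC <- max(0L, Nmax - s)
  if (length(y) != state_dim(network)) {
    stop("state vector length does not match the network layout")
  }
  if (clamp) y[y < 0 & y > -1e-12] <- 0
  P <- y[2:(Nmax + 2)]
  names(P) <- 0:Nmax
  C <- if (nC > 0) setNames(y[(Nmax + 3):(Nmax + 2 + nC)], s:(Nmax - 1L)) else numeric(0)
  structure(list(t = t, M = unname(y[1]), P = P, C = C,
                 s = s, Nmax = Nmax, ic = network$ic),
            class = "chain_state")
}

as_state_vector <- function(state) {
  c(state$M, unname(state$P), unname(state$C))
}

#' Rate equations of the two-stage model (reference implementation)
#'
#' Pure-R evaluation of the concentration time-derivatives; the compiled
#' right-hand side used by [simulate_kinetics()] is tested against it on
#' random states.
#'
#' @param state a [chain_state()] object, or a raw state vector in the
#'   full-ladder layout.
#' @param network a [build_network()] object.
#' @return Named numeric vector of time derivatives, same layout as the
#'   state vector.
#' @export
network_rhs <- function(state, network) {
  if (inherits(state, "chain_state")) state <- as_state_vector(state)
  if (length(state) != state_dim(network)) stop("dimension mismatch")
  p <- network$params
  s <- p$s; Nmax <- network$Nmax
  nC <- max(0L, Nmax - s)
  M <- state[1]
  P <- state[2:(Nmax + 2)]            # P[i+1] = P_i
  C <- if (nC > 0) state[(Nmax + 3):(Nmax + 2 + nC)] else numeric(0)

  dP <- numeric(Nmax + 1)
  dC <- numeric(nC)
  coil_top <- min(s, Nmax)            # coil propagation active for i < coil_top
  sumPcoil <- sum(P[seq_len(coil_top)])
  sumPbind <- if (nC > 0) sum(P[(s + 1):Nmax]) else 0
  sumC <- sum(C)

  dM <- -p$k1 * M * sumPcoil - p$kon * M * sumPbind + p$koff * sumC
  dP[1] <- -p$k1 * M * P[1]
  if (coil_top > 1) {
    i <- 2:coil_top
    dP[i] <- p$k1 * M * (P[i - 1] - P[i])
  }
  if (s <= Nmax) {
    dP[s + 1] <- p$k1 * M * P[s]
    if (nC > 0) {
      dP[s + 1] <- dP[s + 1] - p$kon * M * P[s + 1] + p$koff * C[1]
      if (Nmax > s + 1) {
        i <- (s + 2):Nmax            # P_i for s < i < Nmax
        dP[i] <- p$kr * C[i - s - 1] - p$kon * M * P[i] + p$koff * C[i - s]
      }
      dP[Nmax + 1] <- p$kr * C[nC]
      dC <- p$kon * M * P[(s + 1):Nmax] - (p$koff + p$kr) * C
    }
  } else {
    dP[Nmax + 1] <- p$k1 * M * P[Nmax]
  }
  out <- c(dM, dP, dC)
  names(out) <- names(initial_state_vector(network))
  out
}

#' Conservation residuals of a chain state
#'
#' Two conserved quantities follow from the reaction scheme: the total chain
#' concentration \code{sum(P) + sum(C) = I0} and the monomer-unit balance
#' \code{M + sum(i * P_i) + sum((i+1) * C_i) = M0} (a complex holds its chain
#' plus one bound, unreacted monomer).
#'
#' @param state a [chain_state()] object.
#' @param ic [initial_conditions()]; defaults to those stored in the state.
#' @return Named numeric vector \code{c(chain, mass)} of relative residuals.
#' @export
conservation_residuals <- function(state, ic = state$ic) {
  stopifnot(inherits(state, "chain_state"))
  dp_P <- as.numeric(names(state$P))
  dp_C <- as.numeric(names(state$C))
  chains <- sum(state$P) + sum(state$C)
  mass <- state$M + sum(dp_P * state$P) + sum((dp_C + 1) * state$C)
  c(chain = abs(chains - ic$I0) / ic$I0,
    mass = abs(mass - ic$M0) / ic$M0)
}
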