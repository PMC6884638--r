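#' Chain-length distribution of a chain state
#'
#' Pools propagating chains and helix-monomer complexes at their chain
#' degree of polymerization (the bound monomer in a complex is not part of
#' the chain mass). Unreacted initiator (DP 0) is excluded from the polymer
#' distribution and reported separately.
#'
#' @param state a [chain_state()], or a full-ladder \code{kin_trajectory}
#'   (its terminal state is used).
#' @param drop_empty drop trailing DPs with zero concentration.
#' @return A data frame of class \code{chain_length_distribution} with
#'   columns \code{dp} and \code{conc} (mol/L), and attributes
#'   \code{residual_initiator}, \code{s} and \code{I0}.
#' @export
chain_length_distribution <- function(state, drop_empty = TRUE) {
  if (inherits(state, "kin_trajectory")) state <- terminal_state(state)
  stopifnot(inherits(state, "chain_state"))
  dp <- 1:state$Nmax
  conc <- pmax(unname(state$P[-1]), 0)
  if (length(state$C)) {
    idx <- as.integer(names(state$C))
    conc[idx] <- conc[idx] + pmax(unname(state$C), 0)
  }
  if (drop_empty && any(conc > 0)) {
    keep <- seq_len(max(which(conc > 0)))
    dp <- dp[keep]; conc <- conc[keep]
  } else if (drop_empty) {
    dp <- integer(0); conc <- numeric(0)
  }
  structure(data.frame(dp = dp, conc = conc),
            residual_initiator = max(unname(state$P[1]), 0),
            s = state$s, I0 = state$ic$I0,
            class = c("chain_length_distribution", "data.frame"))
}

#' Molar-mass summary of a chain-length distribution
#'
#' A chain of DP \code{i} has molar mass \code{i * residue_mass + end_mass}.
#' Defaults are the benzyl-glutamate repeat unit (219.24 g/mol) and the
#' n-hexylamine initiator end group (101.19 g/mol).
#'
#' @param cld a [chain_length_distribution()].
#' @param residue_mass repeat-unit molar mass, g/mol.
#' @param end_mass end-group molar mass, g/mol.
#' @param s critical helix length used for the short-chain split; defaults
#'   to the value stored in \code{cld}.
#' @return An object of class \code{mw_summary}: list with \code{DPn},
#'   \code{DPw}, \code{Mn}, \code{Mw} (g/mol), \code{dispersity}
#'   (\code{Mw/Mn}) and \code{short_chain_mass_fraction} (mass fraction of
#'   chains with \code{1 <= DP < s}).
#' @examples
#' cld <- poisson_reference(100, I0 = 0.004)
#' mw_moments(cld)$dispersity  # ~1.0098 on a DP basis
#' @export
mw_moments <- function(cld, residue_mass = 219.24, end_mass = 101.19,
                       s = attr(cld, "s")) {
  stopifnot(inherits(cld, "chain_length_distribution") || is.data.frame(cld))
  if (nrow(cld) == 0 || sum(cld$conc) <= 0) {
    stop("empty chain-length distribution")
  }
  i <- cld$dp; c_i <- cld$conc
  mass_i <- i * residue_mass + end_mass
  DPn <- sum(i * c_i) / sum(c_i)
  DPw <- sum(i^2 * c_i) / sum(i * c_i)
  Mn <- sum(mass_i * c_i) / sum(c_i)
  Mw <- sum(mass_i^2 * c_i) / sum(mass_i * c_i)
  scf <- if (!is.null(s)) sum(i[i < s] * c_i[i < s]) / sum(i * c_i) else NA_real_
  structure(list(DPn = DPn, DPw = DPw, Mn = Mn, Mw = Mw,
                 dispersity = Mw / Mn,
                 short_chain_mass_fraction = scf),
            class = "mw_summary")
}

#' @export
print.mw_summary <- function(x, ...) {
  cat(sprintf("DPn = %.2f, DPw = %.2f; Mn = %.0f, Mw = %.0f g/mol; D = %.4f\n",
              x$DPn, x$DPw, x$Mn, x$Mw, x$dispersity))
  if (is.finite(x$short_chain_mass_fraction)) {
    cat(sprintf("short chains (DP < s): %.3g%% by mass\n",
                100 * x$short_chain_mass_fraction))
  }
  invisible(x)
}

#' Design molecular weight from the feed ratio
#'
#' The target number-average molar mass of a living polymerization at full
#' conversion: \code{ratio * residue_mass + end_mass}, reported in kDa to
#' one decimal.
#'
#' @inheritParams mw_moments
#' @param ratio the feed ratio \code{[M]0/[I]0}.
#' @return design Mn in kDa (one decimal).
#' @examples
#' design_mw(100)  # 22.0
#' @export
design_mw <- function(ratio, residue_mass = 219.24, end_mass = 101.19) {
  if (any(ratio < 0)) stop("'ratio' must be >= 0")
  round((ratio * residue_mass + end_mass) / 1000, 1)
}

#' Poisson reference distribution of ideal living chain growth
#'
#' The chain-length law of a single-stage living polymerization in which all
#' chains start growing at once: Poisson with mean extent \code{nu} (consumed
#' monomer per initiator), scaled to the initiator concentration.
#'
#' @param nu mean extent of reaction per chain (\code{conversion * ratio}).
#' @param I0 initiator concentration used for scaling, mol/L.
#' @param dp_max largest DP carried (default covers the upper tail to
#'   ~12 standard deviations).
#' @return A \code{chain_length_distribution} over \code{1:dp_max}; DP 0
#'   mass is reported via the \code{residual_initiator} attribute.
#' @export
poisson_reference <- function(nu, I0 = 1, dp_max = NULL) {
  stopifnot(nu >= 0, I0 > 0)
  if (is.null(dp_max)) dp_max <- max(10, ceiling(nu + 12 * sqrt(nu + 1)))
  dp <- 1:dp_max
  structure(data.frame(dp = dp, conc = I0 * dpois(dp, nu)),
            residual_initiator = I0 * dpois(0, nu),
            s = NULL, I0 = I0,
            class = c("chain_length_distribution", "data.frame"))
}

#' Synthetic GPC-like trace of a distribution
#'
#' Projects the weight fraction of each chain length onto a \code{log10}
#' molar-mass grid and optionally convolves with a Gaussian band-broadening
#' kernel, mimicking how size-exclusion chromatograms present molecular
#' weight distributions. The area is normalized to one.
#'
#' @inheritParams mw_moments
#' @param broadening_sigma Gaussian broadening width in log10(molar mass)
#'   units (0 disables broadening).
#' @param n_grid number of grid points.
#' @return Data frame with columns \code{log10_M} and \code{signal}
#'   (normalized so that the trapezoidal area is 1).
#' @export
gpc_trace <- function(cld, residue_mass = 219.24, end_mass = 101.19,
                      broadening_sigma = 0.02, n_grid = 600) {
  stopifnot(broadening_sigma >= 0, nrow(cld) > 0)
  mass <- cld$dp * residue_mass + end_mass
  w <- cld$conc * mass
  keep <- w > 0
  if (!any(keep)) stop("empty chain-length distribution")
  lm10 <- log10(mass[keep]); w <- w[keep] / sum(w[keep])
  pad <- max(4 * broadening_sigma, 0.05)
  grid <- seq(min(lm10) - pad, max(lm10) + pad, length.out = n_grid)
  sig <- numeric(n_grid)
  if (broadening_sigma > 0) {
    for (j in seq_along(lm10)) {
      sig <- sig + w[j] * exp(-0.5 * ((grid - lm10[j]) / broadening_sigma)^2)
    }
  } else {
    idx <- findInterval(lm10, grid, all.inside = TRUE)
    for (j in seq_along(lm10)) sig[idx[j]] <- sig[idx[j]] + w[j]
  }
  area <- sum(diff(grid) * (head(sig, -1) + tail(sig, -1)) / 2)
  if (area > 0) sig <- sig / area
  data.frame(log10_M = grid, signal = sig)
}
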