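#' Noise model for synthetic conversion data
#'
#' Additive Gaussian noise on the conversion fraction, emulating the scatter
#' of NMR integral ratios. The default standard deviation of 0.01 matches
#' the replicate scatter typical of kinetic runs followed by in-situ NMR.
#'
#' @param sigma_add standard deviation of the additive noise.
#' @param clip clip noisy conversions into [0, 1].
#' @param seed integer seed.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(sigma_add = 0.01, clip = TRUE, seed = 1) {
  if (sigma_add < 0) stop("'sigma_add' must be >= 0")
  structure(list(sigma_add = sigma_add, clip = isTRUE(clip),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Sampling schedule of a monitored polymerization
#'
#' Either an explicit vector of sampling times, or a rule: sample every
#' \code{by} seconds until the model conversion reaches
#' \code{until_conversion} (never beyond \code{t_max}). The default mimics
#' spectra acquired at 2-minute intervals over a 150-minute run.
#'
#' @param times explicit sampling times, seconds (overrides the rule).
#' @param by sampling interval, seconds.
#' @param until_conversion stop sampling once the (noiseless) model
#'   conversion passes this value; \code{NULL} samples the full span.
#' @param t_max maximum time, seconds.
#' @return An object of class \code{sampling_schedule}.
#' @export
sampling_schedule <- function(times = NULL, by = 120, until_conversion = 0.98,
                              t_max = 9000) {
  if (!is.null(times)) {
    if (length(times) < 5 || any(diff(times) <= 0) || any(times <= 0)) {
      stop("'times' must be >= 5 strictly increasing positive values")
    }
    return(structure(list(times = as.numeric(times)), class = "sampling_schedule"))
  }
  stopifnot(by > 0, t_max >= 5 * by)
  structure(list(by = by, until_conversion = until_conversion, t_max = t_max),
            class = "sampling_schedule")
}

resolve_schedule <- function(schedule, network) {
  if (!is.null(schedule$times)) return(schedule$times)
  t_stop <- schedule$t_max
  if (!is.null(schedule$until_conversion)) {
    t_hit <- tryCatch(time_to_conversion(network, schedule$until_conversion),
                      error = function(e) schedule$t_max)
    # always keep at least 5 points; extend past t_max if the run is slow
    t_stop <- max(5 * schedule$by, min(ceiling(t_hit / schedule$by) * schedule$by,
                                       max(schedule$t_max, t_hit * 1.05)))
  }
  seq(schedule$by, t_stop, by = schedule$by)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate synthetic two-stage kinetic datasets
#'
#' Simulates the two-stage model (exact lumped representation), samples the
#' conversion at the schedule times and adds seeded replicate noise. The
#' result stands in for NMR-monitored conversion curves.
#'
#' @param params [rate_params()].
#' @param ic [initial_conditions()].
#' @param schedule a [sampling_schedule()].
#' @param noise a [noise_model()].
#' @param n_reps number of replicate datasets.
#' @param label free-text condition label attached to each dataset.
#' @param mode observable convention, see [conversion()].
#' @return A list of [kinetic_dataset()] objects (length \code{n_reps}).
#' @examples
#' ds <- generate_dataset(rate_params(0.02, 10, 2, 0.2, 10),
#'                        initial_conditions(0.4, ratio = 100),
#'                        noise = noise_model(sigma_add = 0.01, seed = 7))
#' head(ds[[1]]$times); head(ds[[1]]$conversion)
#' @export
generate_dataset <- function(params, ic, schedule = sampling_schedule(),
                             noise = noise_model(), n_reps = 1,
                             label = "synthetic-DCM",
                             mode = c("ring-intact", "free-monomer")) {
  mode <- match.arg(mode)
  network <- build_network(params, ic)
  times <- resolve_schedule(schedule, network)
  traj <- simulate_kinetics(network, times = times, model = "lumped")
  x <- conversion(traj, mode)
  x_model <- x$conversion[match(times, x$time_s)]
  with_seed(noise$seed, {
    lapply(seq_len(n_reps), function(r) {
      xi <- x_model + rnorm(length(times), 0, noise$sigma_add)
      if (noise$clip) xi <- pmin(pmax(xi, 0), 1)
      kinetic_dataset(times, xi, ic, label = label, replicate_id = r,
                      meta = list(params = params, seed = noise$seed,
                                  sigma_add = noise$sigma_add, mode = mode))
    })
  })
}

#' Generate a factorial panel of synthetic datasets
#'
#' Full factorial over initial monomer concentrations and feed ratios, one
#' dataset per cell, with per-cell seeds derived deterministically from the
#' noise seed. The defaults reproduce the nine-condition design
#' (\code{[M]0} = 0.2/0.3/0.4 M crossed with \code{[M]0/[I]0} = 50/100/150)
#' used for the global fit.
#'
#' @inheritParams generate_dataset
#' @param M0_list initial monomer concentrations, mol/L.
#' @param ratio_list feed ratios.
#' @return A list of [kinetic_dataset()] objects, one per (M0, ratio) cell,
#'   labelled \code{"M0=<x>|ratio=<r>"}.
#' @export
generate_panel <- function(params, M0_list = c(0.2, 0.3, 0.4),
                           ratio_list = c(50, 100, 150),
                           schedule = sampling_schedule(),
                           noise = noise_model(),
                           mode = c("ring-intact", "free-monomer")) {
  mode <- match.arg(mode)
  if (!length(M0_list) || !length(ratio_list)) stop("empty design grids")
  cells <- expand.grid(M0 = M0_list, ratio = ratio_list,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ic <- initial_conditions(M0 = cells$M0[i], ratio = cells$ratio[i])
    cell_noise <- noise
    cell_noise$seed <- noise$seed + i - 1L
    out[[i]] <- generate_dataset(
      params, ic, schedule, cell_noise, n_reps = 1,
      label = sprintf("M0=%g|ratio=%g", cells$M0[i], cells$ratio[i]),
      mode = mode
    )[[1]]
  }
  out
}

#' Generate a single-stage (no-adsorption) control dataset
#'
#' Pure living chain growth with one second-order constant throughout: the
#' behaviour of NCA polymerization in strongly H-bond-disrupting solvents,
#' where no helix-monomer binding assists propagation. Conversion follows
#' the closed form \code{1 - exp(-k1 * I0 * t)}, independent of \code{[M]0}
#' at fixed \code{[I]0}.
#'
#' @inheritParams generate_dataset
#' @param k1 the single propagation rate constant, 1/(M s).
#' @return A [kinetic_dataset()].
#' @export
generate_single_stage_dataset <- function(k1, ic, schedule = sampling_schedule(),
                                          noise = noise_model(),
                                          label = "synthetic-DMF") {
  stopifnot(k1 > 0, inherits(ic, "initial_conditions"))
  times <- if (!is.null(schedule$times)) {
    schedule$times
  } else {
    t_stop <- schedule$t_max
    if (!is.null(schedule$until_conversion)) {
      t_hit <- -log(1 - schedule$until_conversion) / (k1 * ic$I0)
      t_stop <- max(5 * schedule$by,
                    min(ceiling(t_hit / schedule$by) * schedule$by,
                        max(schedule$t_max, t_hit * 1.05)))
    }
    seq(schedule$by, t_stop, by = schedule$by)
  }
  x_model <- 1 - exp(-k1 * ic$I0 * times)
  with_seed(noise$seed, {
    xi <- x_model + rnorm(length(times), 0, noise$sigma_add)
    if (noise$clip) xi <- pmin(pmax(xi, 0), 1)
    kinetic_dataset(times, xi, ic, label = label,
                    meta = list(k1 = k1, seed = noise$seed,
                                sigma_add = noise$sigma_add))
  })
}
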