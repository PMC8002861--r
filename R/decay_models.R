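#' Decay models: mono-exponential, biexponential, excited-state reaction
#'
#' Constructors for the three emission-decay models the simulator supports.
#'
#' `decay_mono(tau_ns)` is the single-lifetime decay `exp(-t/tau)` of a pure
#' species (gel membrane, fluid cytoplasm, lipid-droplet ICT state).
#'
#' `decay_biexp(tau_ns, fractions)` is the amplitude mixture
#' `a1*exp(-t/tau1) + a2*exp(-t/tau2)` seen where two emitting states coexist
#' (ICT + pH-activated emission in acidic organelles).
#'
#' `decay_esr(...)` is a two-state excited-state reaction: a locally excited
#' (LE) state decays with total rate `Gamma_LE + k_transfer` while feeding a
#' relaxed (solvent-relaxed/ICT) state that decays with rate `Gamma_R`. The
#' relaxed-state population is
#' `R(t) = (exp(-Gamma_R t) - exp(-(Gamma_LE + k_transfer) t)) / (Gamma_LE + k_transfer - Gamma_R)`,
#' a rising-then-falling profile whose red-shifted emission places the phasor
#' outside the universal semicircle. The blue (LE) emission decays
#' mono-exponentially with rate `Gamma_LE + k_transfer`.
#'
#' @param tau_ns Lifetime(s) in ns: one value for `decay_mono`, two for
#'   `decay_biexp`.
#' @param fractions Two non-negative amplitude fractions summing to 1.
#' @param rate_LE_per_ns Radiative+non-radiative decay rate of the LE state
#'   (1/ns), excluding transfer.
#' @param rate_transfer_per_ns LE-to-relaxed transfer (solvent relaxation)
#'   rate (1/ns).
#' @param rate_R_per_ns Decay rate of the relaxed state (1/ns).
#' @return An object of class `decay_model`.
#' @name decay_models
NULL

#' @rdname decay_models
#' @export
decay_mono <- function(tau_ns) {
  stopifnot(length(tau_ns) == 1L)
  if (tau_ns <= 0) stop("lifetime must be > 0")
  structure(list(kind = "mono", lifetimes_ns = as.numeric(tau_ns)),
            class = "decay_model")
}

#' @rdname decay_models
#' @export
decay_biexp <- function(tau_ns, fractions = c(0.5, 0.5)) {
  stopifnot(length(tau_ns) == 2L, length(fractions) == 2L)
  if (any(tau_ns <= 0)) stop("lifetimes must be > 0")
  if (any(fractions < 0)) stop("amplitude fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-12) stop("amplitude fractions must sum to 1")
  structure(list(kind = "biexp", lifetimes_ns = as.numeric(tau_ns),
                 amplitude_fractions = as.numeric(fractions)),
            class = "decay_model")
}

#' @rdname decay_models
#' @export
decay_esr <- function(rate_LE_per_ns, rate_transfer_per_ns, rate_R_per_ns) {
  rates <- c(rate_LE_per_ns, rate_transfer_per_ns, rate_R_per_ns)
  if (any(rates <= 0)) stop("all rates must be > 0 for an excited-state reaction")
  structure(list(kind = "excited_state_reaction",
                 rate_LE_per_ns = as.numeric(rate_LE_per_ns),
                 rate_transfer_per_ns = as.numeric(rate_transfer_per_ns),
                 rate_R_per_ns = as.numeric(rate_R_per_ns)),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  switch(x$kind,
    mono = cat(sprintf("decay_model: mono-exponential, tau = %g ns\n", x$lifetimes_ns)),
    biexp = cat(sprintf("decay_model: biexponential, tau = (%g, %g) ns, a = (%g, %g)\n",
                        x$lifetimes_ns[1], x$lifetimes_ns[2],
                        x$amplitude_fractions[1], x$amplitude_fractions[2])),
    cat(sprintf("decay_model: excited-state reaction, Gamma_LE = %g, k_s = %g, Gamma_R = %g (1/ns)\n",
                x$rate_LE_per_ns, x$rate_transfer_per_ns, x$rate_R_per_ns))
  )
  invisible(x)
}

# Exact integrals of exp(-t/tau) over the histogram bins [k*dt, (k+1)*dt).
# Returned un-normalized (units of seconds).
.bin_integrals_exp <- function(tau_s, meta) {
  dt <- meta$time_window_s / meta$n_time_bins
  edges <- (0:meta$n_time_bins) * dt
  e <- exp(-edges / tau_s)
  tau_s * (e[-length(e)] - e[-1])
}

# Exact integrals of t*exp(-gamma*t) over bins (degenerate ESR limit).
.bin_integrals_texp <- function(gamma_per_s, meta) {
  dt <- meta$time_window_s / meta$n_time_bins
  edges <- (0:meta$n_time_bins) * dt
  antider <- -(edges / gamma_per_s + 1 / gamma_per_s^2) * exp(-gamma_per_s * edges)
  antider[-1] - antider[-length(antider)]
}

#' Expected per-bin photon fractions of a decay model
#'
#' Integrates the model's emission profile over each TCSPC bin
#' (`[k*dt, (k+1)*dt)`, delta-function excitation at t = 0, no IRF) and
#' renormalizes so the fractions sum to 1 over the histogram window. Photons
#' emitted after the window are discarded (truncation without wrap-around).
#'
#' For the excited-state-reaction model the emitted profile depends on the
#' spectral band: `emission = "green"` returns the relaxed-state (rising)
#' profile, `emission = "blue"` the mono-exponentially decaying LE profile.
#' The degenerate case `Gamma_R == Gamma_LE + k_transfer` uses the analytic
#' limit `t * exp(-Gamma t)`.
#'
#' @param model A [decay_mono()], [decay_biexp()] or [decay_esr()] model.
#' @param meta An [acquisition_metadata()].
#' @param emission `"green"` or `"blue"`; only consulted for
#'   excited-state-reaction models.
#' @return Numeric vector of length `n_time_bins`, non-negative, summing to 1.
#' @export
#' @examples
#' meta <- acquisition_metadata(n_time_bins = 256)
#' f <- expected_decay(decay_mono(4.0), meta)
#' sum(f)  # 1
expected_decay <- function(model, meta, emission = c("green", "blue")) {
  stopifnot(inherits(model, "decay_model"), inherits(meta, "acquisition_metadata"))
  emission <- match.arg(emission)
  raw <- switch(model$kind,
    mono = .bin_integrals_exp(model$lifetimes_ns * 1e-9, meta),
    biexp = {
      model$amplitude_fractions[1] * .bin_integrals_exp(model$lifetimes_ns[1] * 1e-9, meta) +
      model$amplitude_fractions[2] * .bin_integrals_exp(model$lifetimes_ns[2] * 1e-9, meta)
    },
    excited_state_reaction = {
      gamma_le <- (model$rate_LE_per_ns + model$rate_transfer_per_ns) * 1e9  # 1/s
      gamma_r <- model$rate_R_per_ns * 1e9
      if (emission == "blue") {
        .bin_integrals_exp(1 / gamma_le, meta)
      } else if (abs(gamma_r - gamma_le) < 1e-12 * gamma_le) {
        .bin_integrals_texp(gamma_le, meta)
      } else {
        (.bin_integrals_exp(1 / gamma_r, meta) -
         .bin_integrals_exp(1 / gamma_le, meta)) / (gamma_le - gamma_r)
      }
    }
  )
  # numerical guard: exact bin integrals are >= 0 up to rounding
  raw[raw < 0] <- 0
  raw / sum(raw)
}
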