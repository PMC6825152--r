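# Voltage-gated channel kinetics as data, not code: each gate carries a
# steady-state law and a time-constant law, each a named functional form with
# parameters, so a model configuration is fully serializable to YAML and
# swappable without touching the integrator.

#' Evaluate a gating law at a vector of voltages
#'
#' Supported steady-state forms: `sigmoid` (`1/(1+exp(-(v-vhalf)/k))`; `k < 0`
#' gives inactivation) and `ab` (`alpha/(alpha+beta)`). Supported
#' time-constant forms: `constant`, `scaled_sigmoid`
#' (`base + amp/(1+exp(-(v-vhalf)/k))`), `bi_exp`
#' (`tau_max/(a1*exp((v-vhalf)/k1) + a2*exp(-(v-vhalf)/k2))`) and `ab`
#' (`1/(phi*(alpha+beta))`). Rate sub-forms for `ab` laws: `exp_linear`
#' (`A*(v-vhalf)/(1-exp(-(v-vhalf)/k))`, with the removable singularity
#' filled), `exponential` (`A*exp((v-vhalf)/k)`) and `sigmoid`
#' (`A/(1+exp(-(v-vhalf)/k))`).
#'
#' @param law named list with `form` and its parameters.
#' @param v voltages, mV.
#' @param what `"inf"` or `"tau"`.
#' @return Numeric vector.
#' @export
eval_gate_law <- function(law, v, what = c("inf", "tau")) {
  what <- match.arg(what)
  rate <- function(r) {
    switch(r$form,
      exp_linear = {
        x <- (v - r$vhalf) / r$k
        out <- r$A * r$k * x / (1 - exp(-x))
        out[abs(x) < 1e-7] <- r$A * r$k
        out
      },
      exponential = r$A * exp((v - r$vhalf) / r$k),
      sigmoid = r$A / (1 + exp(-(v - r$vhalf) / r$k)),
      stop("unknown rate form: ", r$form)
    )
  }
  if (identical(law$form, "ab")) {
    a <- rate(law$alpha); b <- rate(law$beta)
    phi <- if (is.null(law$phi)) 1 else law$phi
    return(if (what == "inf") a / (a + b) else 1 / (phi * (a + b)))
  }
  if (what == "inf") {
    switch(law$form,
      sigmoid = 1 / (1 + exp(-(v - law$vhalf) / law$k)),
      stop("unknown steady-state form: ", law$form))
  } else {
    switch(law$form,
      constant = rep(law$tau, length(v)),
      scaled_sigmoid = {
        base <- if (is.null(law$base)) 0 else law$base
        base + law$amp / (1 + exp(-(v - law$vhalf) / law$k))
      },
      bi_exp = law$tau_max /
        (law$a1 * exp((v - law$vhalf) / law$k1) +
         law$a2 * exp(-(v - law$vhalf) / law$k2)),
      stop("unknown time-constant form: ", law$form))
  }
}

#' Construct a channel specification
#'
#' @param name channel label.
#' @param gbar maximal conductance density, S/cm^2 (>= 0).
#' @param reversal reversal potential, mV.
#' @param gates list of gates, each `list(power, inf = <law>, tau = <law>)`.
#' @return List of class `channel_spec`.
#' @export
channel_spec <- function(name, gbar, reversal, gates) {
  if (gbar < 0) stop("gbar must be >= 0")
  vv <- seq(-100, 60, by = 1)
  for (g in gates) {
    tau <- eval_gate_law(g$tau, vv, "tau")
    if (any(!is.finite(tau)) || any(tau <= 0))
      stop("channel ", name, ": time constant not positive on [-100, 60] mV")
  }
  structure(list(name = name, gbar = gbar, reversal = reversal, gates = gates),
            class = "channel_spec")
}

#' Default channel registry
#'
#' Shipped kinetics for the reduced interneuron model:
#' \describe{
#'   \item{na_t}{transient sodium, m^3 h, alpha/beta interneuron kinetics
#'     (temperature factor 5 on h).}
#'   \item{kdr}{delayed-rectifier potassium, n^4, alpha/beta interneuron
#'     kinetics (factor 5).}
#'   \item{km}{slow non-inactivating (M-type) potassium, first order; drives
#'     the regular-spiking phenotype's spike-frequency accommodation.}
#'   \item{kv31}{Kv3.1 fast delayed rectifier, first-order activation,
#'     `minf = 1/(1+exp(-(v-18.7)/9.7))`,
#'     `tau = 4/(1+exp(-(v+46.56)/44.14))` ms (the public Kv3_1 channel
#'     description used by the reference cell-type models).}
#' }
#' Reversals: Na +55 mV, K -90 mV. `gbar` values in the registry are
#' placeholders (0); models set their own densities.
#'
#' @return Named list of `channel_spec`.
#' @export
channel_registry <- function() {
  phi <- 5
  list(
    na_t = channel_spec("na_t", 0, 55, list(
      list(power = 3,
           inf = list(form = "ab",
                      alpha = list(form = "exp_linear", A = 0.1, vhalf = -35, k = 10),
                      beta = list(form = "exponential", A = 4, vhalf = -60, k = -18)),
           # activation is near-instantaneous; the rate factor keeps its
           # time constant well under 0.1 ms so spikes overshoot properly
           tau = list(form = "ab", phi = 5,
                      alpha = list(form = "exp_linear", A = 0.1, vhalf = -35, k = 10),
                      beta = list(form = "exponential", A = 4, vhalf = -60, k = -18))),
      list(power = 1,
           inf = list(form = "ab",
                      alpha = list(form = "exponential", A = 0.07, vhalf = -58, k = -20),
                      beta = list(form = "sigmoid", A = 1, vhalf = -28, k = 10)),
           tau = list(form = "ab", phi = phi,
                      alpha = list(form = "exponential", A = 0.07, vhalf = -58, k = -20),
                      beta = list(form = "sigmoid", A = 1, vhalf = -28, k = 10)))
    )),
    kdr = channel_spec("kdr", 0, -90, list(
      list(power = 4,
           inf = list(form = "ab",
                      alpha = list(form = "exp_linear", A = 0.01, vhalf = -34, k = 10),
                      beta = list(form = "exponential", A = 0.125, vhalf = -44, k = -80)),
           tau = list(form = "ab", phi = phi,
                      alpha = list(form = "exp_linear", A = 0.01, vhalf = -34, k = 10),
                      beta = list(form = "exponential", A = 0.125, vhalf = -44, k = -80)))
    )),
    km = channel_spec("km", 0, -90, list(
      list(power = 1,
           inf = list(form = "sigmoid", vhalf = -35, k = 10),
           tau = list(form = "bi_exp", tau_max = 1000, vhalf = -35,
                      a1 = 3.3, k1 = 20, a2 = 3.3, k2 = 20))
    )),
    kv31 = channel_spec("kv31", 0, -90, list(
      list(power = 1,
           inf = list(form = "sigmoid", vhalf = 18.7, k = 9.7),
           tau = list(form = "scaled_sigmoid", base = 0, amp = 4,
                      vhalf = -46.56, k = 44.14))
    )),
    # hyperpolarization-activated cation conductance; off by default, used
    # to validate the sag measurement
    h = channel_spec("h", 0, -30, list(
      list(power = 1,
           inf = list(form = "sigmoid", vhalf = -80, k = -6),
           tau = list(form = "constant", tau = 50))
    ))
  )
}
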