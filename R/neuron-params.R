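#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for the integrate-and-fire neuron with instantaneous
#' synapses, in either the conductance-based or the current-based variant.
#' In the conductance variant each input multiplicatively pulls the membrane
#' potential toward the corresponding reversal potential
#' (`V <- V + g_X * (V_X - V)`); in the current variant each input adds a
#' fixed amplitude (`V <- V + a_X`). Defaults are the standard operating
#' point of the embedding model: reversal potentials 0 / -80 mV, rest and
#' reset at -70 mV, threshold -55 mV, membrane time constant 20 ms,
#' refractory period 2 ms, and conductance jumps g_E = 0.005, g_I = 0.11.
#'
#' @param model_kind `"conductance"` or `"current"`.
#' @param V_E,V_I Excitatory / inhibitory reversal potentials (mV).
#' @param V_P Resting potential (mV).
#' @param V_R Reset potential (mV).
#' @param V_Theta Spike threshold (mV).
#' @param tau_P Membrane time constant (ms).
#' @param tau_ref Absolute refractory period (ms).
#' @param g_E,g_I Dimensionless conductance jumps (conductance kind).
#' @param a_E,a_I Jump amplitudes in mV (current kind; `a_I` should be <= 0).
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()              # conductance model, default operating point
#' pc <- neuron_params("current", a_E = 0.3125, a_I = -1)
neuron_params <- function(model_kind = c("conductance", "current"),
                          V_E = 0, V_I = -80, V_P = -70, V_R = -70,
                          V_Theta = -55, tau_P = 20, tau_ref = 2,
                          g_E = 0.005, g_I = 0.11,
                          a_E = NULL, a_I = NULL) {
  model_kind <- match.arg(model_kind)
  if (tau_P <= 0) stop_invalid("tau_P must be > 0")
  if (tau_ref < 0) stop_invalid("tau_ref must be >= 0")
  if (model_kind == "conductance") {
    if (!(V_I <= V_R && V_R <= V_Theta && V_Theta < V_E))
      stop_invalid("need V_I <= V_R <= V_Theta < V_E for conductance synapses")
    if (g_E < 0 || g_I < 0) stop_invalid("g_E, g_I must be >= 0")
    if (g_E >= 1 || g_I >= 1) stop_invalid("g_E, g_I must be < 1")
    a_E <- a_E %||% 0; a_I <- a_I %||% 0
  } else {
    if (is.null(a_E) || is.null(a_I))
      stop_invalid("current kind requires a_E and a_I")
    if (a_I > 0) stop_invalid("inhibitory amplitude a_I must be <= 0")
    g_E <- 0; g_I <- 0
    if (!(V_R <= V_Theta)) stop_invalid("need V_R <= V_Theta")
  }
  structure(list(model_kind = model_kind, V_E = V_E, V_I = V_I, V_P = V_P,
                 V_R = V_R, V_Theta = V_Theta, tau_P = tau_P,
                 tau_ref = tau_ref, g_E = g_E, g_I = g_I,
                 a_E = a_E, a_I = a_I),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params: %s>\n", x$model_kind))
  cat(sprintf("  V_P=%g V_R=%g V_Theta=%g V_E=%g V_I=%g mV\n",
              x$V_P, x$V_R, x$V_Theta, x$V_E, x$V_I))
  cat(sprintf("  tau_P=%g ms  tau_ref=%g ms\n", x$tau_P, x$tau_ref))
  if (x$model_kind == "conductance")
    cat(sprintf("  g_E=%g g_I=%g\n", x$g_E, x$g_I))
  else cat(sprintf("  a_E=%g a_I=%g mV\n", x$a_E, x$a_I))
  invisible(x)
}

# Parameter list handed to the compiled engine.
engine_par <- function(params, dt) {
  list(kind = if (params$model_kind == "conductance") 0L else 1L,
       V_P = params$V_P, V_E = params$V_E, V_I = params$V_I,
       V_R = params$V_R, V_Theta = params$V_Theta, tau_P = params$tau_P,
       g_E = params$g_E, g_I = params$g_I,
       a_E = params$a_E, a_I = params$a_I,
       ref_steps = as.integer(round(params$tau_ref / dt)))
}
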