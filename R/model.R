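#' Assemble the laminar local cortical circuit model
#'
#' Builds the five-population laminar circuit from natural-scale parameters.
#' Each intrinsic connection owns one second-order alpha-kernel transform
#' (connection-specific time constant), so the full 13-connection circuit
#' has 26 core state variables; each excitatory connection additionally
#' owns a vesicle-pool state. The extrinsic pulse train enters the
#' granular-layer transform (the dPC->EIN kernel input sum) scaled by `C1`.
#' Membrane potentials are sums of the excitatory minus inhibitory
#' transform outputs converging on each population, and the observed source
#' signal is `u_sPC + u_dPC`.
#'
#' @param params Named numeric vector of natural-scale parameters as
#'   produced by [prior_expectations()] / [to_natural()].
#' @param include_uncertain Which of the six uncertain connections to keep
#'   in the graph; the seven certain connections are always present.
#' @param habituation If `FALSE`, all synaptic efficacies are frozen at 1
#'   (no pools).
#' @return An object of class `nmm_model`.
#' @export
build_lccm <- function(params = prior_expectations(),
                       include_uncertain = uncertain_connections(),
                       habituation = TRUE) {
  params <- unlist(params)
  tab <- lccm_connection_table()
  unknown <- setdiff(include_uncertain, tab$name[tab$uncertain])
  if (length(unknown))
    stop("unknown uncertain connection(s): ", paste(unknown, collapse = ", "))
  tab <- tab[!tab$uncertain | tab$name %in% include_uncertain, ]
  pops <- c("EIN", "sPC", "dPC", "sIIN", "dIIN")
  sig <- sigmoid_params(params[["e0"]], params[["r"]], params[["u0"]])
  J <- nrow(tab)
  hab <- tab$habituating & habituation
  pool_id <- integer(J)
  pool_id[hab] <- seq_len(sum(hab))
  structure(list(
    kind = "LCCM",
    populations = pops,
    connections = data.frame(
      name = tab$name, label = tab$label, source = tab$source,
      target = tab$target, sign = tab$sign,
      C = unname(params[tab$name]),
      tau = unname(params[paste0("tau_", tab$name)]),
      habituating = hab, stringsAsFactors = FALSE),
    transforms = data.frame(
      H = ifelse(tab$sign == "exc", params[["He"]], params[["Hi"]]),
      tau = unname(params[paste0("tau_", tab$name)]),
      input_gain = ifelse(tab$name == "C7", params[["C1"]], 0)),
    drives = data.frame(
      transform = seq_len(J), source = match(tab$source, pops),
      C = unname(params[tab$name]),
      pool = ifelse(hab, pool_id, 0L)),
    outputs = data.frame(
      pop = match(tab$target, pops), transform = seq_len(J),
      w = ifelse(tab$sign == "exc", 1, -1)),
    pools = data.frame(
      name = tab$name[hab], label = tab$label[hab],
      source = match(tab$source, pops)[hab],
      n_depress = unname(params[paste0("nd_", tab$name[hab])]),
      n_recover = unname(params[paste0("nr_", tab$name[hab])]),
      stringsAsFactors = FALSE),
    sigmoid = sig,
    input = input_params(w = params[["w"]], n = 7L, C1 = params[["C1"]],
                         sigmoid = sig),
    obs_populations = c("sPC", "dPC")),
    class = "nmm_model")
}

#' Assemble the Jansen-Rit baseline circuit
#'
#' Classical three-population circuit (EIN, PC, IIN) built on the same
#' kernel/sigmoid machinery. Three second-order transforms (6 core states):
#' the shared excitatory kernel of the pyramidal output (read out by EIN
#' and IIN with weights `C1j` and `C3j`), the excitatory input kernel of
#' the PC (driven by `C2j S(u_EIN)` plus the extrinsic pulse train), and
#' the inhibitory input kernel of the PC (driven by `C4j S(u_IIN)`).
#' Habituation, when enabled, applies to the two excitatory pathways: one
#' pool on the shared pyramidal output synapses and one on the EIN->PC
#' synapse. The observed signal is `u_PC`.
#'
#' @param params Named numeric vector of natural-scale parameters as
#'   produced by `prior_expectations(jrm_priors())`.
#' @param habituation If `FALSE`, efficacies are frozen at 1.
#' @return An object of class `nmm_model`.
#' @export
build_jrm <- function(params = prior_expectations(jrm_priors()),
                      habituation = TRUE) {
  params <- unlist(params)
  pops <- c("EIN", "PC", "IIN")
  sig <- sigmoid_params(params[["e0"]], params[["r"]], params[["u0"]])
  pools <- if (habituation)
    data.frame(name = c("out", "exc"),
               label = c("PC->(EIN,IIN)", "EIN->PC"),
               source = c(2L, 1L),
               n_depress = unname(params[c("nd_out", "nd_exc")]),
               n_recover = unname(params[c("nr_out", "nr_exc")]),
               stringsAsFactors = FALSE)
  else
    data.frame(name = character(), label = character(), source = integer(),
               n_depress = numeric(), n_recover = numeric(),
               stringsAsFactors = FALSE)
  structure(list(
    kind = "JRM",
    populations = pops,
    connections = data.frame(
      name = c("C1j", "C2j", "C3j", "C4j"),
      label = c("PC->EIN", "EIN->PC", "PC->IIN", "IIN->PC"),
      source = c("PC", "EIN", "PC", "IIN"),
      target = c("EIN", "PC", "IIN", "PC"),
      sign = c("exc", "exc", "exc", "inh"),
      C = unname(params[c("C1j", "C2j", "C3j", "C4j")]),
      tau = unname(params[c("tau_out", "tau_exc", "tau_out", "tau_inh")]),
      habituating = habituation & c(TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    transforms = data.frame(
      H = unname(params[c("He", "He", "Hi")]),
      tau = unname(params[c("tau_out", "tau_exc", "tau_inh")]),
      input_gain = c(0, params[["C1"]], 0)),
    drives = data.frame(
      transform = 1:3, source = c(2L, 1L, 3L),
      C = c(1, unname(params[["C2j"]]), unname(params[["C4j"]])),
      pool = if (habituation) c(1L, 2L, 0L) else c(0L, 0L, 0L)),
    outputs = data.frame(
      pop = c(1L, 3L, 2L, 2L), transform = c(1L, 1L, 2L, 3L),
      w = c(unname(params[["C1j"]]), unname(params[["C3j"]]), 1, -1)),
    pools = pools,
    sigmoid = sig,
    input = input_params(w = params[["w"]], n = 7L, C1 = params[["C1"]],
                         sigmoid = sig),
    obs_populations = "PC"),
    class = "nmm_model")
}

#' Number of core (synaptic) state variables of a model
#'
#' Two first-order states per synaptic transform; vesicle-pool states are
#' not counted.
#'
#' @param model An `nmm_model`.
#' @return Integer count.
#' @export
n_core_states <- function(model) {
  stopifnot(inherits(model, "nmm_model"))
  2L * nrow(model$transforms)
}

#' Right-hand side of the full model ODE system
#'
#' Pure-R reference implementation of the model derivative, used for
#' fixed-point checks and as a cross-check of the compiled integrator.
#'
#' @param model An `nmm_model`.
#' @param state Named list with `y` (transform PSPs), `z` (their
#'   derivatives) and `A` (pool occupancies); defaults to the rest state
#'   (all zeros, pools at 1).
#' @param t Time (s) at which the extrinsic input is evaluated.
#' @param train Tone train or numeric onsets for the extrinsic input;
#'   `NULL` means no input.
#' @return List with derivative vectors `dy`, `dz`, `dA` and the current
#'   membrane potentials `u` and rates `S` per population.
#' @export
model_rhs <- function(model, state = NULL, t = 0, train = NULL) {
  stopifnot(inherits(model, "nmm_model"))
  J <- nrow(model$transforms)
  K <- nrow(model$pools)
  if (is.null(state))
    state <- list(y = numeric(J), z = numeric(J), A = rep(1, K))
  P <- length(model$populations)
  u <- numeric(P)
  for (i in seq_len(nrow(model$outputs)))
    u[model$outputs$pop[i]] <- u[model$outputs$pop[i]] +
      model$outputs$w[i] * state$y[model$outputs$transform[i]]
  S <- sigmoid(u, model$sigmoid)
  pt <- if (is.null(train)) 0 else impulse_input(t, train, model$input)
  q <- model$transforms$input_gain * pt
  for (i in seq_len(nrow(model$drives))) {
    w <- if (model$drives$pool[i] > 0) state$A[model$drives$pool[i]] else 1
    q[model$drives$transform[i]] <- q[model$drives$transform[i]] +
      model$drives$C[i] * w * S[model$drives$source[i]]
  }
  dy <- state$z
  dz <- (model$transforms$H / model$transforms$tau) * q -
    2 * state$z / model$transforms$tau - state$y / model$transforms$tau^2
  dA <- if (K > 0)
    pool_rhs_vec(state$A, S[model$pools$source], model$pools$n_depress,
                 model$pools$n_recover, sigmoid_max(model$sigmoid))
  else numeric(0)
  list(dy = dy, dz = dz, dA = dA, u = stats::setNames(u, model$populations),
       S = stats::setNames(S, model$populations))
}

pool_rhs_vec <- function(A, Q, n1, n2, Qmax) {
  dep <- ifelse(Q >= 0, n1 * (Q / Qmax) * A, 0)
  n2 * (1 - A) - dep
}

#' Simulate a neural-mass model
#'
#' Deterministic fixed-step RK4 integration of the full system (synaptic
#' transforms plus vesicle pools) from rest (all core states zero, pools
#' at 1), driven by a tone train.
#'
#' @param model An `nmm_model` from [build_lccm()] or [build_jrm()].
#' @param train A [make_tone_train()] object or numeric vector of onsets;
#'   `NULL` or an empty vector means no stimulation.
#' @param t_span Length-2 numeric, start and end time (s).
#' @param dt Integration step (s), at most 1 ms.
#' @return An object of class `nmm_simulation`: `t` (times), `U` (membrane
#'   potentials, one column per population), `A` (pool occupancies), `Y`
#'   (transform PSPs), plus the model and step used. Errors if the state
#'   blows up, naming the first bad time.
#' @export
simulate_model <- function(model, train = make_tone_train(5),
                           t_span = c(-0.1, 2.5), dt = 1e-3) {
  stopifnot(inherits(model, "nmm_model"), length(t_span) == 2,
            t_span[2] > t_span[1])
  if (dt > 1e-3 + 1e-12) stop("dt must be at most 1 ms")
  onsets <- if (is.null(train)) numeric(0)
  else if (inherits(train, "tone_train")) train$onsets
  else as.numeric(train)
  res <- simulate_cpp(
    H = model$transforms$H, tau = model$transforms$tau,
    gain = model$transforms$input_gain,
    d_tr = model$drives$transform - 1L, d_src = model$drives$source - 1L,
    d_C = model$drives$C, d_pool = as.integer(model$drives$pool) - 1L,
    o_pop = model$outputs$pop - 1L, o_tr = model$outputs$transform - 1L,
    o_w = model$outputs$w,
    p_src = model$pools$source - 1L, n1 = model$pools$n_depress,
    n2 = model$pools$n_recover,
    e0 = model$sigmoid$e0, r = model$sigmoid$r, u0 = model$sigmoid$u0,
    Qmax = sigmoid_max(model$sigmoid),
    in_w = model$input$w, in_n = model$input$n, P0 = model$input$P0,
    onsets = onsets, n_pop = length(model$populations),
    t0 = t_span[1], t1 = t_span[2], dt = dt)
  colnames(res$U) <- model$populations
  if (ncol(res$A) > 0) colnames(res$A) <- model$pools$name
  structure(list(t = res$t, U = res$U, A = res$A, Y = res$Y,
                 model = model, dt = dt, onsets = onsets),
            class = "nmm_simulation")
}

#' Observe the source waveform of a simulation
#'
#' The source signal is the sum of the pyramidal membrane potentials
#' (`u_sPC + u_dPC` for the laminar model, `u_PC` for Jansen-Rit),
#' decimated from the integration rate to the requested sampling rate, and
#' optionally normalized to its maximum absolute amplitude.
#'
#' @param sim An `nmm_simulation`.
#' @param fs Output sampling rate (Hz); must divide the integration rate.
#'   125 Hz is the rate expected by the inversion.
#' @param normalize If `TRUE`, divide by `max(abs(y))` (no-op on an
#'   all-zero waveform).
#' @return An object of class `source_waveform`: `t`, `y`, `fs`,
#'   `normalized`.
#' @export
observe <- function(sim, fs = 125, normalize = FALSE) {
  stopifnot(inherits(sim, "nmm_simulation"))
  step <- 1 / (fs * sim$dt)
  if (abs(step - round(step)) > 1e-8)
    stop("fs must divide the integration rate 1/dt")
  step <- as.integer(round(step))
  idx <- seq(1L, length(sim$t), by = step)
  y <- rowSums(sim$U[idx, sim$model$obs_populations, drop = FALSE])
  if (normalize) {
    m <- max(abs(y))
    if (m > 0) y <- y / m
  }
  structure(list(t = sim$t[idx], y = y, fs = fs, normalized = normalize),
            class = "source_waveform")
}

#' Per-tone response peaks of a waveform
#'
#' Maximum absolute amplitude in a window following each tone onset.
#'
#' @param wf A `source_waveform` (or list with `t`, `y`).
#' @param onsets Numeric tone onsets (s) or a [make_tone_train()] object.
#' @param window Window length after each onset (s).
#' @return Numeric vector of peak amplitudes, one per onset.
#' @export
tone_peaks <- function(wf, onsets, window = 0.45) {
  if (inherits(onsets, "tone_train")) onsets <- onsets$onsets
  vapply(onsets, function(on) {
    idx <- wf$t > on & wf$t <= on + window
    if (!any(idx)) stop("no samples in window after onset ", on)
    max(abs(wf$y[idx]))
  }, numeric(1))
}

#' @export
print.nmm_model <- function(x, ...) {
  cat(sprintf("<nmm_model: %s, %d populations, %d connections, %d core states, %d pools>\n",
              x$kind, length(x$populations), nrow(x$connections),
              n_core_states(x), nrow(x$pools)))
  invisible(x)
}

#' @export
print.nmm_simulation <- function(x, ...) {
  cat(sprintf("<nmm_simulation: %s, t in [%.3f, %.3f] s, dt = %g s>\n",
              x$model$kind, min(x$t), max(x$t), x$dt))
  invisible(x)
}

#' @export
print.source_waveform <- function(x, ...) {
  cat(sprintf("<source_waveform: %d samples at %g Hz%s>\n",
              length(x$y), x$fs, if (x$normalized) ", normalized" else ""))
  invisible(x)
}
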