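#' Intrinsic connection table of the laminar circuit
#'
#' The 13 intrinsic connections of the five-population laminar circuit
#' (LCCM): sources/targets among EIN (layer 4 excitatory interneurons),
#' sPC/dPC (superficial and deep pyramidal cells) and sIIN/dIIN (superficial
#' and deep inhibitory interneurons). Seven "certain" connections (the
#' serial pathway EIN->sPC->dPC, the backward dPC->EIN link, and the
#' intra-laminar pyramidal/interneuron loops) have nonzero prior strength;
#' the six "uncertain" cross-laminar connections have zero prior expectation
#' under a shrinkage prior. All excitatory connections habituate.
#'
#' @return A data frame with one row per connection: `name`, `label`
#'   ("SRC->TGT"), `source`, `target`, `sign`, `strength` (prior
#'   expectation), `uncertain`, `habituating`.
#' @export
lccm_connection_table <- function() {
  tab <- data.frame(
    name = c("C2", "C3", "C4", "C5", "C6", "C7", "C8", "C9", "C10",
             "C11", "C12", "C13", "C14"),
    source = c("EIN", "sPC", "sIIN", "sPC", "dPC", "dPC", "EIN", "dPC",
               "dIIN", "sIIN", "dPC", "dIIN", "sPC"),
    target = c("sPC", "sIIN", "sPC", "dPC", "sPC", "EIN", "dPC", "dIIN",
               "dPC", "dPC", "sIIN", "sPC", "dIIN"),
    sign = c("exc", "exc", "inh", "exc", "exc", "exc", "exc", "exc", "inh",
             "inh", "exc", "inh", "exc"),
    strength = c(108, 33.75, 33.75, 135, 0, 135, 0, 33.75, 33.75,
                 0, 0, 0, 0),
    uncertain = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                  FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  tab$label <- paste0(tab$source, "->", tab$target)
  tab$habituating <- tab$sign == "exc"
  tab
}

#' Uncertain connection names
#'
#' @return Character vector of the six cross-laminar connections carrying a
#'   shrinkage (squared) prior.
#' @export
uncertain_connections <- function() {
  tab <- lccm_connection_table()
  tab$name[tab$uncertain]
}

prior_row <- function(name, class, u, var) {
  data.frame(name = name, class = class, u = u, var = var,
             stringsAsFactors = FALSE)
}

#' Prior specification for the laminar circuit model
#'
#' Gaussian priors on re-parameterized (latent) parameters. Three latent
#' classes are used:
#' \describe{
#'   \item{`exp`}{`phi = u exp(theta)`, `theta ~ N(0, var)`; positivity is
#'     guaranteed and `u` is the prior expectation. `var = 1/2` is an
#'     uninformative prior, `var = 1/16` an informative one.}
#'   \item{`sq`}{`phi = theta^2`, `theta ~ N(0, 1e4)`; a shrinkage prior
#'     that keeps a connection at zero unless the data demand otherwise.}
#'   \item{`const`}{the parameter is fixed at its expectation and excluded
#'     from estimation.}
#' }
#' Certain connection strengths, all dendritic time constants (10 ms
#' excitatory, 20 ms inhibitory) and all per-connection depression/recovery
#' rates (20 and 2 1/s) are uninformative `exp`; the input time constant
#' `w` and input strength `C1` are informative `exp`; the six uncertain
#' connections are `sq`; synaptic gains `He`, `Hi` and the sigmoid
#' parameters are constants. A free observation gain `gain` (expectation 1,
#' uninformative) absorbs residual amplitude scaling of the normalized
#' waveform.
#'
#' @return A data frame with columns `name`, `class`, `u` (natural-scale
#'   expectation), `var` (latent prior variance).
#' @export
lccm_priors <- function() {
  tab <- lccm_connection_table()
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    rows[[length(rows) + 1L]] <- if (tab$uncertain[i])
      prior_row(tab$name[i], "sq", 0, 1e4)
    else
      prior_row(tab$name[i], "exp", tab$strength[i], 1 / 2)
  }
  for (i in seq_len(nrow(tab)))
    rows[[length(rows) + 1L]] <- prior_row(
      paste0("tau_", tab$name[i]), "exp",
      if (tab$sign[i] == "exc") 10e-3 else 20e-3, 1 / 2)
  for (nm in tab$name[tab$habituating]) {
    rows[[length(rows) + 1L]] <- prior_row(paste0("nd_", nm), "exp", 20, 1 / 2)
    rows[[length(rows) + 1L]] <- prior_row(paste0("nr_", nm), "exp", 2, 1 / 2)
  }
  rows[[length(rows) + 1L]] <- prior_row("w", "exp", 0.005, 1 / 16)
  rows[[length(rows) + 1L]] <- prior_row("C1", "exp", 50, 1 / 16)
  rows[[length(rows) + 1L]] <- prior_row("He", "const", 3.25e-3, 0)
  rows[[length(rows) + 1L]] <- prior_row("Hi", "const", 22e-3, 0)
  rows[[length(rows) + 1L]] <- prior_row("e0", "const", 2.5, 0)
  rows[[length(rows) + 1L]] <- prior_row("r", "const", 560, 0)
  rows[[length(rows) + 1L]] <- prior_row("u0", "const", 6e-3, 0)
  rows[[length(rows) + 1L]] <- prior_row("gain", "exp", 1, 1 / 2)
  do.call(rbind, rows)
}

#' Prior specification for the Jansen-Rit baseline
#'
#' Classical three-population circuit (EIN, PC, IIN) with the standard
#' connectivity constant `C = 135` and ratios 1, 0.8, 0.25, 0.25 for the
#' four intrinsic connections, the same synaptic gains and sigmoid as the
#' laminar model, per-transform dendritic time constants, habituation on
#' the two excitatory pathways (the shared pyramidal output synapses and
#' the EIN->PC synapse), and the same input and gain priors as
#' [lccm_priors()].
#'
#' @return A data frame in the same format as [lccm_priors()].
#' @export
jrm_priors <- function() {
  rbind(
    prior_row("C1j", "exp", 135, 1 / 2),
    prior_row("C2j", "exp", 108, 1 / 2),
    prior_row("C3j", "exp", 33.75, 1 / 2),
    prior_row("C4j", "exp", 33.75, 1 / 2),
    prior_row("tau_out", "exp", 10e-3, 1 / 2),
    prior_row("tau_exc", "exp", 10e-3, 1 / 2),
    prior_row("tau_inh", "exp", 20e-3, 1 / 2),
    prior_row("nd_out", "exp", 20, 1 / 2),
    prior_row("nr_out", "exp", 2, 1 / 2),
    prior_row("nd_exc", "exp", 20, 1 / 2),
    prior_row("nr_exc", "exp", 2, 1 / 2),
    prior_row("w", "exp", 0.005, 1 / 16),
    prior_row("C1", "exp", 50, 1 / 16),
    prior_row("He", "const", 3.25e-3, 0),
    prior_row("Hi", "const", 22e-3, 0),
    prior_row("e0", "const", 2.5, 0),
    prior_row("r", "const", 560, 0),
    prior_row("u0", "const", 6e-3, 0),
    prior_row("gain", "exp", 1, 1 / 2))
}

#' Active (estimated) parameters of a prior table
#'
#' @param priors A prior table ([lccm_priors()] or [jrm_priors()]).
#' @return Logical vector marking non-constant rows.
#' @export
active_priors <- function(priors) priors$class != "const"

#' Map latent parameters to natural scale
#'
#' Applies the per-parameter re-parameterization: `u exp(theta)` for
#' `exp`-class rows, `theta^2` for `sq`-class rows; constants pass through
#' at their expectation. At `theta = 0` the natural value equals the prior
#' expectation (`exp`) or zero (`sq`).
#'
#' @param theta Numeric vector of latent parameters over the active rows of
#'   `priors`, in table order (names, if present, are checked).
#' @param priors A prior table.
#' @return Named numeric vector of natural-scale parameters for all rows.
#' @export
to_natural <- function(theta, priors) {
  act <- active_priors(priors)
  stopifnot(length(theta) == sum(act))
  if (!is.null(names(theta)) && any(nzchar(names(theta))))
    stopifnot(identical(names(theta), priors$name[act]))
  phi <- numeric(nrow(priors))
  names(phi) <- priors$name
  phi[!act] <- priors$u[!act]
  th_full <- numeric(nrow(priors))
  th_full[act] <- theta
  is_exp <- priors$class == "exp"
  is_sq <- priors$class == "sq"
  phi[is_exp] <- priors$u[is_exp] * exp(th_full[is_exp])
  phi[is_sq] <- th_full[is_sq]^2
  phi
}

#' Natural-scale prior expectations
#'
#' Convenience wrapper: [to_natural()] at `theta = 0`.
#'
#' @param priors A prior table; defaults to [lccm_priors()].
#' @return Named numeric vector of prior-expected natural parameters.
#' @export
prior_expectations <- function(priors = lccm_priors()) {
  to_natural(rep(0, sum(active_priors(priors))), priors)
}
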