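#' Configuration for the selective particle attention filter
#'
#' Bundles the hyper-parameters of the particle-filter attention mechanism:
#' the channel count the filter runs over, the ensemble size, the strengths
#' of the bottom-up (movement) and top-down (observation) pressures, the
#' per-particle refresh probability, and the scheduling constants that the
#' experiment loop uses to decide when to update attention and how long a
#' return window to score particles against.
#'
#' @param K Number of feature channels (positive integer).
#' @param N Number of particles (positive integer; default 250).
#' @param tau_bu Bottom-up strength: larger values push refreshed particles
#'   harder toward the currently most active channels (nonnegative).
#' @param tau_td Top-down strength: larger values penalise particles whose
#'   induced attention predicts the observed return poorly (nonnegative).
#' @param phi Probability that a given particle is refreshed during the
#'   movement step, in `[0, 1]`.
#' @param c_max Attention-update period in environment steps (positive
#'   integer). The filter itself is purely functional; the experiment loop
#'   calls [update_attention()] every `c_max` steps.
#' @param t_max Maximum return-window length in steps (positive integer).
#' @param p_init Initial per-entry probability that a particle marks a
#'   channel useful (default 0.5, an uninformative prior).
#' @param seed Integer seed controlling ensemble initialisation and all
#'   subsequent stochastic filter operations run under it.
#' @param redraw_empty If `TRUE`, an all-zero particle is redrawn during
#'   initialisation and movement instead of being interpreted as uniform
#'   attention.
#'
#' @return An object of class `spa_config` (a named list).
#' @seealso [spa_config_mc()], [spa_config_oc()] for the task presets.
#' @export
#' @examples
#' cfg <- spa_config(K = 32)
#' cfg$N
spa_config <- function(K, N = 250L, tau_bu = 10, tau_td = 10, phi = 0.1,
                       c_max = 1L, t_max = 1L, p_init = 0.5, seed = 1L,
                       redraw_empty = FALSE) {
  check_count(K, "K")
  check_count(N, "N")
  check_nonneg(tau_bu, "tau_bu")
  check_nonneg(tau_td, "tau_td")
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1) {
    stop("`phi` must be a single number in [0, 1].", call. = FALSE)
  }
  check_count(c_max, "c_max")
  check_count(t_max, "t_max")
  if (!is.numeric(p_init) || p_init < 0 || p_init > 1) {
    stop("`p_init` must be a probability.", call. = FALSE)
  }
  structure(
    list(
      K = as.integer(K), N = as.integer(N),
      tau_bu = as.numeric(tau_bu), tau_td = as.numeric(tau_td),
      phi = as.numeric(phi),
      c_max = as.integer(c_max), t_max = as.integer(t_max),
      p_init = as.numeric(p_init), seed = as.integer(seed),
      redraw_empty = isTRUE(redraw_empty)
    ),
    class = "spa_config"
  )
}

#' @describeIn spa_config Preset for the multiple-choice task
#'   (`tau_bu = 10`, `c_max = 1`, `t_max = 1`).
#' @param ... Overrides passed on to [spa_config()].
#' @export
spa_config_mc <- function(K, ...) {
  args <- utils::modifyList(
    list(K = K, tau_bu = 10, tau_td = 10, c_max = 1L, t_max = 1L),
    list(...)
  )
  do.call(spa_config, args)
}

#' @describeIn spa_config Preset for the object-collection game
#'   (`tau_bu = 1`, `c_max = 1000`, `t_max = 10`).
#' @export
spa_config_oc <- function(K, ...) {
  args <- utils::modifyList(
    list(K = K, tau_bu = 1, tau_td = 10, c_max = 1000L, t_max = 10L),
    list(...)
  )
  do.call(spa_config, args)
}

#' @export
print.spa_config <- function(x, ...) {
  cat("<spa_config>\n")
  cat(sprintf("  K = %d channels, N = %d particles\n", x$K, x$N))
  cat(sprintf("  tau_bu = %g, tau_td = %g, phi = %g\n", x$tau_bu, x$tau_td, x$phi))
  cat(sprintf("  c_max = %d, t_max = %d, p_init = %g, seed = %d\n",
              x$c_max, x$t_max, x$p_init, x$seed))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer.", name), call. = FALSE)
  }
  invisible(TRUE)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single nonnegative number.", name), call. = FALSE)
  }
  invisible(TRUE)
}
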