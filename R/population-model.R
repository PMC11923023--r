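#' Model configuration: both strains plus shared parameters
#'
#' @param inducer,suppressor [strain_params()] for each strain at the
#'   active temperature.
#' @param shared [shared_params()] (carrying capacity `C`, benefit `b`).
#' @return A `model_config` object.
#' @export
model_config <- function(inducer, suppressor, shared = shared_params()) {
  stopifnot(inherits(inducer, "strain_params"),
            inherits(suppressor, "strain_params"),
            inherits(shared, "shared_params"))
  structure(list(inducer = inducer, suppressor = suppressor, shared = shared),
            class = "model_config")
}

#' Four-compartment model state
#'
#' Densities (individuals/plant) of inducer juveniles (`NI1`), inducer
#' adults (`NI2`), suppressor juveniles (`NS1`) and suppressor adults
#' (`NS2`).
#'
#' @param NI1,NI2,NS1,NS2 Non-negative densities.
#' @return A named numeric vector in the order (NI1, NI2, NS1, NS2).
#' @export
model_state <- function(NI1 = 0, NI2 = 0, NS1 = 0, NS2 = 0) {
  y <- c(NI1 = NI1, NI2 = NI2, NS1 = NS1, NS2 = NS2)
  if (any(!is.finite(y)) || any(y < 0))
    stop("state densities must be finite and non-negative")
  y
}

#' Density-dependent per-adult reproduction rate
#'
#' Juvenile production per adult falls linearly with the total density of
#' both strains and both stages, clamped at zero once the carrying capacity
#' is reached: `r_max * max(0, 1 - N_total / C)`.
#'
#' @param state Model state vector (see [model_state()]).
#' @param r_max Maximum net reproduction rate (offspring/adult/day).
#' @param C Carrying capacity (> 0).
#' @return Realised reproduction rate; `r_max` on an empty plant, 0 at or
#'   above capacity, never negative.
#' @export
reproduction_rate <- function(state, r_max, C) {
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  if (any(state < 0)) stop("densities must be >= 0")
  r_max * max(0, 1 - sum(state) / C)
}

#' Right-hand side of the two-phenotype competition model
#'
#' The stage-structured dynamics of inducer (I) and suppressor (S) strains
#' on a shared plant:
#' \deqn{dNI_1/dt = (R_I b) NI_2 - v_I NI_1}
#' \deqn{dNI_2/dt = e_I NI_1 - \mu_I NI_2}
#' \deqn{dNS_1/dt = R_S NS_2 - v_S NS_1}
#' \deqn{dNS_2/dt = e_S NS_1 - \mu_S NS_2}
#' with \eqn{R_I, R_S} from [reproduction_rate()] (both strains share the
#' same capacity `C`). The benefit multiplier `b` boosts inducer
#' reproduction only; the strains do not interbreed. The signature follows
#' the \pkg{deSolve} convention so the function can be passed directly to
#' [deSolve::ode()].
#'
#' @param t Time (days); unused (the system is autonomous within one
#'   temperature segment) but part of the solver interface.
#' @param state Model state vector.
#' @param cfg A [model_config()].
#' @return A list whose first element is the derivative vector.
#' @export
mite_rhs <- function(t, state, cfg) {
  if (any(!is.finite(state)))
    stop("non-finite state passed to the model right-hand side")
  I <- cfg$inducer; S <- cfg$suppressor
  RI <- reproduction_rate(state, I$r, cfg$shared$C)
  RS <- reproduction_rate(state, S$r, cfg$shared$C)
  list(c(
    RI * cfg$shared$b * state[2] - I$v * state[1],
    I$e * state[1] - I$mu * state[2],
    RS * state[4] - S$v * state[3],
    S$e * state[3] - S$mu * state[4]
  ))
}

#' Single-strain equilibrium total density
#'
#' With one strain alone and no benefit (`b = 1`), the positive fixed point
#' of the stage-structured system has total density
#' `N* = C * (1 - v*mu / (r*e))`, with juveniles and adults split as
#' `N1/N2 = mu/e`. Strains with `r*e <= mu*v` are inviable and return 0.
#'
#' @param p A [strain_params()] object.
#' @param C Carrying capacity.
#' @return Equilibrium total density, with attribute `viable` (logical) and
#'   attribute `stage_split` (the juvenile:adult ratio `mu/e`).
#' @export
single_strain_equilibrium <- function(p, C) {
  stopifnot(inherits(p, "strain_params"))
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  viable <- p$r * p$e > p$mu * p$v
  n <- if (viable) C * (1 - (p$v * p$mu) / (p$r * p$e)) else 0
  structure(n, viable = viable, stage_split = p$mu / p$e)
}
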