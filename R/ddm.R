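# Wiener first-passage-time density and sampler.

#' Wiener first-passage-time density
#'
#' Density (1/seconds) of absorption at a boundary of a Wiener diffusion
#' with drift `v`, boundary separation `a` and relative starting point `z`
#' at decision time `t`.  The lower-boundary density is evaluated from the
#' series expansion, switching adaptively between the large-time (sine
#' series) and small-time representations so the truncation error stays
#' below `eps`; the upper boundary uses the reflection
#' `(v, z) -> (-v, 1 - z)`.
#'
#' @param t decision time(s) in seconds, strictly positive.
#' @param v drift rate (signed).
#' @param a boundary separation (> 0).
#' @param z relative starting point in (0, 1).
#' @param boundary which boundary is absorbed.
#' @param eps truncation error bound.
#' @return densities, 0 where the value underflows.
#' @export
#' @examples
#' dwfpt(0.5, v = 1, a = 2, boundary = "upper")
dwfpt <- function(t, v, a, z = 0.5, boundary = c("lower", "upper"),
                  eps = 1e-10) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be positive and finite", call. = FALSE)
  if (!is.finite(v) || !is.finite(a) || a <= 0 || z <= 0 || z >= 1)
    stop("invalid diffusion parameters", call. = FALSE)
  if (boundary == "upper") {
    v <- -v
    z <- 1 - z
  }
  wfpt_pdf_cpp(t, v, a, z, eps)
}

# map task response labels onto the fixed boundary frame
response_boundary <- function(choice) {
  up <- c("upper", "left", "match")
  lo <- c("lower", "right", "nonmatch")
  if (!all(choice %in% c(up, lo)))
    stop("unknown choice label(s): ",
         paste(setdiff(choice, c(up, lo)), collapse = ", "), call. = FALSE)
  ifelse(choice %in% up, "upper", "lower")
}

#' Likelihood of an observed response and reaction time
#'
#' Evaluates the first-passage density at `rt - tau` for the boundary the
#' response maps to (upper = left response in the discriminative choice
#' task, upper = match response in the match recognition task).  Reaction
#' times at or below the non-decision time return a floor likelihood of
#' 1e-10 so the fitting surface stays finite.
#'
#' @param rt observed reaction time in seconds.
#' @param choice `"upper"`/`"lower"`, or a task response label
#'   (`"left"`/`"right"`, `"match"`/`"nonmatch"`).
#' @inheritParams dwfpt
#' @param tau non-decision time in seconds.
#' @export
response_likelihood <- function(rt, choice, v, a, tau, z = 0.5) {
  b <- response_boundary(choice)
  out <- numeric(length(rt))
  td <- rt - tau
  low <- td <= 0
  out[low] <- 1e-10
  for (bb in c("lower", "upper")) {
    i <- !low & b == bb
    if (any(i)) out[i] <- dwfpt(td[i], v, a, z, boundary = bb)
  }
  out
}

#' Sample first-passage times and boundaries
#'
#' Euler-Maruyama simulation of `dX = v dt + dW` from `X0 = z * a` with
#' absorbing boundaries 0 and `a`, including a Brownian-bridge correction
#' for crossings between grid points.  Returned times include the
#' non-decision offset `tau`.
#'
#' @param n number of draws.
#' @inheritParams response_likelihood
#' @param dt Euler step in seconds.
#' @param seed integer seed.
#' @return data frame with `rt` (seconds) and `boundary`
#'   (`"lower"`/`"upper"`).
#' @export
sample_first_passage <- function(n, v, a, tau, z = 0.5, dt = 1e-4, seed = 1L) {
  stopifnot(a > 0, tau >= 0, z > 0, z < 1, dt > 0)
  out <- fpt_sample_cpp(n, v, a, z, dt, seed)
  data.frame(rt = out$rt + tau,
             boundary = ifelse(out$boundary == 1L, "upper", "lower"))
}
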