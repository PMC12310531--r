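#' Perturbation protocols (inhibitor schedules)
#'
#' A protocol defines `iota(t)`, the fraction of uninhibited catalytic CDK
#' activity over time, emulating treatment of an analogue-sensitive kinase
#' with an ATP-analogue inhibitor.  `protocol_free_run()` is the unperturbed
#' cell (`iota = 1`).  `protocol_block_release()` holds cells in G2 at a low
#' residual activity and then releases them; the release is not a hard step
#' but an exponential washout with time constant `tau_washout`, emulating
#' inhibitor leaving the cell after the medium is exchanged.
#' `protocol_acute_inhibition()` steps the activity down at `t_inhibit`
#' (optionally back up at `t_release`), emulating acute addition of a
#' saturating inhibitor dose during mitosis.
#'
#' @param t_release release time (min).
#' @param iota_block residual activity fraction during the block.
#' @param tau_washout washout time constant at release (min).
#' @param t_inhibit acute inhibition time (min).
#' @param iota_after residual activity after acute inhibition.
#' @return a list of class `"cdk_protocol"`.
#' @examples
#' pr <- protocol_block_release(t_release = 120)
#' protocol_iota(pr, c(0, 119, 121, 140))
#' @export
protocol_free_run <- function() {
  structure(list(type = "free_run"), class = "cdk_protocol")
}

#' @rdname protocol_free_run
#' @export
protocol_block_release <- function(t_release, iota_block = 0.02,
                                   tau_washout = 1.5) {
  stop_if_not_scalar(t_release, "t_release", lower = 0)
  stop_if_not_scalar(iota_block, "iota_block", lower = 0, upper = 1)
  stop_if_not_scalar(tau_washout, "tau_washout", lower = 1e-6)
  structure(list(type = "block_release", t_release = t_release,
                 iota_block = iota_block, tau_washout = tau_washout),
            class = "cdk_protocol")
}

#' @rdname protocol_free_run
#' @export
protocol_acute_inhibition <- function(t_inhibit, iota_after = 0,
                                      t_release = Inf) {
  stop_if_not_scalar(t_inhibit, "t_inhibit", lower = 0)
  stop_if_not_scalar(iota_after, "iota_after", lower = 0, upper = 1)
  structure(list(type = "acute_inhibition", t_inhibit = t_inhibit,
                 iota_after = iota_after, t_release = t_release),
            class = "cdk_protocol")
}

#' Evaluate a protocol's activity schedule
#'
#' @param protocol a `"cdk_protocol"` object.
#' @param t numeric vector of times (min).
#' @return numeric vector of `iota(t)` values in `[0, 1]`.
#' @export
protocol_iota <- function(protocol, t) {
  stopifnot(inherits(protocol, "cdk_protocol"))
  switch(protocol$type,
    free_run = rep(1, length(t)),
    block_release = {
      ib <- protocol$iota_block
      out <- rep(ib, length(t))
      past <- t >= protocol$t_release
      out[past] <- 1 - (1 - ib) *
        exp(-(t[past] - protocol$t_release) / protocol$tau_washout)
      out
    },
    acute_inhibition = {
      out <- rep(1, length(t))
      out[t >= protocol$t_inhibit & t < protocol$t_release] <-
        protocol$iota_after
      out
    },
    stop("unknown protocol type: ", protocol$type))
}

#' @export
print.cdk_protocol <- function(x, ...) {
  desc <- switch(x$type,
    free_run = "free run (iota = 1 throughout)",
    block_release = sprintf(
      "G2 block (iota = %g) released at t = %g min (washout tau = %g min)",
      x$iota_block, x$t_release, x$tau_washout),
    acute_inhibition = sprintf(
      "acute inhibition to iota = %g at t = %g min%s", x$iota_after,
      x$t_inhibit,
      if (is.finite(x$t_release))
        sprintf(", released at t = %g min", x$t_release) else ""))
  cat("CDK activity protocol:", desc, "\n")
  invisible(x)
}
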