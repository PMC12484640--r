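# FRAP normalization and single-exponential recovery fitting.

#' Normalize a FRAP trace to percent recovery
#'
#' Background-subtracts the trace, then scales it as
#' `100 * (I - Imin) / (I0 - Imin)`, where `I0` is the mean
#' background-subtracted intensity over all pre-bleach frames and `Imin` is
#' the background-subtracted intensity at the bleach frame (0 s after
#' bleaching). By construction the bleach frame maps to 0\% and a frame
#' recovering to the pre-bleach level maps to 100\%.
#'
#' @param trace data frame with columns `time_s`, `intensity`,
#'   `background` (e.g. a [make_frap_trace()] result).
#' @param bleach_index 1-based index of the first post-bleach frame;
#'   defaults to the trace's `bleach_index` attribute. Must be >= 2 so at
#'   least one pre-bleach frame defines `I0`.
#' @return Data frame with columns `time_s` and `recovery_pct`, with
#'   attributes `bleach_index`, `I0` and `Imin` (background-subtracted).
#' @export
normalize_frap <- function(trace, bleach_index = attr(trace, "bleach_index")) {
  if (is.null(bleach_index)) stopf("'bleach_index' is required")
  req <- c("time_s", "intensity", "background")
  if (!all(req %in% names(trace))) {
    stopf("trace needs columns: %s", paste(req, collapse = ", "))
  }
  n <- nrow(trace)
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n) {
    stopf("'bleach_index' must be in 2..%d (need a pre-bleach baseline)", n)
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stopf("'time_s' must be strictly increasing")
  }
  corr <- trace$intensity - trace$background
  I0 <- mean(corr[seq_len(bleach_index - 1L)])
  Imin <- corr[bleach_index]
  if (I0 == Imin) stopf("no bleach depth: I0 equals Imin")
  out <- data.frame(time_s = trace$time_s,
                    recovery_pct = 100 * (corr - Imin) / (I0 - Imin))
  attr(out, "bleach_index") <- bleach_index
  attr(out, "I0") <- I0
  attr(out, "Imin") <- Imin
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of `R(t) = 100 * M * (1 - exp(-k * (t - t_bleach)))`
#' to the post-bleach samples of a percent-recovery curve, reporting the
#' mobile fraction `M`, the recovery rate `k` (per second) and the
#' half-time `t_half = ln(2) / k`. Fitting uses Levenberg-Marquardt with
#' `M` bounded to `[0, 1.05]` (a little headroom over full recovery for
#' noise). When the fitted plateau is negligible the rate is not
#' identifiable and the fit is flagged rather than trusted; non-convergence
#' is likewise flagged, never thrown.
#'
#' @param recovery a [normalize_frap()] result, or a data frame with
#'   `time_s` and `recovery_pct`.
#' @param bleach_index 1-based first post-bleach frame (defaults to the
#'   `bleach_index` attribute).
#' @return An object of class `frap_fit`: list with `mobile_fraction`,
#'   `rate_k`, `t_half`, `fitted` (post-bleach fitted values),
#'   `residual_sd`, `converged` and `flags` (character vector; empty when
#'   the fit is clean).
#' @export
fit_recovery <- function(recovery, bleach_index = attr(recovery, "bleach_index")) {
  if (is.null(bleach_index)) stopf("'bleach_index' is required")
  post <- recovery[seq(from = bleach_index, to = nrow(recovery)), ]
  if (nrow(post) < 5L) stopf("need at least 5 post-bleach samples")
  tau <- post$time_s - post$time_s[1L]
  y <- post$recovery_pct
  plateau <- mean(utils::tail(y, max(3L, length(y) %/% 5L)))
  if (plateau < 1) {
    # essentially no recovery: the mobile fraction is ~0 and the rate
    # carries no information, so report the plateau and flag it instead of
    # chasing an unidentifiable exponential
    return(structure(list(mobile_fraction = max(plateau, 0) / 100,
                          rate_k = NA_real_, t_half = NA_real_,
                          fitted = rep(plateau, length(y)),
                          residual_sd = stats::sd(y - plateau),
                          converged = TRUE,
                          flags = "rate_unidentifiable"),
                     class = "frap_fit"))
  }
  m_start <- min(max(plateau / 100, 1e-3), 1.04)
  half_idx <- which(y >= plateau / 2)
  k_start <- if (length(half_idx) && tau[half_idx[1L]] > 0) {
    log(2) / tau[half_idx[1L]]
  } else {
    1 / max(tau[length(tau)] / 4, .Machine$double.eps)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 100 * M * (1 - exp(-k * tau)),
      start = list(M = m_start, k = k_start),
      lower = c(M = 0, k = 1e-12), upper = c(M = 1.05, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) e
  )
  flags <- character(0)
  if (inherits(fit, "error")) {
    return(structure(list(mobile_fraction = NA_real_, rate_k = NA_real_,
                          t_half = NA_real_, fitted = rep(NA_real_, length(y)),
                          residual_sd = stats::sd(y), converged = FALSE,
                          flags = c("fit_failed", conditionMessage(fit))),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  if (cf[["M"]] < 0.01) flags <- c(flags, "rate_unidentifiable")
  structure(list(mobile_fraction = unname(cf[["M"]]),
                 rate_k = unname(cf[["k"]]),
                 t_half = log(2) / unname(cf[["k"]]),
                 fitted = stats::fitted(fit),
                 residual_sd = stats::sd(stats::residuals(fit)),
                 converged = TRUE, flags = flags),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: mobile fraction %.3f, k = %.4f /s, t1/2 = %.2f s%s\n",
    x$mobile_fraction, x$rate_k, x$t_half,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Normalize and fit one or many FRAP traces
#'
#' @param traces a single trace data frame or a named list of traces
#'   (columns `time_s`, `intensity`, `background`).
#' @param bleach_index first post-bleach frame, shared by all traces unless
#'   each trace carries its own `bleach_index` attribute.
#' @return Data frame with one row per trace: `trace_id`,
#'   `mobile_fraction`, `rate_k`, `t_half`, `converged`, `flags`.
#' @export
analyze_frap <- function(traces, bleach_index = NULL) {
  if (is.data.frame(traces)) traces <- list(trace_1 = traces)
  ids <- names(traces) %||% sprintf("trace_%03d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    bi <- bleach_index %||% attr(traces[[i]], "bleach_index")
    fit <- fit_recovery(normalize_frap(traces[[i]], bi), bi)
    data.frame(trace_id = ids[[i]], mobile_fraction = fit$mobile_fraction,
               rate_k = fit$rate_k, t_half = fit$t_half,
               converged = fit$converged,
               flags = paste(fit$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
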