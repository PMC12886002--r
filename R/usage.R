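# Lightweight instrumentation: counts how often each optional module's code
# path actually runs, so ablation rows can prove that disabled modules are
# bypassed entirely.

.usage_env <- new.env(parent = emptyenv())

usage_reset <- function() {
  .usage_env$weem <- 0L
  .usage_env$gpsa <- 0L
  .usage_env$transfer <- 0L
  invisible(NULL)
}

usage_bump <- function(which) {
  cur <- .usage_env[[which]] %||% 0L
  assign(which, cur + 1L, envir = .usage_env)
  invisible(NULL)
}

#' Module usage counters
#'
#' Returns how many times the wavelet-enhancement, Gaussian-attention and
#' transfer code paths have executed since the last reset — the evidence the
#' ablation harness uses to show that an all-off configuration runs none of
#' the three modules.
#'
#' @param reset Reset counters to zero after reading.
#' @return Named integer vector `c(weem, gpsa, transfer)`.
#' @export
module_usage <- function(reset = FALSE) {
  out <- c(weem = .usage_env$weem %||% 0L,
           gpsa = .usage_env$gpsa %||% 0L,
           transfer = .usage_env$transfer %||% 0L)
  if (reset) usage_reset()
  out
}
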