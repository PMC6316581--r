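#' @keywords internal
"_PACKAGE"

#' @useDynLib ptcnmf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov as.dist cophenetic cor cutree dist glm glm.fit hclust mad
#'   median pchisq pnorm qnorm quantile rbinom rexp rgamma rnorm runif sd
#'   setNames binomial coef vcov chisq.test fisher.test rpois complete.cases
#' @importFrom utils read.delim write.table head modifyList packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

ptc_verbose <- function() isTRUE(getOption("ptcnmf.verbose", FALSE))

ptc_log <- function(...) {
  if (ptc_verbose()) message(sprintf(...))
  invisible(NULL)
}

stop_ptc <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "ptcnmf_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warn_ptc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Draw a sub-seed deterministically from a base seed and a stream index;
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(base_seed, stream) {
  as.integer((as.numeric(base_seed) * 1000003 + stream * 7919) %% 2147483647L)
}
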