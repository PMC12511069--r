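#' @import data.table
#' @importFrom stats approx coef cor lm median predict quantile qt rnorm runif
#'   sd setNames spline var rbinom
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

#' The twelve ALSFRS-R subscale identifiers, in instrument order
#'
#' Items 1-3 cover the bulbar domain, 4-6 fine motor, 7-9 gross motor and
#' 10-12 respiratory function. Each is scored 0 (dependent) to 4 (normal);
#' the composite is their sum (0-48).
#'
#' @export
ALSFRS_SUBSCALES <- c(
  "speech", "salivation", "swallowing",
  "handwriting", "cutting", "dressing",
  "turning", "walking", "stairs",
  "dyspnea", "orthopnea", "respiratory"
)

#' All modeled scale identifiers (subscales plus composite)
#' @export
ALSFRS_SCALES <- c(ALSFRS_SUBSCALES, "composite")

#' Derive a reproducible child seed from a master seed and a label path
#'
#' Every source of randomness in the pipeline draws its seed through this
#' function, so one master seed determines the full run. A polynomial rolling
#' hash of the label strings is folded into the seed modulo 2^31 - 1; the
#' result is a valid 32-bit R seed and is stable across platforms.
#'
#' @param seed master integer seed
#' @param ... label components (coerced to character), e.g. "streams", "P1"
#' @return integer in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# round half away from zero (scores are nonnegative, so half-up)
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scale range: subscales live on [0,4], the composite on [0,48]
scale_range <- function(scale_id) {
  if (identical(scale_id, "composite")) c(0, 48) else c(0, 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_alstrack <- function(...) stop(..., call. = FALSE)
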