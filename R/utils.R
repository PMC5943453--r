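#' Inverse-logit and logit transforms
#'
#' Thin wrappers around [stats::plogis()] and [stats::qlogis()] used on the
#' link scale of the survival and productivity models.
#'
#' @param x numeric vector (log-odds for `invlogit`, probabilities for
#'   `logit`).
#' @return numeric vector of the same length.
#' @export
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @export
logit <- function(x) stats::qlogis(x)

# clamp a linear predictor so exp()/plogis() stay finite
.clamp <- function(x, lim = 30) pmin(pmax(x, -lim), lim)

.is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# region coding used throughout: integer index into this level set
REGION_LEVELS <- c("west", "central", "east")

.region_index <- function(region) {
  idx <- match(as.character(region), REGION_LEVELS)
  if (anyNA(idx)) {
    .stopf("unknown region label(s): %s",
           paste(unique(setdiff(region, REGION_LEVELS)), collapse = ", "))
  }
  idx
}
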