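# Internal helpers shared across modules.

# Transition kinds use the same spelling everywhere (memory, CSV, JSON).
.KIND_RT <- "RUN_TO_TURN"
.KIND_TR <- "TURN_TO_RUN"
.KINDS <- c(.KIND_RT, .KIND_TR)
.STATES <- c("RUN", "TURN")

# classed conditions so callers can distinguish bad input from bad luck
.optorc_stop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "optorc_error")))
}

stop_invalid <- function(...) .optorc_stop("optorc_invalid_argument", ...)
stop_degenerate <- function(...) .optorc_stop("optorc_degenerate", ...)
stop_not_found <- function(...) .optorc_stop("optorc_not_found", ...)
stop_empty <- function(...) .optorc_stop("optorc_empty_result", ...)
stop_fit_failure <- function(...) .optorc_stop("optorc_fit_failure", ...)
stop_simulation <- function(...) .optorc_stop("optorc_simulation_failure", ...)

check_kind <- function(kind) {
  if (!(is.character(kind) && length(kind) == 1L && kind %in% .KINDS)) {
    stop_invalid("`kind` must be one of ", paste(.KINDS, collapse = ", "))
  }
  kind
}

# state an animal must occupy to be at risk for a transition of `kind`
source_state <- function(kind) if (kind == .KIND_RT) "RUN" else "TURN"
target_state <- function(kind) if (kind == .KIND_RT) "TURN" else "RUN"

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("`", name, "` must be > 0")
  invisible(x)
}

# population standard deviation (divide by n); declared convention for
# speed standard scores
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
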