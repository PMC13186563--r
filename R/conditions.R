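# Classed conditions so callers (and the CLI) can distinguish bad input,
# incomplete landscapes, and simulation/capacity failures.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("consortia_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_incomplete <- function(msg, ...) {
  stop(structure(
    class = c("consortia_incomplete_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_simulation <- function(msg, ...) {
  stop(structure(
    class = c("consortia_simulation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_capacity <- function(msg, step = NA_integer_, ...) {
  stop(structure(
    class = c("consortia_capacity_error", "consortia_simulation_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), step = step)
  ))
}
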