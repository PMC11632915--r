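# Classed conditions so callers (and the CLI) can map failures to exit codes.

cirbe_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cirbe_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

domain_error <- function(message) cirbe_error(message, "cirbe_domain_error")
schema_error <- function(message) cirbe_error(message, "cirbe_schema_error")
usage_error <- function(message) cirbe_error(message, "cirbe_usage_error")
convergence_error <- function(message) cirbe_error(message, "cirbe_convergence_error")
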