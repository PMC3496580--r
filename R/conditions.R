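#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failure kinds to exit
# codes without string matching.
pg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
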