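# Condition classes shared across the package. Three failure families are
# distinguished so a command-line wrapper can map them to distinct exit codes:
#   vw_usage_error    -- the request itself is malformed (bad flags, bad
#                        region expression, too few files)
#   vw_input_error    -- a data file violates its format contract
#   vw_analysis_error -- inputs parse but the analysis is impossible
#                        (e.g. no seed gene present in the network)

vw_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "vw_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

vw_usage_error <- function(msg) vw_stop("vw_usage_error", msg, sys.call(-1))
vw_input_error <- function(msg) vw_stop("vw_input_error", msg, sys.call(-1))
vw_analysis_error <- function(msg) vw_stop("vw_analysis_error", msg, sys.call(-1))

# Trim surrounding whitespace from a character vector.
vw_trim <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", x)
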