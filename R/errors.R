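# Condition classes used across the package. Every user-facing failure is
# signalled with a subclass of "dwisig_error" so callers (and the CLI) can
# distinguish bad input from bad geometry from degenerate data.

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_input_error", "dwisig_error"))
}

stop_geometry <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_geometry_error", "dwisig_error"))
}

stop_tiling <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_tiling_error", "dwisig_error"))
}

stop_size <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_size_error", "dwisig_error"))
}

stop_division <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_division_error", "dwisig_error"))
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_config_error", "dwisig_error"))
}

stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("dwisig_degenerate_data_error", "dwisig_error"))
}
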