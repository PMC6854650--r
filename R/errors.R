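# Classed conditions so callers (and the CLI) can distinguish bad
# configuration from bad data without parsing messages.

kc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "kc_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid_kmer   <- function(msg) kc_stop(msg, "kc_invalid_kmer_error")
stop_invalid_sequence <- function(msg) kc_stop(msg,
                                               "kc_invalid_sequence_error")
stop_incompatible   <- function(msg) kc_stop(msg, "kc_incompatible_db_error")
stop_format         <- function(msg) kc_stop(msg, "kc_format_error")
stop_data           <- function(msg) kc_stop(msg, "kc_data_error")
stop_config         <- function(msg) kc_stop(msg, "kc_config_error")
stop_empty_sample   <- function(msg) kc_stop(msg, c("kc_empty_sample_error",
                                                    "kc_data_error"))
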