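# Structured error conditions: configuration errors (bad arguments, bad
# config files) vs data errors (malformed or inconsistent inputs). The CLI
# maps these to exit codes 2 and 3.

lg_config_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("loopgene_config_error", "loopgene_error", "error", "condition")))
}

lg_data_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("loopgene_data_error", "loopgene_error", "error", "condition")))
}

lg_parse_error <- function(msg, path = NULL, line = NULL) {
  loc <- if (!is.null(path) && !is.null(line)) {
    sprintf(" [%s, line %d]", path, as.integer(line))
  } else if (!is.null(line)) {
    sprintf(" [line %d]", as.integer(line))
  } else ""
  stop(errorCondition(paste0(msg, loc),
    class = c("loopgene_parse_error", "loopgene_data_error",
              "loopgene_error", "error", "condition")))
}
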