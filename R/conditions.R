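ct_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "celltyper_error")))
}

ct_msg <- function(...) {
  message("[celltyper] ", ...)
}

ct_warn <- function(...) {
  warning("[celltyper] ", ..., call. = FALSE)
}

# non-standard evaluation columns used in ggplot2 layers
utils::globalVariables(c("cluster", "cell_type", "size_value", "bar_value",
                         "is_hard_label"))
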