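# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Classed conditions so callers can distinguish configuration problems,
# malformed data and stage failures programmatically.
config_error <- function(...) {
  stop(structure(class = c("hubtrace_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
data_error <- function(...) {
  stop(structure(class = c("hubtrace_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stage_error <- function(stage, parent) {
  stop(structure(class = c("hubtrace_stage_error", "error", "condition"),
                 list(message = paste0("stage '", stage, "' failed: ",
                                       conditionMessage(parent)),
                      call = sys.call(-1), stage = stage)))
}
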