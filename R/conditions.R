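# Classed error conditions.  Every error the package raises carries
#   spadspec_<Name>   (specific condition, e.g. spadspec_BandNotFound)
#   spadspec_input / spadspec_degenerate  (category; the CLI maps input
#       errors to exit code 2 and degenerate-data errors to exit code 3)
#   spadspec_error
.spadStop <- function(name, message, category, data = list()) {
  cond <- structure(
    class = c(paste0("spadspec_", name),
              paste0("spadspec_", category),
              "spadspec_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

.stopInput <- function(name, message, ...) {
  .spadStop(name, message, "input", list(...))
}

.stopDegenerate <- function(name, message, ...) {
  .spadStop(name, message, "degenerate", list(...))
}
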