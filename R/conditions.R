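# Classed error conditions. Everything a malformed input can raise inherits
# from "lipidParseError" so table-level code can skip-and-log bad rows while
# still propagating programming errors.

.parseError <- function(subclass, message, offending = NULL, call = NULL) {
  stop(structure(
    class = c(subclass, "lipidParseError", "error", "condition"),
    list(message = message, call = call, offending = offending)))
}

.unparseableName <- function(name, why) {
  .parseError("unparseableNameError",
              sprintf("unparseable name: '%s' (%s)", name, why), name)
}

.unparseableChain <- function(token) {
  .parseError("unparseableChainError",
              sprintf("unparseable chain token: '%s'", token), token)
}

.malformedIdentifier <- function(name, why) {
  .parseError("malformedIdentifierError",
              sprintf("malformed identifier: '%s' (%s)", name, why), name)
}

.unparseableLipid <- function(name, why) {
  .parseError("unparseableLipidError",
              sprintf("unparseable lipid identifier: '%s' (%s)", name, why),
              name)
}
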