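# internal numerical helpers

clip01 <- function(x) pmin(1, pmax(0, x))

# log10(1 + 10^u), stable for large |u|
log10_1p_pow10 <- function(u) {
  out <- numeric(length(u))
  big <- u > 0
  out[big] <- u[big] + log1p(10^(-u[big])) / log(10)
  out[!big] <- log1p(10^(u[!big])) / log(10)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_combosens <- function(..., class) {
  stop(structure(
    class = c(class, "combosens_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
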