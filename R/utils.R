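`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Polynomial rolling hash over a character vector; used for config
## fingerprints in run manifests (stable across sessions, unlike serialize()).
.config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.empty_df <- function(cols, classes) {
  out <- lapply(classes, function(cl) vector(cl, 0L))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
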