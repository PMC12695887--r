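#' @keywords internal
"_PACKAGE"

# Content digest of an arbitrary R object: serialized bytes -> md5.
# Used for provenance stamps; stable within a session and across reloads
# of the same object, not across R serialization-format changes.
pa_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(serialize(x, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

# Deterministic per-item seed derived from a top-level seed so that
# generation is order-independent: item (i, j) always gets the same
# substream regardless of how many other items are drawn.
pa_child_seed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) * 48271 + as.double(i) * 69621 + as.double(j)) %%
    2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pa <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
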