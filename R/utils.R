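#' @keywords internal
"_PACKAGE"

# Derive a stage-specific seed from a master seed. Offsets are fixed and
# documented so that every source of randomness funnels through one master
# seed; results stay below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    split = 101L, cv = 211L, folds = 223L, shap = 307L, scramble = 401L,
    bootstrap = 503L, sim = 601L, featsel = 701L, explain = 809L,
    model = 907L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

stopif <- function(cond, ...) if (cond) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
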