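# Frozen oracle constants, computed by dense independent integration
# (adaptive LSODA at rtol 1e-12 / atol 1e-16, peak refined by bounded
# minimisation on the dense interpolant) before the implementation was
# written.
HMAX_STEP06_SLOW <- 0.5914354886  # peak H, 0.6 mM step, slow-mRNA linear set
HMAX_STEP06_FAST <- 0.5575289929  # same, fast-mRNA linear set
HEQ_STEP04_SLOW  <- 0.0296555202  # equilibrium H, 0.4 mM step, slow set
HEQ_NL_BASAL     <- 3.932883e-4   # nonlinear-set equilibrium H at I = 0

# lazily cached expensive quantities shared across test files
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

htox_of <- function(set) {
  cached(paste0("htox_", set), calibrateHtox(linearParams(set)))
}

log_doses <- function() c(0, exp(seq(log(0.002), log(0.4), length.out = 19)))
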