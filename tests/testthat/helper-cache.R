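# shared steady states across test files (same process), to keep the suite fast
.cache <- new.env(parent = emptyenv())

ref_params <- function() reference_parameters()

ref_off <- function() {
  if (is.null(.cache$off)) .cache$off <- find_steady_state(ref_params())
  .cache$off
}

ref_fold <- function() {
  if (is.null(.cache$fold))
    .cache$fold <- steady_fold_change(ref_params(), 28.062)
  .cache$fold
}

ref_on <- function() attr(ref_fold(), "on")
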