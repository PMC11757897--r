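# .Call glue for the compiled residual/flow kernels

.residual_kernel <- function(x, cn, mode, hfreeze) {
  .Call(`_hemonet_residual_kernel`, as.numeric(x), cn, as.integer(mode),
        as.numeric(hfreeze))
}

.flows_kernel <- function(x, cn, mode, hfreeze) {
  .Call(`_hemonet_flows_kernel`, as.numeric(x), cn, as.integer(mode),
        as.numeric(hfreeze))
}
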