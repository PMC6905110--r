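# Independent oracles: deliberately naive re-derivations of the analytic
# quantities, used to cross-check the package's closed-form implementations.

# literal loop-nest multiplication counter: walks every output position and
# kernel tap of every conv layer and adds Cin * Cout per tap
oracle_flops <- function(spec, input_hw) {
  hw <- as.integer(input_hw)
  total <- 0
  for (ly in spec$layers) {
    out_h <- (hw[1] + 2L * ly$padding - ly$kernel[1]) %/% ly$stride + 1L
    out_w <- (hw[2] + 2L * ly$padding - ly$kernel[2]) %/% ly$stride + 1L
    if (ly$kind == "conv") {
      for (oy in seq_len(out_h)) for (ox in seq_len(out_w))
        for (ky in seq_len(ly$kernel[1])) for (kx in seq_len(ly$kernel[2]))
          total <- total + ly$in_channels * ly$out_channels
    }
    hw <- c(out_h, out_w)
  }
  total
}

# receptive field by gradient support of a linearized stack: every conv is
# replaced by a single-channel all-ones kernel, every maxpool by an all-ones
# conv with the same kernel/stride (valid linearization for support), and a
# unit perturbation at one interior output cell is propagated back to the
# input; the side length of its nonzero support is the receptive field
oracle_rf_support <- function(kernels, strides, input_n = 160L) {
  hw <- c(input_n, input_n)
  dims <- list()
  for (l in seq_along(kernels)) {
    dims[[l]] <- hw
    hw <- (hw - kernels[l]) %/% strides[l] + 1L
  }
  stopifnot(all(hw >= 3L))
  dout <- array(0, c(hw, 1L))
  dout[ceiling(hw[1] / 2), ceiling(hw[2] / 2), 1] <- 1
  for (l in rev(seq_along(kernels))) {
    w <- matrix(1, kernels[l]^2, 1)
    x <- array(0, c(dims[[l]], 1L))
    dout <- conv_backward_oracle(x, w, dout, kernels[l], strides[l])
  }
  supp <- which(dout != 0, arr.ind = TRUE)
  max(supp[, 1]) - min(supp[, 1]) + 1L
}

# minimal transposed convolution (scatter of dout through an all-ones
# kernel), independent of the package's C++ engine
conv_backward_oracle <- function(x, w, dout, k, s) {
  d <- dim(x)
  dx <- array(0, d)
  oh <- dim(dout)[1]; ow <- dim(dout)[2]
  for (oj in seq_len(ow)) for (oi in seq_len(oh)) {
    v <- dout[oi, oj, 1]
    if (v == 0) next
    rows <- ((oi - 1L) * s + 1L):((oi - 1L) * s + k)
    cols <- ((oj - 1L) * s + 1L):((oj - 1L) * s + k)
    dx[rows, cols, 1] <- dx[rows, cols, 1] + v
  }
  dx
}

# direct window summation over a density matrix (no summed-area table)
oracle_window_sum <- function(values, top, left, size) {
  H <- nrow(values); W <- ncol(values)
  r <- intersect(seq_len(H), (top + 1L):(top + size))
  c <- intersect(seq_len(W), (left + 1L):(left + size))
  if (length(r) == 0 || length(c) == 0) 0 else sum(values[r, c])
}

rand_conv_stack <- function(n_layers) {
  kernels <- sample(c(1L, 3L, 5L), n_layers, replace = TRUE)
  strides <- sample(1:2, n_layers, replace = TRUE)
  list(kernels = kernels, strides = strides)
}
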