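# shared helpers for the decompevo test suite

# default microsite parameters with a small lattice for fast spatial tests
fast_params <- function(L = 4, ...) {
  p <- soil_params(...)
  p$L <- L
  p
}

# a populated microsite with hand-set pools and n cells at trait phi
toy_site <- function(n = 3, phi = 0.5, S = 0, c = 1e-7, d = 1e-11, z = 1e-10) {
  microsite_state(c = c, d = d, z = z,
                  cells = data.frame(phi = rep(phi, n),
                                     S = rep(S, length.out = max(n, 1))[seq_len(n)],
                                     strain = rep(1L, n)))
}

# relative difference guarded against zero denominators
rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)
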