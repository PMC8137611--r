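# Independent oracles used across the suite; none of these call the
# package's own solution paths.

# Closed-form solution of the feedback-free (gamma = 0) model after an
# instantaneous kill of the proliferating pool: the chain is linear with
# constant input p0, so compartment j (1-based, circ is j = n_transit + 1)
# relaxes as an Erlang partial sum.
linear_chain_circ <- function(t, circ0, p0, k, n_transit) {
  j <- n_transit + 1L
  terms <- sapply(t, function(tt) sum((k * tt)^(0:(j - 1L)) / factorial(0:(j - 1L))))
  p0 + (circ0 - p0) * exp(-k * t) * terms
}

# Eigenvalues of the linearization from the characteristic relation
# mu * (mu + 1)^(n_transit + 1) = -gamma, solved with polyroot and scaled
# by k = (n_transit + 1) / mtt.
characteristic_eigenvalues <- function(gamma, mtt, n_transit) {
  m1 <- n_transit + 1L
  # polynomial gamma + sum_i C(m1, i) mu^(i+1), ascending coefficients
  coefs <- c(gamma, choose(m1, 0:m1))
  k <- m1 / mtt
  k * polyroot(coefs)
}

# canonical ordering for multiset comparison of complex spectra
sort_complex <- function(z) z[order(round(Re(z), 12), round(Im(z), 12))]

expect_spectra_equal <- function(a, b, rel_tol = 1e-8) {
  a <- sort_complex(a); b <- sort_complex(b)
  scale <- max(Mod(b))
  expect_lt(max(Mod(a - b)), rel_tol * scale)
}
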