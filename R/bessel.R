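# Bessel J0 and J1 for complex argument.
#
# The Womersley solution needs J0 and J1 at z = i^{3/2} * alpha * (r/R), i.e.
# along the ray arg(z) = 3*pi/4 with |z| up to the Womersley-number cap of 50.
# Base R's besselJ is real-only, so these are evaluated from the ascending
# power series
#   J0(z) = sum_k (-1)^k (z^2/4)^k / (k!)^2
#   J1(z) = (z/2) sum_k (-1)^k (z^2/4)^k / (k! (k+1)!)
# in complex double arithmetic. At |z| = 50 the largest term is ~1e19 against
# a result of ~1e14, so roundoff cancellation costs ~5 digits, leaving ~1e-11
# relative accuracy — far below anything the downstream quadrature resolves.
# Terms are added until they fall below 1e-18 of the running maximum (capped
# at 200, ample for |z| <= 50).

besselJ0_complex <- function(z) {
  z <- as.complex(z)
  w <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))
  total <- term
  biggest <- abs(term)
  for (k in 1:200) {
    term <- term * w / (k * k)
    total <- total + term
    biggest <- pmax(biggest, abs(term))
    if (all(abs(term) < 1e-18 * pmax(biggest, 1))) break
  }
  total
}

besselJ1_complex <- function(z) {
  z <- as.complex(z)
  w <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))
  total <- term
  biggest <- abs(term)
  for (k in 1:200) {
    term <- term * w / (k * (k + 1))
    total <- total + term
    biggest <- pmax(biggest, abs(term))
    if (all(abs(term) < 1e-18 * pmax(biggest, 1))) break
  }
  (z / 2) * total
}
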