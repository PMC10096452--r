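#' Exact speciation of a 1:1 host-guest equilibrium
#'
#' Solves the mass-action equilibrium H + G <-> HG with association constant
#' K = \[HG\]/(\[H\]\[G\]) under the mass balances
#' \[H\] + \[HG\] = host_total and \[G\] + \[HG\] = guest_total. The complex
#' concentration is the physically admissible (smaller) root of
#' K x^2 - (K (Ht + Gt) + 1) x + K Ht Gt = 0, evaluated in the numerically
#' stable form 2c / (b + sqrt(b^2 - 4ac)) so that no cancellation occurs for
#' weak or very strong binding.
#'
#' @param K Association constant in 1/M (>= 0). Scalar or vector.
#' @param host_total,guest_total Total (analytical) concentrations in mol/L
#'   (>= 0). Vectors are recycled to a common length.
#' @return A data.frame of class `equilibrium_state` with columns
#'   `free_host`, `free_guest`, `complex` (mol/L).
#' @examples
#' solve_equilibrium_1to1(1e4, 1e-4, 1e-4)   # complex = 3.8197e-5 M
#' solve_equilibrium_1to1(0,   1e-4, 1e-4)   # no association
#' @export
solve_equilibrium_1to1 <- function(K, host_total, guest_total) {
  n <- max(length(K), length(host_total), length(guest_total))
  K <- rep_len(as.numeric(K), n)
  ht <- rep_len(as.numeric(host_total), n)
  gt <- rep_len(as.numeric(guest_total), n)
  if (any(K < 0) || any(ht < 0) || any(gt < 0) ||
      any(!is.finite(c(K, ht, gt))))
    stop("K and total concentrations must be finite and >= 0", call. = FALSE)

  b <- K * (ht + gt) + 1
  c_ <- K * ht * gt
  disc <- pmax(b * b - 4 * K * c_, 0)
  hg <- ifelse(c_ == 0, 0, 2 * c_ / (b + sqrt(disc)))
  hg <- pmin(hg, pmin(ht, gt))   # guard rounding at the K -> Inf limit
  out <- data.frame(free_host = ht - hg, free_guest = gt - hg, complex = hg)
  class(out) <- c("equilibrium_state", "data.frame")
  out
}
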