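#' Circuit parameters for the CPE + R1||C + R2 equivalent circuit
#'
#' Constructs the five-element parameter set of the fibrosing-electrode
#' equivalent circuit: a constant phase element (CPE) for the
#' electrode-electrolyte interface, a resistor `r1` in parallel with a
#' capacitor `c` for the bulk tissue/construct, and a series resistor `r2`
#' for the medium and ground path.
#'
#' @param cpe_t CPE magnitude Y, in S·s^p. Strictly positive.
#' @param cpe_p CPE phase exponent p, dimensionless, in (0, 1]. `p = 1`
#'   reduces the CPE to an ideal capacitor of value `cpe_t` farad.
#' @param r1 Bulk resistance R1 in ohm. Strictly positive.
#' @param c Bulk capacitance C in farad. Strictly positive.
#' @param r2 Series (access/medium) resistance R2 in ohm. Strictly positive.
#'
#' @return An object of class `circuit_params`: a named list with the five
#'   elements.
#' @examples
#' circuit_params(cpe_t = 1e-7, cpe_p = 0.8, r1 = 500, c = 1e-9, r2 = 300)
#' @export
circuit_params <- function(cpe_t, cpe_p, r1, c, r2) {
  vals <- c(cpe_t = cpe_t, cpe_p = cpe_p, r1 = r1, c = c, r2 = r2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all circuit elements must be finite and strictly positive")
  }
  if (cpe_p > 1) {
    stop("cpe_p must lie in (0, 1]")
  }
  structure(list(cpe_t = cpe_t, cpe_p = cpe_p, r1 = r1, c = c, r2 = r2),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>  CPE-T =", format(x$cpe_t, digits = 4),
      "S.s^p  CPE-P =", format(x$cpe_p, digits = 4),
      "\n  R1 =", format(x$r1, digits = 5), "Ohm  C =",
      format(x$c, digits = 4), "F  R2 =", format(x$r2, digits = 5), "Ohm\n")
  invisible(x)
}

#' Parameters for the legacy access-resistance / polarization circuit
#'
#' The simple two-element waveform circuit of the earlier cochlear-implant
#' literature: an interface resistor `r_pol` in parallel with an interface
#' capacitor `c_pol`, in series with a bulk access resistor `r_access`.
#'
#' @param r_access Series bulk (access) resistance, ohm.
#' @param r_pol Interface (polarization) resistance, ohm.
#' @param c_pol Interface capacitance, farad.
#' @return An object of class `simple_circuit_params`.
#' @examples
#' simple_circuit_params(r_access = 300, r_pol = 5000, c_pol = 1e-8)
#' @export
simple_circuit_params <- function(r_access, r_pol, c_pol) {
  vals <- c(r_access = r_access, r_pol = r_pol, c_pol = c_pol)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all circuit elements must be finite and strictly positive")
  }
  structure(list(r_access = r_access, r_pol = r_pol, c_pol = c_pol),
            class = "simple_circuit_params")
}

#' @export
print.simple_circuit_params <- function(x, ...) {
  cat("<simple_circuit_params>  R_access =", format(x$r_access, digits = 5),
      "Ohm  R_pol =", format(x$r_pol, digits = 5), "Ohm  C_pol =",
      format(x$c_pol, digits = 4), "F\n")
  invisible(x)
}

element_names <- function(model_kind) {
  switch(model_kind,
         full = c("cpe_t", "cpe_p", "r1", "c", "r2"),
         simple = c("r_access", "r_pol", "c_pol"),
         stop("unknown model_kind: ", model_kind))
}
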