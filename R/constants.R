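# Physical constants (SI).  GAS_R in J/(mol K), FARADAY in C/mol.
AVOGADRO <- 6.02214076e23
FARADAY  <- 96485.33212
GAS_R    <- 8.31446262

#' Default temperature used for Goldman-Hodgkin-Katz terms
#'
#' 293.15 K (20 degrees C) unless a model declares otherwise.
#' @keywords internal
DEFAULT_TEMPERATURE <- 293.15
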