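# Physical constants (SI, CODATA 2018 exact values).
# Package-wide units: time s, concentration mM, energy kJ mol^-1, temperature K.
.kB <- 1.380649e-23    # J K^-1
.h  <- 6.62607015e-34  # J s
.Rgas <- 8.314462618   # J mol^-1 K^-1

.C_TO_K <- 273.15

#' Standard operating temperature of the motor network (40 degrees C), K
#' @keywords internal
.T_OPERATING <- 40 + .C_TO_K  # 313.15 K
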