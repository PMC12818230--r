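# lead-name constants used across modules (file sorts first for collation)

LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")
LEADS_8  <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

`%||%` <- function(a, b) if (is.null(a)) b else a
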