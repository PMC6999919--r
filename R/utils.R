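`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi
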