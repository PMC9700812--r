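# shared internal constants: fixed variable order and component indices

.VARS <- c("Cdh1", "SBF", "Cln2", "Clb5", "Clb2G", "Clb2M", "Cdc20")
.NVAR <- 7L

.I_CDH1 <- 1L; .I_SBF <- 2L; .I_CLN2 <- 3L; .I_CLB5 <- 4L
.I_CLB2G <- 5L; .I_CLB2M <- 6L; .I_CDC20 <- 7L

.SINK_IDX <- 65L  # index of the stable G1 state "1000000"
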