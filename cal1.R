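library(slepath)
source(system.file("acceptance","experiments.R", package="slepath"), local=TRUE)
t0 <- Sys.time()
res <- acc_null_rejection(101, 500)
cat("rejection:", res$rate, " time", round(as.numeric(Sys.time()-t0, units="secs")), "s\n")
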