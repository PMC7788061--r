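library(slepath)
source(system.file("acceptance","experiments.R", package="slepath"), local=TRUE)
res <- acc_perm_agreement(202, 20)
print(round(res$z, 2))
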