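#!/usr/bin/env Rscript
# End-to-end study: GP champions + printed solutions + lambda sweep,
# orchestrated by run_full_pipeline(), with all artefacts and a JSON
# manifest under results/pipeline/.

library(evoreliab)

res <- run_full_pipeline(out_dir = "results/pipeline",
                         n_champions = 3, gp_seeds = 1:3,
                         lambdas = c(0, 0.1), evo_seeds = 1:3)
print(res$report)
cat("\nNetwork summary (champion per gate x lambda x seed):\n")
print(res$nn_summary, digits = 3)
cat("\nArtefacts written under results/pipeline/\n")
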