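#!/usr/bin/env Rscript
# Stage 4 -- haplogroup assignment of the stage-3 consensus.
#
# Variants are called against the synthetic reference, hypervariable sites
# are masked (A/C stretches at nps 303-315, 522-523 and 16180-16193 except
# 16189, plus np 16519), and the variant set is scored against the fixture
# defining-variant tree with the Kulczynski measure.

library(osteoid)
dir.create("results", showWarnings = FALSE)

ref <- simulate_reference(16569, seed = 9)
tree <- fixture_haplogroup_tree(ref, seed = 101)

cons_path <- "results/consensus.fasta"
if (!file.exists(cons_path)) stop("run analysis/03_adna.R first")
cons <- read_fasta_seq(cons_path)

vs <- apply_mask(call_variants(cons, ref), mask_policy())
cat(sprintf("%d substitution variants after masking; %d uncovered positions\n",
            nrow(vs$variants), length(vs$uncovered)))

call <- assign_haplogroup(vs, tree)
print(call)
cat("Runner-ups:\n")
print(call$runner_ups)

jsonlite::write_json(list(
  best_label = call$best_label, score = call$score, expected = call$expected,
  found = call$found,
  private = paste0(call$private$ref, call$private$position, call$private$alt),
  runner_ups = call$runner_ups),
  "results/haplogroup_call.json", auto_unbox = TRUE, digits = NA)
cat("written: results/haplogroup_call.json\n")
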