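#!/usr/bin/env Rscript
# Stage 4 — identity clustering and phylogeny-based decontamination.
#
# Clusters the cohort at 95% identity (cd-hit semantics: greedy by length,
# best eligible cluster, identity over the shorter sequence), then builds
# a neighbor-joining tree over the cluster representatives and flags
# taxonomically incongruent leaves round by round. The planted
# contaminants carry a MANEAL taxogroup label but MANEA sequence content,
# so they should be the ones flagged.

suppressMessages(library(gh99evo))

records <- read_fasta("results/data/cohort.fasta")
tax <- read_taxonomy("results/data/taxonomy.tsv")
truth <- read.delim("results/data/truth.tsv")
dir.create("results/decontam", showWarnings = FALSE, recursive = TRUE)

cl <- greedy_cluster(records, c = 0.95, s = 0.5)
write_cluster_tsv(cl, "results/decontam/clusters.tsv")
cat("Clustering at 95% identity:", nrow(records), "records ->",
    length(cluster_representatives(cl)), "clusters\n")

reps <- cluster_representatives(cl)
rep_records <- records[match(reps, records$id), ]
D <- pairwise_distance(rep_records)
report <- flag_contaminants(D, tax,
                            species_of = setNames(rep_records$species,
                                                  rep_records$id),
                            k = 3, level = 1, max_rounds = 5)
write_contamination_tsv(report, "results/decontam/contamination.tsv")
ape::write.tree(neighbor_joining(D), "results/decontam/nj_representatives.nwk")

planted <- truth$id[truth$contaminant]
cat("Decontamination over", report$rounds, "round(s): flagged",
    nrow(report$flagged), "of", length(reps), "representatives\n")
cat("Planted contaminants flagged:",
    sum(report$flagged$id %in% planted), "of", length(planted),
    "; false positives:", sum(!(report$flagged$id %in% planted)), "\n")
writeLines(report$surviving, "results/decontam/surviving_ids.txt")
cat("Wrote results/decontam\n")
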