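#!/usr/bin/env Rscript
# Step 2 — trans contact counting and length-normalized rates.
#
# Counts trans pairs T_ij for every scaffold pair of each assembly in a
# single pass, normalizes by the product of scaffold lengths (pairs per
# Mb^2), tallies intra-scaffold pairs above 1 kb separation, and bins
# trans pair ends into 500 kb density tracks. The scaffold-pair rate
# tables written here are the genome-wide background that step 3 tests
# breakpoints against.

library(karyocourt)
dir.create("results", showWarnings = FALSE)

study <- simulate_study(sim_config(seed = 1))

for (side in names(study$assemblies)) {
  a <- study$assemblies[[side]]
  ss <- a$derivation$scaffolds
  ct <- count_contacts(a$pairs, ss)
  print(ct)
  tab <- ct$pairs
  names(tab)[names(tab) == "T"] <- "T_ij"
  names(tab)[names(tab) == "rate"] <- "rate_pairs_per_Mb2"
  write.table(tab, sprintf("results/02_contact_rates_%s.tsv",
                           assembly_id(ss)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(ct$intra, sprintf("results/02_intra_rates_%s.tsv",
                                assembly_id(ss)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  dens <- bin_trans_density(a$pairs, ss)
  write.table(dens, sprintf("results/02_trans_density_%s.tsv",
                            assembly_id(ss)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf(
    "%s: median background rate %.2f pairs/Mb2, median intra rate %.0f",
    assembly_id(ss), median(ct$pairs$rate), median(ct$intra$rate_intra)))
}
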