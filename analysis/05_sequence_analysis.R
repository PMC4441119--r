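#!/usr/bin/env Rscript
# Stage 5: sequence charge patterning.
#
# Computes the Das-Pappu kappa parameter for the BH3 peptide the package's
# bead model emulates, alongside reference sequences spanning the 0-1 range.

library(ktnet)
dir.create("results", showWarnings = FALSE)

seqs <- list(
  bh3_peptide = read_fasta_sequence(
    system.file("extdata", "puma_bh3.fasta", package = "ktnet")),
  perfectly_mixed = "EKEKEKEKEKEKEKEKEKEK",
  fully_segregated = "EEEEEEEEEEKKKKKKKKKK")

tab <- do.call(rbind, lapply(names(seqs), function(nm) {
  p <- charge_patterning(seqs[[nm]])
  data.frame(sequence = nm, length = nchar(seqs[[nm]]),
             FCR = round(p$FCR, 3), NCPR = round(p$NCPR, 3),
             kappa = round(p$kappa, 4))
}))
print(tab, row.names = FALSE)
write.table(tab, "results/05_charge_patterning.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

p <- charge_patterning(seqs$bh3_peptide)
message(sprintf(
  "BH3 peptide: FCR %.2f (strong polyampholyte), kappa %.3f - well-mixed charges,",
  p$FCR, p$kappa))
message("consistent with an expanded-to-globular disordered ensemble held ",
        "together by alternative electrostatic networks.")
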