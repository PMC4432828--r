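#!/usr/bin/env Rscript
# Step 1 — synthetic study inputs.
#
# Builds the data every later step consumes: a random reference chromosome
# with human-like CpG depletion, a synthetic gene annotation, and the two
# repeat consensus amplicons with their primer-delimited definitions. Writes
# everything under results/data/ and prints what was made.

suppressPackageStartupMessages(library(bsmethr))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()
g <- cfg$global

ref <- generate_reference(g$reference_length, g$gc_fraction, g$cpg_factor,
                          seed = cfg$seed, id = "chrS")
write_sequences(ref, file.path(outdir, "reference.fasta"), "FASTA")

genes <- generate_genes(g$gene_count, g$reference_length, g$gene_mean_len,
                        chrom = "chrS", seed = cfg$seed + 1L)
write_intervals(genes, file.path(outdir, "genes.bed"))

ctx <- table(assign_methylome(ref, 0.5, seed = 1)$context)
cat(sprintf("reference: %d b (GC target %.2f), cytosine contexts: %s\n",
            g$reference_length, g$gc_fraction,
            paste(names(ctx), as.integer(ctx), sep = "=", collapse = ", ")))
cat(sprintf("genes: %d intervals, total %d b\n",
            nrow(genes), sum(genes$end - genes$start)))

amp_rows <- do.call(rbind, lapply(c("alu", "line1"), function(a) {
  amp <- consensus_amplicon(a)
  def <- locate_amplicon(amp$primers, amp$consensus, bisulfite_space = TRUE)
  file.copy(system.file("extdata", paste0(a, "_consensus.fasta"),
                        package = "bsmethr"),
            file.path(outdir, paste0(a, "_consensus.fasta")),
            overwrite = TRUE)
  data.frame(amplicon = a, consensus_id = def$consensus_id,
             orientation = def$orientation, start = def$start,
             end = def$end, length = def$length,
             fwd_mismatches = def$fwd_mismatches,
             rev_mismatches = def$rev_mismatches,
             stringsAsFactors = FALSE)
}))
write_tsv(amp_rows, file.path(outdir, "amplicon_definitions.tsv"))
cat("amplicon definitions (bisulfite-space primer matching):\n")
print(amp_rows, row.names = FALSE)
cat("done; inputs under", outdir, "\n")
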