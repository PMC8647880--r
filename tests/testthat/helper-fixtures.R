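# Shared small fixtures, built in code at load time.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(n_genotypes = 60, n_markers = 120,
                                            n_chromosomes = 3, seed = 7))
    cache
  }
})

# hand-written HapMap fixture: 2 markers x 3 samples, A/T site with calls
# AA / AT / TT and an IUPAC heterozygote
write_hapmap_fixture <- function(path) {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "S1", "S2", "S3"), collapse = "\t")
  rows <- c(paste(c("m1", "A/T", "Chr1", "100", "+", rep("NA", 6),
                    "AA", "AT", "TT"), collapse = "\t"),
            paste(c("m2", "A/T", "Chr1", "200", "+", rep("NA", 6),
                    "W", "N", "AA"), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("Chr1", "100", "v1", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("Chr1", "200", "v2", "G", "C", ".", "PASS", ".", "GT",
            "./.", "0/0", "1/1"), collapse = "\t"),
    paste(c("Chr1", "300", "v3", "G", "C,A", ".", "PASS", ".", "GT",
            "0/1", "0/2", "1/1"), collapse = "\t")), path)
  path
}

write_gff_fixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    paste(c("Chr2", "test", "gene", "720000", "730000", ".", "+", ".",
            "ID=GeneA"), collapse = "\t"),
    paste(c("Chr2", "test", "gene", "600000", "708457", ".", "-", ".",
            "ID=GeneB"), collapse = "\t"),
    paste(c("Chr2", "test", "gene", "1000000", "1100000", ".", "+", ".",
            "ID=GeneC"), collapse = "\t"),
    paste(c("Chr3", "test", "gene", "1", "1000", ".", "+", ".",
            "ID=GeneD"), collapse = "\t")), path)
  path
}
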