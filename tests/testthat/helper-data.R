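# Small builders shared across test files.

# A minimal three-variant cohort: one missense in a brain gene, one
# synonymous, one missense in a non-brain gene; two samples.
tiny_cohort <- function() {
  v <- variant_table(chrom = c("1", "1", "2"),
                     pos = c(100L, 200L, 300L),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     gene = c("BRAIN1", "BRAIN1", "MUSCLE1"),
                     protein = c("D10N", "K20K", "E30Q"),
                     consequence = c("missense", "synonymous", "missense"))
  g <- genotype_table(sample_id = c("S1", "S1", "S2", "S2"),
                      key = v$key[c(1, 2, 2, 3)],
                      zygosity = c("het", "het", "hom_alt", "het"))
  variant_cohort(v, g, samples = c("S1", "S2"))
}

# The four ATP1A3 substitutions with their published chromosome-19
# coordinates, as a bare variant table.
atp1a3_variants <- function() {
  variant_table(chrom = "19",
                pos = c(42479781L, 42474436L, 42474557L, 42472976L),
                ref = "G", alt = c("T", "A", "A", "A"),
                gene = "ATP1A3",
                cdna = c("c.2263G>T", "c.2443G>A", "c.2401G>A", "c.2780G>A"),
                protein = c("G755C", "E815K", "D801N", "C927Y"),
                consequence = "missense")
}

# Known-variant database holding only the D801Y record: same chr19 position
# as D801N, different alternate allele.
d801y_db <- function() known_db("19", 42474557L, "G", "T", "RDP_D801Y")

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
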