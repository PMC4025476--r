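{
  "version": "starter-1",
  "entries": [
    {"term": "allele", "definition": "One of the alternative forms of a gene found at the same locus."},
    {"term": "genotype", "definition": "The allelic constitution of an individual at one or more loci."},
    {"term": "phenotype", "definition": "The observable characteristics of an individual produced by genotype and environment."},
    {"term": "locus", "definition": "The position on a chromosome where a particular gene resides."},
    {"term": "dominant", "definition": "Describes an allele whose phenotype is expressed in the heterozygote."},
    {"term": "recessive", "definition": "Describes an allele whose phenotype is masked in the heterozygote."},
    {"term": "homozygote", "definition": "An individual carrying two identical alleles at a locus."},
    {"term": "heterozygote", "definition": "An individual carrying two different alleles at a locus."},
    {"term": "hemizygous", "definition": "Carrying a single copy of a gene, as males are for X-linked loci."},
    {"term": "testcross", "definition": "A cross of an individual to a fully homozygous recessive partner to reveal its gametes."},
    {"term": "recombination", "definition": "The production of offspring allele combinations absent from either parent, by crossing over or independent assortment."},
    {"term": "linkage", "definition": "The tendency of alleles at nearby loci on the same chromosome to be inherited together."},
    {"term": "centimorgan", "definition": "A map unit corresponding to a one percent recombination frequency between two loci."},
    {"term": "interference", "definition": "The reduction of double crossovers below the frequency expected from independent exchanges."},
    {"term": "genetic drift", "definition": "Random change of allele frequencies caused by sampling in a finite population."},
    {"term": "fixation", "definition": "The rise of an allele to a frequency of one hundred percent in a population."},
    {"term": "inbreeding coefficient", "definition": "The probability that the two alleles of an individual are identical by descent, measured as a deficit of heterozygotes."},
    {"term": "heritability", "definition": "The proportion of phenotypic variance in a trait attributable to genetic variance."},
    {"term": "selection differential", "definition": "The difference between the mean trait value of selected parents and the population mean."},
    {"term": "fitness", "definition": "The relative reproductive success of a genotype."}
  ]
}
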