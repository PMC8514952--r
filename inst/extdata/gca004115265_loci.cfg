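# T-cell receptor locus regions of the greater horseshoe bat assembly
# GCA_004115265.3, delimited by the published flanking (borne) genes.
# Coordinates are 1-based inclusive on the NCBI chromosome accessions and
# cover the interval between the flanking genes; strand is the locus
# transcription orientation. Use with a locally downloaded genome FASTA:
#   store <- load_sequences("GCA_004115265.3.fasta")
#   loci  <- read_locus_config(system.file("extdata",
#              "gca004115265_loci.cfg", package = "trlocus"))
#   annotate_genome(store, loci, refs)
TRA/D = NC_046289.1, 2450212, 3318652, +, OR10G2, DAD1
TRG = NC_046303.1, 52030212, 52205146, -, AMPH, STARD3NL
TRB = NC_046309.1, 7926437, 8164120, -, MOXD2, EPHB6
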