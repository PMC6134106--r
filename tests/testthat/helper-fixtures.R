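## Small deterministic genomes and tables used across tests.

## A hand-built 60 bp genome with one plus-strand and one minus-strand
## protein gene whose coding sequences are known exactly, plus a primer mask.
##  - plus gene: positions 4..15, frame 0, sequence ATGGCAAAATGG  (M A K W)
##  - minus gene: positions 31..42, frame 0; genomic ATGCATCATCAT read on the
##    minus strand (revcomp) = ATGATGATGCAT (M M M H)
tinyGenome <- function() {
  s <- paste0(
    "TTT",           # 1..3   intergenic
    "ATGGCAAAATGG",  # 4..15  plus-strand CDS
    "CCCCC",         # 16..20 intergenic
    "GGGGGGGGGG",    # 21..30 control region
    "ATGCATCATCAT",  # 31..42 minus-strand CDS (revcomp = ATGATGATGCAT)
    "ACGTACGTACGTACGTAC")  # 43..60 intergenic
  gr <- GenomicRanges::GRanges(
    seqnames = "mito",
    ranges = IRanges::IRanges(start = c(4, 21, 31, 50),
                              end = c(15, 30, 42, 52)),
    strand = c("+", "*", "-", "*"))
  gr$name <- c("plusGene", "CR", "minusGene", "primer1")
  gr$type <- c("protein", "noncoding", "protein", "primer")
  gr$frame <- c(0L, NA_integer_, 0L, NA_integer_)
  methods::new("Mitogenome", sequence = Biostrings::DNAString(s),
               features = gr)
}

## calls table with the minimum columns the IO layer requires
makeCalls <- function(position, maf, depth = 2000, ref = "A", alt = "G",
                      sample = "S1") {
  n <- length(position)
  data.frame(position = position, ref = rep_len(ref, n),
             alt = rep_len(alt, n), maf = maf,
             depth = rep_len(depth, n), sample = rep_len(sample, n),
             stringsAsFactors = FALSE)
}
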